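# Plain-text raster I/O (ESRI ASCII grid) with a YAML provenance sidecar.
# The .asc header carries the georeference; class codes are written as
# integers, indicators as floats; -9999 marks nodata.

#' Write a raster to ESRI ASCII grid
#'
#' @param x a [LandCoverMap-class], or a numeric matrix with georeference
#'   arguments supplied.
#' @param path output path (conventionally .asc).
#' @param xmin,ymin,res georeference, used when \code{x} is a bare matrix.
#' @param config optional [synthConfig()] written to a \code{.yml} sidecar
#'   for provenance.
#' @return \code{path}, invisibly.
#' @export
writeAsciiGrid <- function(x, path, xmin = 0, ymin = 0, res = 1,
                           config = NULL) {
  if (is(x, "LandCoverMap")) {
    m <- x@codes; xmin <- x@xmin; ymin <- x@ymin; res <- x@res
  } else m <- x
  hdr <- c(sprintf("NCOLS %d", ncol(m)), sprintf("NROWS %d", nrow(m)),
           sprintf("XLLCORNER %.10g", xmin), sprintf("YLLCORNER %.10g", ymin),
           sprintf("CELLSIZE %.10g", res), "NODATA_VALUE -9999")
  m[is.na(m)] <- -9999
  body <- apply(m, 1L, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  if (!is.null(config))
    yaml::write_yaml(unclass(config), paste0(tools::file_path_sans_ext(path), ".yml"))
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path path to a .asc file.
#' @param categorical if TRUE return a [LandCoverMap-class], else a list
#'   with the numeric matrix and georeference.
#' @return See \code{categorical}.
#' @export
readAsciiGrid <- function(path, categorical = TRUE) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  vals <- setNames(as.numeric(vapply(hdr, `[`, "", 2)),
                   toupper(vapply(hdr, `[`, "", 1)))
  m <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  m[m == vals[["NODATA_VALUE"]]] <- NA
  if (categorical)
    LandCoverMap(m, xmin = vals[["XLLCORNER"]], ymin = vals[["YLLCORNER"]],
                 res = vals[["CELLSIZE"]])
  else
    list(values = m, xmin = vals[["XLLCORNER"]], ymin = vals[["YLLCORNER"]],
         res = vals[["CELLSIZE"]])
}

# WKT polygon for a grid cell footprint (CSV geometry column)
cellWKT <- function(cells) {
  sprintf("POLYGON((%g %g, %g %g, %g %g, %g %g, %g %g))",
          cells$xmin, cells$ymin, cells$xmax, cells$ymin,
          cells$xmax, cells$ymax, cells$xmin, cells$ymax,
          cells$xmin, cells$ymin)
}

#' Write a RiskGrid to CSV
#'
#' One row per cell with id, grid row/col, clipped area and a WKT geometry
#' column of the square footprint.
#'
#' @param grid a [RiskGrid-class].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeGridCSV <- function(grid, path) {
  df <- cellTable(grid)
  df$geometry_wkt <- cellWKT(df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
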