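# internal helpers shared across modules

# pixel-center coordinate vectors for a raster with nr x nc pixels
pixelCenters <- function(nr, nc, xmin, ymin, res) {
  list(x = xmin + (seq_len(nc) - 0.5) * res,
       y = ymin + (nr - seq_len(nr) + 0.5) * res)  # row 1 = top
}

mapExtent <- function(m) {
  d <- if (is(m, "LandCoverMap")) dim(m@codes) else dim(m@surfaces[[1]])
  c(xmin = m@xmin, ymin = m@ymin,
    xmax = m@xmin + d[2] * m@res, ymax = m@ymin + d[1] * m@res)
}

# registry equality for any pair of map-like objects
sameRegistry <- function(a, b, tol = 1e-9) {
  da <- if (is(a, "LandCoverMap")) dim(a@codes) else dim(a@surfaces[[1]])
  db <- if (is(b, "LandCoverMap")) dim(b@codes) else dim(b@surfaces[[1]])
  identical(da, db) && abs(a@xmin - b@xmin) < tol &&
    abs(a@ymin - b@ymin) < tol && abs(a@res - b@res) < tol
}

registryDiff <- function(a, b) {
  da <- if (is(a, "LandCoverMap")) dim(a@codes) else dim(a@surfaces[[1]])
  db <- if (is(b, "LandCoverMap")) dim(b@codes) else dim(b@surfaces[[1]])
  sprintf("registry mismatch: dim %s vs %s; origin (%g,%g) vs (%g,%g); res %g vs %g",
          paste(da, collapse = "x"), paste(db, collapse = "x"),
          a@xmin, a@ymin, b@xmin, b@ymin, a@res, b@res)
}

# shift a matrix by (dr, dc), padding with `fill`
shiftMatrix <- function(m, dr, dc, fill = NA) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  rok <- rs >= 1L & rs <= nr; cok <- cs >= 1L & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

neighborOffsets <- function(connectivity) {
  four <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 4L) return(four)
  c(four, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
}

#' @describeIn LandCoverMap display summary
#' @param object a LandCoverMap
#' @export
setMethod("show", "LandCoverMap", function(object) {
  d <- dim(object@codes)
  valid <- sum(!is.na(object@codes))
  cat(sprintf("LandCoverMap: %d x %d pixels @ %g km (%.0f km^2 valid)\n",
              d[1], d[2], object@res, valid * object@res^2))
  tab <- table(factor(object@codes, levels = 1:6, labels = names(landClasses())))
  print(round(100 * tab / max(valid, 1), 1))
})

#' @describeIn IndicatorStack display summary
#' @param object an IndicatorStack
#' @export
setMethod("show", "IndicatorStack", function(object) {
  d <- dim(object@surfaces[[1]])
  cat(sprintf("IndicatorStack: 8 surfaces, %d x %d pixels @ %g km\n",
              d[1], d[2], object@res))
  orient <- ifelse(object@orientations > 0, "+", "-")
  cat("  orientation:", paste0(names(object@orientations), orient, collapse = " "), "\n")
})

#' @describeIn RiskGrid display summary
#' @param object a RiskGrid
#' @export
setMethod("show", "RiskGrid", function(object) {
  cat(sprintf("RiskGrid: %d cells of %g km (total clipped area %.1f km^2)\n",
              nrow(object@cells), object@cellSize, sum(object@cells$area_km2)))
})

#' @describeIn CellComposition display summary
#' @param object a CellComposition
#' @export
setMethod("show", "CellComposition", function(object) {
  cat(sprintf("CellComposition: %d cells x %d classes, total area %.1f km^2\n",
              nrow(object@classArea), ncol(object@classArea),
              sum(object@cellArea)))
})

#' Number of assessment cells
#' @param grid a [RiskGrid-class]
#' @return integer count of retained cells
#' @export
nCells <- function(grid) nrow(grid@cells)

#' Cell table of a RiskGrid
#' @param grid a [RiskGrid-class]
#' @return data.frame of cell ids, footprints and clipped areas
#' @export
cellTable <- function(grid) grid@cells

#' Clipped per-cell areas A_k
#' @param grid a [RiskGrid-class]
#' @return named numeric vector of areas (km^2), names = cell ids
#' @export
cellAreas <- function(grid) setNames(grid@cells$area_km2, grid@cells$id)

#' Class-area matrix of a composition
#' @param x a [CellComposition-class]
#' @return cells x classes matrix of areas (km^2)
#' @export
classAreas <- function(x) x@classArea
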