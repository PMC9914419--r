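# Assessment grid construction and zonal statistics.
#
# Geometry is deliberately small and exact: study boundaries are single-ring
# polygons (no holes), cells are axis-aligned squares, and the clipped cell
# area comes from Sutherland-Hodgman clipping + the shoelace formula. Pixels
# are assigned to the cell containing their center (half-open intervals,
# left/bottom inclusive).

#' Rectangle boundary helper
#'
#' @param xmin,ymin,xmax,ymax rectangle corners in km.
#' @return A closed two-column ring matrix usable as a study boundary.
#' @export
boundaryFromExtent <- function(xmin, ymin, xmax, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  cbind(x = c(xmin, xmax, xmax, xmin, xmin),
        y = c(ymin, ymin, ymax, ymax, ymin))
}

#' Read a polygon boundary from GeoJSON
#'
#' Reads the outer ring of the first (Multi)Polygon feature. Holes and
#' additional parts are not supported and raise an error.
#'
#' @param path path to a GeoJSON file; coordinates are taken as km.
#' @return Closed two-column ring matrix.
#' @export
readBoundaryGeoJSON <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- if (!is.null(g$features)) {
    if (is.data.frame(g$features)) g$features$geometry else g$features[[1]]$geometry
  } else if (!is.null(g$geometry)) g$geometry else g
  type <- if (is.data.frame(geom)) geom$type[1] else geom$type
  co <- if (is.data.frame(geom)) geom$coordinates[[1]] else geom$coordinates
  ring <- switch(type,
    Polygon = if (is.list(co)) co[[1]] else co[1, , ],
    MultiPolygon = stop("MultiPolygon boundaries are not supported"),
    stop("unsupported geometry type: ", type))
  ring <- as.matrix(ring)
  if (length(dim(ring)) == 3L) ring <- ring[1, , ]
  colnames(ring) <- c("x", "y")
  closeRing(ring)
}

closeRing <- function(ring) {
  if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  ring
}

# signed shoelace area; abs() is the polygon area
polygonArea <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

# Sutherland-Hodgman clip of an arbitrary simple polygon against an
# axis-aligned rectangle (convex clip window, so the algorithm is exact)
clipRingToRect <- function(ring, xmin, ymin, xmax, ymax) {
  poly <- ring[-nrow(ring), , drop = FALSE]  # open representation
  for (side in 1:4) {
    if (nrow(poly) == 0L) return(poly)
    inside <- switch(side,
      poly[, 1] >= xmin, poly[, 1] <= xmax,
      poly[, 2] >= ymin, poly[, 2] <= ymax)
    n <- nrow(poly)
    out <- matrix(numeric(0), 0, 2)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      p <- poly[i, ]; q <- poly[j, ]
      pin <- inside[i]; qin <- inside[j]
      if (pin) out <- rbind(out, p)
      if (xor(pin, qin)) {
        t <- switch(side,
          (xmin - p[1]) / (q[1] - p[1]), (xmax - p[1]) / (q[1] - p[1]),
          (ymin - p[2]) / (q[2] - p[2]), (ymax - p[2]) / (q[2] - p[2]))
        out <- rbind(out, p + t * (q - p))
      }
    }
    poly <- out
  }
  poly
}

# clipped area of the boundary within one rectangle
clippedArea <- function(ring, xmin, ymin, xmax, ymax) {
  poly <- clipRingToRect(ring, xmin, ymin, xmax, ymax)
  if (nrow(poly) < 3L) return(0)
  polygonArea(rbind(poly, poly[1, ]))
}

#' Build the square assessment grid over a study boundary
#'
#' Lays a fishnet of \code{cellSize} squares anchored at the boundary
#' envelope's lower-left corner (plus an optional offset), clips each cell to
#' the boundary, and retains cells whose clipped area exceeds
#' \code{sliverFrac} of a full cell. Ids are row-major from the grid origin
#' (bottom row first, left to right) and are stable across runs.
#'
#' @param boundary closed ring matrix (e.g. [boundaryFromExtent()] or
#'   [readBoundaryGeoJSON()]).
#' @param cellSize cell edge length in km (default 20).
#' @param offset numeric length-2 shift of the grid origin (km).
#' @param sliverFrac drop cells with clipped area below this fraction of a
#'   full cell (default 0.01).
#' @return A [RiskGrid-class].
#' @export
#' @examples
#' g <- buildFishnet(boundaryFromExtent(0, 0, 40, 40), cellSize = 20)
#' cellTable(g)
buildFishnet <- function(boundary, cellSize = 20, offset = c(0, 0),
                         sliverFrac = 0.01) {
  if (is.null(dim(boundary)) || nrow(boundary) < 4L)
    stop("boundary must be a closed polygon ring with >= 3 vertices")
  if (cellSize <= 0) stop("cellSize must be > 0")
  boundary <- closeRing(as.matrix(boundary))
  if (polygonArea(boundary) <= 0) stop("boundary polygon is empty")
  ox <- min(boundary[, 1]) + offset[1]
  oy <- min(boundary[, 2]) + offset[2]
  nx <- ceiling((max(boundary[, 1]) - ox) / cellSize - 1e-9)
  ny <- ceiling((max(boundary[, 2]) - oy) / cellSize - 1e-9)
  rows <- integer(0); cols <- integer(0); areas <- numeric(0)
  for (r in seq_len(ny)) {
    y0 <- oy + (r - 1) * cellSize
    for (cc in seq_len(nx)) {
      x0 <- ox + (cc - 1) * cellSize
      a <- clippedArea(boundary, x0, y0, x0 + cellSize, y0 + cellSize)
      if (a > sliverFrac * cellSize^2) {
        rows <- c(rows, r); cols <- c(cols, cc); areas <- c(areas, a)
      }
    }
  }
  if (!length(areas)) stop("no cells intersect the boundary")
  cells <- data.frame(
    id = seq_along(areas), row = rows, col = cols,
    xmin = ox + (cols - 1) * cellSize, ymin = oy + (rows - 1) * cellSize,
    xmax = ox + cols * cellSize, ymax = oy + rows * cellSize,
    area_km2 = areas)
  new("RiskGrid", cells = cells, cellSize = cellSize, origin = c(ox, oy),
      boundary = boundary)
}

# per-pixel cell id (NA where the pixel falls in no retained cell);
# half-open assignment by pixel center
pixelCellIds <- function(grid, mapLike) {
  d <- if (is(mapLike, "LandCoverMap")) dim(mapLike@codes) else
    dim(mapLike@surfaces[[1]])
  ctr <- pixelCenters(d[1], d[2], mapLike@xmin, mapLike@ymin, mapLike@res)
  gcol <- floor((ctr$x - grid@origin[1]) / grid@cellSize) + 1L
  grow <- floor((ctr$y - grid@origin[2]) / grid@cellSize) + 1L
  key <- function(r, cc) r * 1e6 + cc
  lookup <- setNames(grid@cells$id, key(grid@cells$row, grid@cells$col))
  ids <- matrix(lookup[as.character(key(rep(grow, times = d[2]),
                                        rep(gcol, each = d[1])))],
                d[1], d[2])
  ids
}

#' Zonal land-cover composition of the grid
#'
#' Counts pixels of each class within each cell (pixel-center assignment)
#' and converts counts to areas \eqn{A_{ki}} via the pixel area. The
#' pixel-counted cell area \eqn{A_k} is the partition total, so
#' \eqn{\sum_i A_{ki} = A_k} holds exactly. Cells containing no valid pixel
#' are dropped with a warning.
#'
#' @param grid a [RiskGrid-class].
#' @param map a [LandCoverMap-class] registered to the same extent.
#' @return A [CellComposition-class].
#' @export
zonalComposition <- function(grid, map) {
  stopifnot(is(grid, "RiskGrid"), is(map, "LandCoverMap"))
  ids <- pixelCellIds(grid, map)
  ok <- !is.na(ids) & !is.na(map@codes)
  tab <- table(factor(ids[ok], levels = grid@cells$id),
               factor(map@codes[ok], levels = 1:6))
  classArea <- unclass(tab) * map@res^2
  dimnames(classArea) <- list(grid@cells$id, names(landClasses()))
  cellArea <- rowSums(classArea)
  empty <- cellArea <= 0
  if (any(empty)) {
    warning(sum(empty), " cell(s) contain no valid pixel and were dropped: ",
            paste(grid@cells$id[empty], collapse = ", "))
    classArea <- classArea[!empty, , drop = FALSE]
    cellArea <- cellArea[!empty]
  }
  new("CellComposition", classArea = classArea, cellArea = cellArea,
      cellIds = grid@cells$id[!empty])
}

#' Zonal means of indicator surfaces
#'
#' Arithmetic mean of each indicator over the valid pixels of each cell.
#' Cells with no valid pixel get \code{NA} and a warning.
#'
#' @param grid a [RiskGrid-class].
#' @param stack an [IndicatorStack-class] registered to the grid's extent.
#' @return Numeric matrix, cells x 8 indicators; rownames are cell ids.
#' @export
zonalIndicatorMeans <- function(grid, stack) {
  stopifnot(is(grid, "RiskGrid"), is(stack, "IndicatorStack"))
  ids <- pixelCellIds(grid, stack)
  out <- sapply(stack@surfaces, function(s) {
    ok <- !is.na(ids) & !is.na(s)
    f <- factor(ids[ok], levels = grid@cells$id)
    sums <- tapply(s[ok], f, sum, default = NA_real_)
    cnts <- tapply(rep(1, sum(ok)), f, sum, default = 0)
    as.numeric(sums) / ifelse(cnts > 0, as.numeric(cnts), NA_real_)
  })
  rownames(out) <- grid@cells$id
  if (anyNA(out))
    warning("cells with no valid pixels produced NA indicator means")
  out
}
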