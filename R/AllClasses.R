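#' @import methods
#' @importFrom stats quantile sd setNames runif rnorm
#' @importFrom utils write.csv read.csv
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData
#' @importFrom S4Vectors DataFrame
NULL

#' Land-cover legend
#'
#' The fixed six-class legend used throughout the package. Class codes are
#' integers 1..6 mapping, in order, to cropland, woodland, grassland, water,
#' urban land and unused land. Out-of-boundary pixels are stored as \code{NA}.
#'
#' @return Named integer vector of class codes.
#' @export
#' @examples
#' landClasses()
landClasses <- function() {
  c(cropland = 1L, woodland = 2L, grassland = 3L, water = 4L,
    urban = 5L, unused = 6L)
}

#' Indicator panel names
#'
#' Names of the eight environmental indicators used to build the composite
#' vulnerability adjustment factor: GDP density, population density,
#' elevation, slope, temperature, precipitation, net primary productivity
#' (NPP) and NDVI.
#'
#' @return Character vector of length 8.
#' @export
indicatorNames <- function() {
  c("GDP", "population", "elevation", "slope", "temperature",
    "precipitation", "NPP", "NDVI")
}

#' Default indicator orientations
#'
#' Orientation of each indicator with respect to ecological vulnerability:
#' \code{+1} means larger values indicate higher vulnerability (socio-economic
#' pressure and terrain exposure), \code{-1} means larger values indicate
#' lower vulnerability (moisture and vegetation productivity buffer risk).
#'
#' @return Named numeric vector of +1/-1 over [indicatorNames()].
#' @export
defaultOrientations <- function() {
  setNames(c(1, 1, 1, 1, 1, -1, -1, -1), indicatorNames())
}

#' Published fixed indicator weights
#'
#' The fixed entropy-method weight set for the eight indicators (GDP,
#' population, elevation, slope, temperature, precipitation, NPP, NDVI).
#' The weights sum to exactly 1.
#'
#' @return Named numeric vector of length 8.
#' @export
fixedIndicatorWeights <- function() {
  setNames(c(0.2421, 0.1467, 0.1482, 0.0985, 0.0892, 0.0647, 0.1023, 0.1083),
           indicatorNames())
}

#' Empirical landscape vulnerability ranks
#'
#' Expert-assigned vulnerability rank per land-cover class: unused land = 6,
#' water = 5, cropland = 4, grassland = 3, woodland = 2, urban land = 1.
#'
#' @return Named numeric vector over the six classes, in legend order.
#' @export
empiricalVulnerability <- function() {
  c(cropland = 4, woodland = 2, grassland = 3, water = 5, urban = 1,
    unused = 6)
}

# ---------------------------------------------------------------------------
# LandCoverMap

#' LandCoverMap class
#'
#' A categorical land-cover raster over a rectangular extent. Codes are the
#' six-class legend of [landClasses()]; \code{NA} marks pixels outside the
#' study boundary. Row 1 of the code matrix is the northernmost row;
#' coordinates are in kilometres.
#'
#' @slot codes integer matrix of class codes (NA = nodata).
#' @slot xmin,ymin lower-left corner of the extent (km).
#' @slot res pixel edge length (km); pixel area is \code{res^2} km^2.
#' @export
setClass("LandCoverMap",
  representation(codes = "matrix", xmin = "numeric", ymin = "numeric",
                 res = "numeric"),
  validity = function(object) {
    v <- object@codes
    msg <- character()
    if (!is.integer(v)) msg <- c(msg, "codes must be an integer matrix")
    bad <- v[!is.na(v)]
    if (length(bad) && (any(bad < 1L) || any(bad > 6L)))
      msg <- c(msg, "class codes must be in 1..6")
    if (length(object@res) != 1L || object@res <= 0)
      msg <- c(msg, "res must be a single positive length (km)")
    if (length(msg)) msg else TRUE
  })

#' Construct a LandCoverMap
#'
#' @param codes integer matrix of class codes (1..6, NA = outside boundary);
#'   row 1 is the top (north) row.
#' @param xmin,ymin lower-left corner of the extent in km.
#' @param res pixel edge length in km.
#' @return A [LandCoverMap-class] object.
#' @export
LandCoverMap <- function(codes, xmin = 0, ymin = 0, res = 1) {
  storage.mode(codes) <- "integer"
  new("LandCoverMap", codes = codes, xmin = xmin, ymin = ymin, res = res)
}

# ---------------------------------------------------------------------------
# IndicatorStack

#' IndicatorStack class
#'
#' Eight co-registered continuous indicator surfaces sharing one extent and
#' resolution with a paired [LandCoverMap-class]. Each surface is a numeric
#' matrix; \code{NA} marks out-of-boundary pixels.
#'
#' @slot surfaces named list of numeric matrices, one per indicator.
#' @slot orientations named numeric vector of +1/-1 per indicator.
#' @slot xmin,ymin,res georeference, as for [LandCoverMap-class].
#' @export
setClass("IndicatorStack",
  representation(surfaces = "list", orientations = "numeric",
                 xmin = "numeric", ymin = "numeric", res = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!identical(names(object@surfaces), indicatorNames()))
      msg <- c(msg, "surfaces must be named exactly by indicatorNames()")
    dims <- unique(lapply(object@surfaces, dim))
    if (length(dims) > 1L)
      msg <- c(msg, "all surfaces must share one dimension")
    if (!identical(names(object@orientations), indicatorNames()) ||
        !all(object@orientations %in% c(-1, 1)))
      msg <- c(msg, "orientations must be +1/-1 named by indicatorNames()")
    if (length(msg)) msg else TRUE
  })

#' Construct an IndicatorStack
#'
#' @param surfaces named list of numeric matrices (names = [indicatorNames()]).
#' @param orientations +1/-1 per indicator; default [defaultOrientations()].
#' @param xmin,ymin,res georeference in km.
#' @return An [IndicatorStack-class] object.
#' @export
IndicatorStack <- function(surfaces, orientations = defaultOrientations(),
                           xmin = 0, ymin = 0, res = 1) {
  new("IndicatorStack", surfaces = surfaces,
      orientations = orientations[indicatorNames()],
      xmin = xmin, ymin = ymin, res = res)
}

# ---------------------------------------------------------------------------
# RiskGrid

#' RiskGrid class
#'
#' The square assessment grid (fishnet) clipped to a study boundary. Each
#' retained cell carries a stable integer id (row-major from the grid
#' origin), its square footprint and its clipped in-boundary area in km^2.
#'
#' @slot cells data.frame with columns id, row, col, xmin, ymin, xmax, ymax,
#'   area_km2 (clipped polygon area).
#' @slot cellSize cell edge length (km).
#' @slot origin grid anchor (lower-left), numeric length 2.
#' @slot boundary closed polygon ring, two-column matrix (km).
#' @export
setClass("RiskGrid",
  representation(cells = "data.frame", cellSize = "numeric",
                 origin = "numeric", boundary = "matrix"),
  validity = function(object) {
    msg <- character()
    need <- c("id", "row", "col", "xmin", "ymin", "xmax", "ymax", "area_km2")
    if (!all(need %in% names(object@cells)))
      msg <- c(msg, paste("cells must have columns:", paste(need, collapse = ", ")))
    else {
      if (anyDuplicated(object@cells$id)) msg <- c(msg, "cell ids must be unique")
      if (any(object@cells$area_km2 <= 0)) msg <- c(msg, "all A_k must be > 0")
    }
    if (length(msg)) msg else TRUE
  })

# ---------------------------------------------------------------------------
# CellComposition

#' CellComposition class
#'
#' Per-cell land-cover composition from zonal pixel counting: the area
#' \eqn{A_{ki}} of each class in each cell, and the pixel-counted cell area
#' \eqn{A_k} (valid pixels times pixel area). Classes partition the valid
#' pixels, so \eqn{\sum_i A_{ki} = A_k} exactly.
#'
#' @slot classArea numeric matrix, cells x 6 classes, km^2.
#' @slot cellArea numeric vector of pixel-counted A_k, km^2.
#' @slot cellIds integer cell ids (rows of classArea).
#' @export
setClass("CellComposition",
  representation(classArea = "matrix", cellArea = "numeric",
                 cellIds = "integer"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@classArea) != length(object@cellArea) ||
        nrow(object@classArea) != length(object@cellIds))
      msg <- c(msg, "classArea, cellArea and cellIds must agree in length")
    if (any(object@classArea < 0)) msg <- c(msg, "areas must be >= 0")
    if (length(msg) == 0 &&
        any(abs(rowSums(object@classArea) - object@cellArea) > 1e-8))
      msg <- c(msg, "class areas must sum to the cell area")
    if (length(msg)) msg else TRUE
  })

# ---------------------------------------------------------------------------
# RiskPanel

#' RiskPanel class
#'
#' Assessment results as a \linkS4class{SummarizedExperiment}: rows are grid
#' cells, columns are time points, and the \code{"LERI"} assay holds the
#' landscape ecological risk index. Temporal statistics (RRC, CV) and
#' key-area flags are attached to \code{rowData} by their computing
#' functions.
#'
#' @export
setClass("RiskPanel", contains = "SummarizedExperiment")

#' Construct a RiskPanel
#'
#' @param leri numeric matrix of LERI values, cells x time points; column
#'   names are the time labels (e.g. years), row names the cell ids.
#' @param cellArea per-cell area A_k (km^2), recycled into rowData.
#' @return A [RiskPanel-class].
#' @export
RiskPanel <- function(leri, cellArea = NULL) {
  if (is.null(colnames(leri)))
    colnames(leri) <- paste0("t", seq_len(ncol(leri)))
  rd <- S4Vectors::DataFrame(row.names = rownames(leri))
  if (!is.null(cellArea)) rd$area_km2 <- cellArea
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(LERI = leri), rowData = rd)
  new("RiskPanel", se)
}

#' @describeIn RiskPanel the LERI assay matrix.
#' @param panel a RiskPanel.
#' @export
leriValues <- function(panel) {
  SummarizedExperiment::assay(panel, "LERI")
}
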