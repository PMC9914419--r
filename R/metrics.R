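# Per-cell, per-class patch metrics and the landscape disturbance index.
#
# E_ki = a*C_ki + b*S_ki + c*D_ki with defaults a=0.5, b=0.3, c=0.2:
#   C_ki = n_ki / A_ki                      (fragmentation, patches/km^2)
#   S_ki = A_k / (2 A_ki) * sqrt(n_ki/A_k)  (separation)
#   D_ki = (Q_i + M_ki)/4 + L_ki/2          (dominance, in [0,1])
# Patches are delineated independently within each cell window; a patch
# spanning two cells counts in both (the index is strictly per-plot).
# Absent classes (A_ki = 0) take all metrics 0 by convention.

#' Disturbance index weights
#'
#' Weights of fragmentation, separation and dominance in the landscape
#' disturbance index. Must be non-negative and sum to 1; defaults a = 0.5,
#' b = 0.3, c = 0.2.
#'
#' @param a,b,c component weights.
#' @return Named numeric vector c(a, b, c).
#' @export
disturbanceWeights <- function(a = 0.5, b = 0.3, c = 0.2) {
  w <- c(a = a, b = b, c = c)
  if (any(w < 0)) stop("disturbance weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-8)
    stop("disturbance weights must sum to 1 (got ", format(sum(w)), ")")
  w
}

# connected-component labelling of a logical mask by iterative minimum-label
# propagation; exact for any mask, converges in O(geodesic diameter) sweeps
labelComponents <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(Inf, nr, nc)
  lab[mask] <- which(mask)
  offs <- neighborOffsets(connectivity)
  repeat {
    new <- lab
    for (o in offs) {
      s <- shiftMatrix(lab, o[1], o[2], fill = Inf)
      new <- pmin(new, s)
    }
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  out <- matrix(0L, nr, nc)
  if (any(mask)) {
    ids <- lab[mask]
    out[mask] <- as.integer(factor(ids, levels = sort(unique(ids))))
  }
  out
}

#' Count patches of one class in a cell window
#'
#' Number of connected components of pixels holding class \code{class} in
#' the window (n_ki). Diagonal adjacency joins patches under 8-connectivity
#' only.
#'
#' @param window integer matrix of class codes (NA allowed).
#' @param class a legend code in 1..6.
#' @param connectivity 4 or 8 (default 8, the common landscape-pattern
#'   software convention).
#' @return Integer patch count (0 if the class is absent).
#' @export
#' @examples
#' w <- matrix(c(1, 2, 2, 1), 2, 2)
#' labelPatches(w, 1, connectivity = 4)  # 2
#' labelPatches(w, 1, connectivity = 8)  # 1
labelPatches <- function(window, class, connectivity = 8L) {
  if (length(window) == 0L) stop("empty window")
  if (!class %in% 1:6) stop("unknown class code: ", class)
  mask <- !is.na(window) & window == class
  if (!any(mask)) return(0L)
  max(labelComponents(mask, connectivity))
}

#' Fragmentation index C_ki
#'
#' Patches per unit class area, \eqn{C_{ki} = n_{ki}/A_{ki}}. An absent
#' class (n = 0, A = 0) returns 0 by convention.
#'
#' @param n patch count n_ki.
#' @param area class area A_ki in km^2.
#' @return Fragmentation in patches/km^2.
#' @export
fragmentation <- function(n, area) {
  ifelse(area > 0, n / area, 0)
}

#' Separation index S_ki
#'
#' Isolation of a class's patches within a cell,
#' \eqn{S_{ki} = \frac{A_k}{2A_{ki}}\sqrt{n_{ki}/A_k}}. Increases with patch
#' count at fixed areas and decreases with class area share. Absent classes
#' return 0.
#'
#' @param n patch count n_ki.
#' @param area class area A_ki (km^2).
#' @param cellArea cell area A_k (km^2).
#' @return Separation (dimensionless given km^2 inputs).
#' @export
separation <- function(n, area, cellArea) {
  if (any(cellArea <= 0)) stop("cell area must be > 0")
  ifelse(area > 0, cellArea / (2 * area) * sqrt(n / cellArea), 0)
}

#' Occurrence frequency Q_i
#'
#' Fraction of grid cells in which each class occurs (A_ki > 0).
#'
#' @param composition a [CellComposition-class].
#' @return Named numeric vector over the six classes, values in [0,1].
#' @export
occurrenceFrequency <- function(composition) {
  stopifnot(is(composition, "CellComposition"))
  colMeans(composition@classArea > 0)
}

#' Dominance index D_ki
#'
#' \eqn{D_{ki} = (Q_i + M_{ki})/4 + L_{ki}/2}, where Q is the class's
#' occurrence frequency across cells, M its share of the cell's patches and
#' L its share of the cell's area, all in [0,1]. For an absent class the
#' convention is D = 0 (applied by [cellTypeMetrics()], not here).
#'
#' @param Q,M,L components in [0,1].
#' @return Dominance in [0,1].
#' @export
dominance <- function(Q, M, L) {
  if (any(c(Q, M, L) < 0) || any(c(Q, M, L) > 1))
    stop("dominance components must lie in [0, 1]")
  (Q + M) / 4 + L / 2
}

#' Disturbance index E_ki
#'
#' Weighted combination \eqn{E = aC + bS + cD} of fragmentation, separation
#' and dominance.
#'
#' @param C,S,D component metrics.
#' @param weights a [disturbanceWeights()] vector.
#' @return Disturbance index values.
#' @export
disturbance <- function(C, S, D, weights = disturbanceWeights()) {
  weights <- disturbanceWeights(weights[["a"]], weights[["b"]], weights[["c"]])
  weights[["a"]] * C + weights[["b"]] * S + weights[["c"]] * D
}

#' Per-cell, per-class patch metrics
#'
#' Extracts each cell's pixel window from the map, counts patches per class,
#' and evaluates fragmentation, separation, dominance and disturbance. Areas
#' are the pixel-counted zonal composition, so metric and composition areas
#' agree exactly.
#'
#' @param grid a [RiskGrid-class].
#' @param map a [LandCoverMap-class].
#' @param weights [disturbanceWeights()].
#' @param connectivity 4 or 8 (default 8).
#' @param composition optional precomputed [zonalComposition()] result.
#' @return Long-format data.frame: cell_id, class, n, area_km2, cell_area_km2,
#'   C, S, D, E. Only cells retained by the composition appear.
#' @export
cellTypeMetrics <- function(grid, map, weights = disturbanceWeights(),
                            connectivity = 8L,
                            composition = zonalComposition(grid, map)) {
  stopifnot(is(grid, "RiskGrid"), is(map, "LandCoverMap"))
  ids <- pixelCellIds(grid, map)
  Q <- occurrenceFrequency(composition)
  classes <- names(landClasses())
  res <- vector("list", length(composition@cellIds))
  for (k in seq_along(composition@cellIds)) {
    cid <- composition@cellIds[k]
    sel <- which(ids == cid & !is.na(map@codes), arr.ind = TRUE)
    rr <- range(sel[, 1]); cr <- range(sel[, 2])
    window <- map@codes[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
    inCell <- ids[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE] == cid
    window[!inCell | is.na(inCell)] <- NA_integer_
    n <- vapply(1:6, function(cl) {
      if (composition@classArea[k, cl] > 0)
        labelPatches(window, cl, connectivity) else 0L
    }, integer(1))
    A <- composition@classArea[k, ]
    Ak <- composition@cellArea[k]
    Cki <- fragmentation(n, A)
    Ski <- separation(n, A, Ak)
    M <- if (sum(n) > 0) n / sum(n) else rep(0, 6)
    L <- A / Ak
    Dki <- ifelse(A > 0, dominance(Q, M, L), 0)
    res[[k]] <- data.frame(
      cell_id = cid, class = classes, n = n, area_km2 = as.numeric(A),
      cell_area_km2 = Ak, C = as.numeric(Cki), S = as.numeric(Ski),
      D = as.numeric(Dki), E = as.numeric(disturbance(Cki, Ski, Dki, weights)),
      row.names = NULL)
  }
  do.call(rbind, res)
}
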