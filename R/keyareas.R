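# Key risk-management areas: the union of three top-quantile categories.
# "Top q" (default q = 0.15) means strictly greater than the (1-q) empirical
# percentile (linear interpolation, stats::quantile type 7); tied values at
# the threshold are excluded with a warning. With all-distinct rankings this
# flags exactly floor(q*N) cells.

topQuantileFlags <- function(x, q, what = "values") {
  if (!is.numeric(q) || q <= 0 || q >= 1) stop("q must be in (0, 1)")
  ok <- is.finite(x)
  thr <- quantile(x[ok], probs = 1 - q, names = FALSE)
  flags <- ok & x > thr
  if (any(ok & x == thr))
    warning("ties at the ", 100 * (1 - q), "th percentile of ", what,
            " are excluded from the top quantile")
  flags
}

#' Stable high-risk cells
#'
#' Cells whose LERI lies in the top \code{q} fraction of cells in every
#' period — risk that remained high for the duration of the study.
#'
#' @param panel a [RiskPanel-class] with >= 2 periods.
#' @param q quantile threshold in (0,1); default 0.15.
#' @return Logical flag per cell.
#' @export
stableHighRisk <- function(panel, q = 0.15) {
  L <- leriValues(panel)
  if (ncol(L) < 2L) stop("need >= 2 periods")
  perPeriod <- vapply(seq_len(ncol(L)), function(t)
    topQuantileFlags(L[, t], q, paste0("LERI ", colnames(L)[t])),
    logical(nrow(L)))
  setNames(rowSums(perPeriod) == ncol(L), rownames(L))
}

#' Risk-reduction-lagged cells
#'
#' Cells whose full-period RRC is in the top \code{q} fraction: the slowest
#' reducers (or fastest growers) of risk.
#'
#' @param rrc full-period RRC per cell (% per year).
#' @param q quantile threshold; default 0.15.
#' @return Logical flag per cell (NA RRC never flags).
#' @export
reductionLagged <- function(rrc, q = 0.15) {
  topQuantileFlags(rrc, q, "RRC")
}

#' Risk-unstable cells
#'
#' Cells whose LERI coefficient of variation is in the top \code{q}
#' fraction: the least temporally stable risk.
#'
#' @param cv CV per cell.
#' @param q quantile threshold; default 0.15.
#' @return Logical flag per cell.
#' @export
riskUnstable <- function(cv, q = 0.15) {
  topQuantileFlags(cv, q, "CV")
}

#' Combine the three key-area categories
#'
#' @param stable,lagged,unstable logical flags over the same cells (named
#'   vectors are matched by name).
#' @return List of class \code{keyAreaMask}: per-cell flags data.frame,
#'   per-category counts, pairwise overlap counts, the union count and the
#'   union share of all cells in percent.
#' @export
#' @examples
#' m <- combineKeyAreas(c(TRUE, FALSE, FALSE), c(FALSE, TRUE, FALSE),
#'                      c(FALSE, FALSE, FALSE))
#' m$unionCount  # 2
combineKeyAreas <- function(stable, lagged, unstable) {
  if (length(stable) != length(lagged) || length(stable) != length(unstable))
    stop("flag vectors must align")
  nms <- names(stable)
  if (!is.null(nms) &&
      (!identical(nms, names(lagged)) || !identical(nms, names(unstable))))
    stop("mismatched cell ids across categories")
  f <- function(x) !is.na(x) & x
  stable <- f(stable); lagged <- f(lagged); unstable <- f(unstable)
  union <- stable | lagged | unstable
  flags <- data.frame(cell_id = nms %||% seq_along(stable),
                      stable_high_risk = stable, reduction_lagged = lagged,
                      risk_unstable = unstable, key_union = union)
  structure(list(
    flags = flags,
    counts = c(stable_high_risk = sum(stable), reduction_lagged = sum(lagged),
               risk_unstable = sum(unstable)),
    overlaps = c(stable_lagged = sum(stable & lagged),
                 stable_unstable = sum(stable & unstable),
                 lagged_unstable = sum(lagged & unstable)),
    unionCount = sum(union),
    nCells = length(union),
    unionSharePct = 100 * sum(union) / length(union)),
    class = "keyAreaMask")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Identify key risk-management areas from a panel
#'
#' Runs the three category rules at a common quantile threshold and combines
#' them. Requires [addTemporalStats()] to have been applied (or applies it).
#'
#' @param panel a [RiskPanel-class].
#' @param q quantile threshold; default 0.15.
#' @return A \code{keyAreaMask} (see [combineKeyAreas()]).
#' @export
keyAreas <- function(panel, q = 0.15) {
  rd <- SummarizedExperiment::rowData(panel)
  if (!all(c("RRC", "CV") %in% colnames(rd))) {
    panel <- addTemporalStats(panel)
    rd <- SummarizedExperiment::rowData(panel)
  }
  nms <- rownames(leriValues(panel))
  combineKeyAreas(stableHighRisk(panel, q),
                  setNames(reductionLagged(rd$RRC, q), nms),
                  setNames(riskUnstable(rd$CV, q), nms))
}
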