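# The landscape ecological risk index and its temporal statistics:
#   LERI_k = sum_i E_ki * F_ki * A_ki / A_k
#   RRC_k  = (LERI_T2 - LERI_T1)/LERI_T1 * 1/dT * 100   (% per year)
#   CV_k   = SD_k / AV_k over the cell's LERI time series (sample SD).

#' Landscape ecological risk index per cell
#'
#' Combines the per-class disturbance (E), vulnerability (F) and area share
#' into the composition-weighted risk index
#' \eqn{LERI_k = \sum_i E_{ki} F_{ki} A_{ki}/A_k}. It is the
#' composition-weighted mean of \eqn{E\times F} and is bounded above by
#' \eqn{\max_i E_{ki}F_{ki}}.
#'
#' @param metrics long-format metrics from [cellTypeMetrics()] (columns
#'   cell_id, class, area_km2, cell_area_km2, E).
#' @param vulnerability cells x 6 matrix of F_ki with rownames = cell ids
#'   (e.g. \code{computeVulnerability(...)$F}), or a single per-cell MN
#'   vector combined with \code{EV}.
#' @param EV empirical class values used when \code{vulnerability} is an MN
#'   vector; default [empiricalVulnerability()].
#' @return Named numeric vector of LERI values, names = cell ids.
#' @export
leriIndex <- function(metrics, vulnerability, EV = empiricalVulnerability()) {
  if (any(metrics$cell_area_km2 <= 0)) stop("cell areas must be > 0")
  if (is.null(dim(vulnerability)))
    vulnerability <- vulnerabilityIndex(vulnerability, EV)
  cid <- as.character(metrics$cell_id)
  if (is.null(rownames(vulnerability)))
    stop("vulnerability matrix must carry cell ids as rownames")
  Fki <- vulnerability[cbind(match(cid, rownames(vulnerability)),
                             match(metrics$class, names(landClasses())))]
  if (anyNA(Fki)) stop("vulnerability missing for some cell/class pairs")
  term <- metrics$E * Fki * metrics$area_km2 / metrics$cell_area_km2
  out <- tapply(term, factor(cid, levels = unique(cid)), sum)
  setNames(as.numeric(out), names(out))
}

#' Risk classification scheme
#'
#' Ordered break values separating five risk levels. The default fixed
#' breaks are 0.60, 1.18, 1.72, 2.40, giving: low (< 0.60), medium-low
#' [0.60, 1.18), medium [1.18, 1.72), medium-high [1.72, 2.40) and high
#' (>= 2.40). Intervals are left-closed/right-open; the top class is closed
#' below at the last break.
#'
#' @param breaks strictly increasing numeric vector (length = classes - 1).
#' @param method "fixed" or "jenks" (provenance tag only).
#' @return A \code{classificationScheme} list.
#' @export
classificationScheme <- function(breaks = c(0.60, 1.18, 1.72, 2.40),
                                 method = "fixed") {
  if (any(diff(breaks) <= 0)) stop("breaks must be strictly increasing")
  structure(list(breaks = breaks, method = method,
                 nClasses = length(breaks) + 1L),
            class = "classificationScheme")
}

#' Risk level labels
#' @param n number of classes (5 gives the standard label set).
#' @return Character vector of ordered level names.
#' @export
riskLevels <- function(n = 5L) {
  if (n == 5L) c("low", "medium-low", "medium", "medium-high", "high")
  else paste0("class", seq_len(n))
}

#' Classify LERI values into risk levels
#'
#' @param values non-negative LERI values.
#' @param scheme a [classificationScheme()].
#' @return Ordered factor of risk levels.
#' @export
#' @examples
#' classifyRisk(c(0.5999, 0.60, 1.3443, 2.40))
classifyRisk <- function(values, scheme = classificationScheme()) {
  if (!inherits(scheme, "classificationScheme")) stop("invalid scheme")
  if (any(values < 0, na.rm = TRUE)) stop("LERI values must be >= 0")
  lev <- riskLevels(scheme$nClasses)
  idx <- findInterval(values, scheme$breaks, left.open = FALSE) + 1L
  factor(lev[idx], levels = lev, ordered = TRUE)
}

#' Jenks natural breaks
#'
#' Optimal one-dimensional classification by Fisher's dynamic program:
#' minimizes the total within-class sum of squared deviations over all
#' partitions of the sorted values into \code{nClasses} contiguous groups.
#' Returned break values are the minima of classes 2..n, so
#' [classifyRisk()]'s left-closed convention reproduces the optimal
#' partition exactly.
#'
#' @param values numeric vector with at least \code{nClasses} distinct values.
#' @param nClasses number of classes (default 5).
#' @return A [classificationScheme()] with method "jenks".
#' @export
#' @examples
#' jenksBreaks(c(1, 2, 3, 10, 11, 12), 2)$breaks  # 10
jenksBreaks <- function(values, nClasses = 5L) {
  x <- sort(values[is.finite(values)])
  n <- length(x)
  if (length(unique(x)) < nClasses)
    stop("need at least ", nClasses, " distinct values")
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  sse <- function(i, j) {
    # within-class SSE of x[i..j], vectorized over i
    s <- cs[j] - c(0, cs)[i]
    q <- cs2[j] - c(0, cs2)[i]
    q - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, nClasses, n)
  B <- matrix(1L, nClasses, n)
  D[1, ] <- vapply(seq_len(n), function(j) sse(1, j), numeric(1))
  for (m in 2:nClasses) {
    for (j in m:n) {
      i <- m:j  # first index of the last class
      tot <- D[m - 1, i - 1] + sse(i, j)
      best <- which.min(tot)
      D[m, j] <- tot[best]
      B[m, j] <- i[best]
    }
  }
  starts <- integer(nClasses)
  j <- n
  for (m in nClasses:1) {
    starts[m] <- B[m, j]
    j <- starts[m] - 1L
  }
  classificationScheme(breaks = x[starts[-1]], method = "jenks")
}

#' Risk rate of change (RRC)
#'
#' Annualized percentage change of LERI relative to its initial value:
#' \eqn{RRC = \frac{LERI_{T2}-LERI_{T1}}{LERI_{T1}}\cdot\frac{1}{\Delta T}
#' \cdot 100}. Negative values mean the risk decreased. Cells with zero
#' initial LERI are undefined and returned as \code{NA} with a warning.
#'
#' @param leri1,leri2 LERI at the start and end of the window.
#' @param deltaT window length in years (> 0).
#' @return RRC in percent per year.
#' @export
#' @examples
#' riskRateOfChange(1.0, 0.8, 5)  # -4
riskRateOfChange <- function(leri1, leri2, deltaT) {
  if (deltaT <= 0) stop("deltaT must be > 0")
  undef <- leri1 <= 0
  if (any(undef)) warning(sum(undef), " cell(s) have LERI_T1 = 0; RRC is NA")
  out <- (leri2 - leri1) / leri1 / deltaT * 100
  out[undef] <- NA_real_
  out
}

#' Coefficient of variation of a LERI series
#'
#' Per-cell temporal stability: sample standard deviation (n - 1 divisor)
#' over mean of the cell's LERI time series. Larger CV = less stable risk.
#'
#' @param series numeric vector (one cell) or matrix (cells x time points).
#' @return CV per cell; NA with a warning where the mean is <= 0.
#' @export
coefficientOfVariation <- function(series) {
  if (is.null(dim(series))) series <- matrix(series, nrow = 1)
  if (ncol(series) < 2L) stop("need a series of length >= 2")
  mu <- rowMeans(series)
  s <- apply(series, 1L, sd)
  undef <- mu <= 0
  if (any(undef)) warning(sum(undef), " cell(s) have mean LERI <= 0; CV is NA")
  out <- s / mu
  out[undef] <- NA_real_
  out
}

#' Attach temporal statistics to a RiskPanel
#'
#' Computes full-period RRC, per-window RRC and CV from the panel's LERI
#' assay and stores them in \code{rowData}. Column names must be coercible
#' to years; windows are consecutive column pairs.
#'
#' @param panel a [RiskPanel-class] with >= 2 time points.
#' @return The panel with \code{RRC}, \code{CV} and per-window RRC columns.
#' @export
addTemporalStats <- function(panel) {
  L <- leriValues(panel)
  if (ncol(L) < 2L) stop("temporal statistics need >= 2 time points")
  years <- suppressWarnings(as.numeric(gsub("[^0-9.]", "", colnames(L))))
  if (anyNA(years)) years <- seq_len(ncol(L))
  rd <- SummarizedExperiment::rowData(panel)
  rd$RRC <- riskRateOfChange(L[, 1], L[, ncol(L)],
                             years[ncol(L)] - years[1])
  for (w in seq_len(ncol(L) - 1L)) {
    nm <- paste0("RRC_", colnames(L)[w], "_", colnames(L)[w + 1L])
    rd[[nm]] <- riskRateOfChange(L[, w], L[, w + 1L], years[w + 1L] - years[w])
  }
  rd$CV <- coefficientOfVariation(L)
  SummarizedExperiment::rowData(panel) <- rd
  panel
}

#' @describeIn RiskPanel display summary
#' @param object a RiskPanel
#' @export
setMethod("show", "RiskPanel", function(object) {
  L <- leriValues(object)
  cat(sprintf("RiskPanel: %d cells x %d time points (%s)\n",
              nrow(L), ncol(L), paste(colnames(L), collapse = ", ")))
  cat("mean LERI per period:",
      paste(sprintf("%.4f", colMeans(L)), collapse = ", "), "\n")
  extras <- setdiff(colnames(SummarizedExperiment::rowData(object)),
                    "area_km2")
  if (length(extras)) cat("rowData statistics:", paste(extras, collapse = ", "), "\n")
})
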