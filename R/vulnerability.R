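# Dynamic landscape vulnerability: empirical class ranks (EV_i) modulated by
# a per-cell composite adjustment factor MN_k built from entropy-weighted,
# min-max standardized environmental indicators:
#   EQ_k = sum_j w_j m_jk,  MN_k = EQ_k / mean_k(EQ),  F_ki = EV_i * MN_k.
# MN has grid mean 1 by construction, so the adjustment redistributes
# vulnerability across space without inflating its average level.

#' Min-max standardization of the indicator matrix
#'
#' Rescales each indicator column to [0,1]; negatively oriented indicators
#' (larger value = lower vulnerability) are reflected, so m = 1 corresponds
#' to the most vulnerable cell in every column. A constant column carries no
#' information and is set to 0.5 with a warning.
#'
#' @param raw numeric matrix, cells x indicators (>= 2 rows, finite).
#' @param orientations +1/-1 per column; default [defaultOrientations()]
#'   matched by column name.
#' @return Matrix of standardized values m_jk in [0,1].
#' @export
#' @examples
#' standardizeIndicators(cbind(GDP = c(0, 5, 10)), orientations = c(GDP = 1))
standardizeIndicators <- function(raw, orientations = defaultOrientations()) {
  raw <- as.matrix(raw)
  if (nrow(raw) < 2L) stop("need at least 2 cells to standardize")
  if (any(!is.finite(raw))) stop("indicator values must be finite")
  if (is.null(colnames(raw))) colnames(raw) <- names(orientations)[seq_len(ncol(raw))]
  out <- raw
  for (j in seq_len(ncol(raw))) {
    x <- raw[, j]
    rng <- range(x)
    o <- orientations[[colnames(raw)[j]]]
    if (is.null(o) || is.na(o)) stop("no orientation for column ", colnames(raw)[j])
    if (rng[2] == rng[1]) {
      warning("indicator '", colnames(raw)[j],
              "' is constant; standardized to 0.5")
      out[, j] <- 0.5
    } else if (o > 0) {
      out[, j] <- (x - rng[1]) / (rng[2] - rng[1])
    } else {
      out[, j] <- (rng[2] - x) / (rng[2] - rng[1])
    }
  }
  out
}

#' Entropy weights of the indicators
#'
#' Shannon-entropy weighting over cells: \eqn{p_{jk} = m_{jk}/\sum_k m_{jk}},
#' \eqn{e_j = -\frac{1}{\ln K}\sum_k p_{jk}\ln p_{jk}} (with 0 ln 0 = 0), and
#' \eqn{w_j = (1-e_j)/\sum_j (1-e_j)}. Indicators that differentiate cells
#' more strongly receive more weight; weights sum to 1.
#'
#' @param m standardized matrix from [standardizeIndicators()].
#' @return Named weight vector summing to 1.
#' @export
entropyWeights <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 cells")
  if (any(m < 0) || any(m > 1)) stop("standardized values must lie in [0, 1]")
  colsum <- colSums(m)
  if (any(colsum <= 0))
    stop("all-zero indicator column(s): ",
         paste(colnames(m)[colsum <= 0], collapse = ", "))
  K <- nrow(m)
  e <- vapply(seq_len(ncol(m)), function(j) {
    p <- m[, j] / colsum[j]
    p <- p[p > 0]
    -sum(p * log(p)) / log(K)
  }, numeric(1))
  d <- 1 - e
  if (sum(d) <= 0) {
    # every column perfectly uniform: fall back to equal weights
    w <- rep(1 / ncol(m), ncol(m))
  } else {
    w <- d / sum(d)
  }
  setNames(w, colnames(m))
}

#' Weighted indicator sum EQ_k
#'
#' @param m standardized cells x indicators matrix.
#' @param w weights (fixed or entropy-derived), matched by name when named.
#' @return Per-cell composite EQ_k in [0,1] for normalized weights.
#' @export
indicatorSum <- function(m, w) {
  m <- as.matrix(m)
  if (!is.null(names(w)) && !is.null(colnames(m))) w <- w[colnames(m)]
  if (length(w) != ncol(m)) stop("weight length must match indicator count")
  drop(m %*% w)
}

#' Composite adjustment factor MN_k
#'
#' Normalizes EQ by its grid mean: \eqn{MN_k = EQ_k/\overline{EQ}}, so
#' \code{mean(MN) == 1}. Computed per time point when indicators vary over
#' time, which is what makes the vulnerability dynamic.
#'
#' @param EQ per-cell weighted indicator sums.
#' @return Per-cell adjustment factors with mean exactly 1.
#' @export
adjustmentFactor <- function(EQ) {
  mu <- mean(EQ)
  if (!is.finite(mu) || mu <= 0) stop("mean(EQ) must be > 0")
  EQ / mu
}

#' Landscape vulnerability index F_ki
#'
#' \eqn{F_{ki} = EV_i \times MN_k}: the empirical class rank scaled by the
#' cell's composite adjustment factor. With MN = 1 (neutral adjustment) the
#' classic static vulnerability is recovered.
#'
#' @param MN per-cell adjustment factors.
#' @param EV empirical values per class; default [empiricalVulnerability()].
#' @return Matrix cells x 6 classes of F_ki.
#' @export
vulnerabilityIndex <- function(MN, EV = empiricalVulnerability()) {
  if (!all(names(landClasses()) %in% names(EV)))
    stop("EV must name all six land-cover classes")
  EV <- EV[names(landClasses())]
  outer(MN, EV)
}

#' Full vulnerability pipeline for one time point
#'
#' Convenience wrapper: standardize raw zonal indicator means, derive
#' weights (fixed published set or entropy method), and return EQ, MN and
#' the per-class vulnerability matrix.
#'
#' @param raw cells x 8 matrix of raw zonal means ([zonalIndicatorMeans()]).
#' @param weightMode "fixed" (published weight set) or "entropy".
#' @param orientations indicator orientations; default [defaultOrientations()].
#' @param EV empirical class values; default [empiricalVulnerability()].
#' @return List with m, w, EQ, MN, F (cells x classes).
#' @export
computeVulnerability <- function(raw, weightMode = c("fixed", "entropy"),
                                 orientations = defaultOrientations(),
                                 EV = empiricalVulnerability()) {
  weightMode <- match.arg(weightMode)
  m <- standardizeIndicators(raw, orientations)
  w <- if (weightMode == "fixed") fixedIndicatorWeights() else entropyWeights(m)
  EQ <- indicatorSum(m, w)
  MN <- adjustmentFactor(EQ)
  list(m = m, w = w, EQ = EQ, MN = MN, F = vulnerabilityIndex(MN, EV))
}
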