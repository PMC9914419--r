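# Neutral-landscape synthesis: modified random clusters for categorical
# land cover, smoothed Gaussian fields for indicators, and a frontier-growth
# urbanization process for multi-year change sequences.

#' Synthetic-landscape configuration
#'
#' Bundles the knobs of the synthetic-data generators. Proportions are the
#' target class area shares (legend order of [landClasses()]); clumping in
#' [0,1] controls spatial aggregation (0 = independent pixels, 1 = few large
#' patches); \code{corLength} is the Gaussian smoothing length of the
#' indicator fields in pixels; \code{urbanRate} is the fraction of
#' urban-adjacent cropland converted per step.
#'
#' @param seed integer RNG seed used by all three generators.
#' @param proportions numeric length 6, non-negative, summing to 1.
#' @param clumping numeric in [0,1].
#' @param corLength positive smoothing length (pixels).
#' @param urbanRate numeric in [0,1].
#' @param steps number of change steps for [evolveLandcover()].
#' @return A validated list of class \code{synthConfig}.
#' @export
#' @examples
#' cfg <- synthConfig(seed = 1, clumping = 0.5)
synthConfig <- function(seed = 1L,
                        proportions = c(0.30, 0.15, 0.30, 0.05, 0.10, 0.10),
                        clumping = 0.5, corLength = 8, urbanRate = 0.10,
                        steps = 4L) {
  if (length(proportions) != 6L || any(proportions < 0) || any(!is.finite(proportions)))
    stop("proportions must be 6 non-negative finite numbers")
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("proportions must sum to 1 (got ", format(sum(proportions)), ")")
  if (clumping < 0 || clumping > 1) stop("clumping must be in [0, 1]")
  if (corLength <= 0) stop("corLength must be > 0")
  if (urbanRate < 0 || urbanRate > 1) stop("urbanRate must be in [0, 1]")
  structure(list(seed = as.integer(seed),
                 proportions = setNames(proportions, names(landClasses())),
                 clumping = clumping, corLength = corLength,
                 urbanRate = urbanRate, steps = as.integer(steps)),
            class = "synthConfig")
}

# resolve extent/resolution into pixel dimensions; res must divide extent
extentDims <- function(extent, res) {
  w <- extent[3] - extent[1]; h <- extent[4] - extent[2]
  if (w <= 0 || h <= 0) stop("degenerate extent")
  nc <- w / res; nr <- h / res
  if (abs(nc - round(nc)) > 1e-6 || abs(nr - round(nr)) > 1e-6)
    stop("resolution must divide the extent edge lengths")
  c(nr = as.integer(round(nr)), nc = as.integer(round(nc)))
}

#' Generate a synthetic land-cover map
#'
#' Modified-random-clusters neutral landscape: a Bernoulli percolation map
#' at probability proportional to \code{clumping} is labelled into 4-connected
#' clusters; each cluster draws one class from the target proportions; the
#' remaining pixels are filled by iterative majority vote of their assigned
#' 8-neighbours (isolated remainders draw independently). At clumping 0 every
#' pixel is an independent draw.
#'
#' @param config a [synthConfig()].
#' @param extent numeric c(xmin, ymin, xmax, ymax) in km.
#' @param res pixel edge (km); must divide both extent edges.
#' @return A [LandCoverMap-class].
#' @export
#' @examples
#' m <- generateLandcover(synthConfig(seed = 7), c(0, 0, 40, 40), 1)
generateLandcover <- function(config, extent = c(0, 0, 100, 100), res = 1) {
  stopifnot(inherits(config, "synthConfig"))
  d <- extentDims(extent, res)
  set.seed(config$seed)
  codes <- mrcLandcover(d["nr"], d["nc"], config$proportions, config$clumping)
  LandCoverMap(codes, xmin = extent[1], ymin = extent[2], res = res)
}

# core MRC draw on an nr x nc lattice (uses the current RNG stream)
mrcLandcover <- function(nr, nc, proportions, clumping) {
  n <- nr * nc
  # keep the percolation probability below the 4-neighbour threshold (~0.593)
  p <- 0.58 * clumping
  codes <- matrix(NA_integer_, nr, nc)
  if (p > 0) {
    marked <- matrix(runif(n) < p, nr, nc)
    if (any(marked)) {
      lab <- labelComponents(marked, connectivity = 4L)
      nclust <- max(lab)
      clustClass <- sample.int(6L, nclust, replace = TRUE, prob = proportions)
      codes[marked] <- clustClass[lab[marked]]
    }
  }
  # single majority-fill pass: unassigned pixels take the modal class of
  # their cluster-assigned 8-neighbours (random tie-break); pixels with no
  # assigned neighbour draw independently by proportion
  if (anyNA(codes)) {
    counts <- array(0L, dim = c(nr, nc, 6L))
    for (o in neighborOffsets(8L)) {
      s <- shiftMatrix(codes, o[1], o[2], fill = NA_integer_)
      for (cl in 1:6) counts[, , cl] <- counts[, , cl] + (!is.na(s) & s == cl)
    }
    tot <- rowSums(counts, dims = 2L)
    fillable <- is.na(codes) & tot > 0L
    if (any(fillable)) {
      idx <- which(fillable)
      cnt <- matrix(counts, ncol = 6L)[idx, , drop = FALSE]
      jitter <- matrix(runif(length(cnt)), nrow(cnt), 6L) * 0.5
      codes[idx] <- max.col(cnt + jitter)
    }
    rest <- is.na(codes)
    if (any(rest))
      codes[rest] <- sample.int(6L, sum(rest), TRUE, prob = proportions)
  }
  codes
}

#' Generate synthetic indicator surfaces
#'
#' Draws eight spatially autocorrelated random fields (white noise smoothed
#' with a separable Gaussian kernel of standard deviation \code{corLength}
#' pixels, then rescaled to an indicator-specific location and spread).
#' Larger \code{corLength} yields smoother surfaces.
#'
#' @inheritParams generateLandcover
#' @return An [IndicatorStack-class] of 8 surfaces named [indicatorNames()].
#' @export
generateIndicators <- function(config, extent = c(0, 0, 100, 100), res = 1) {
  stopifnot(inherits(config, "synthConfig"))
  if (config$corLength <= 0) stop("corLength must be > 0")
  d <- extentDims(extent, res)
  set.seed(config$seed + 1L)
  # plausible location/spread per indicator (units as commonly mapped:
  # 1e4 yuan/km2, persons/km2, m, %, degC, mm, gC/m2, unitless)
  loc <- c(GDP = 500, population = 200, elevation = 1500, slope = 10,
           temperature = 8, precipitation = 450, NPP = 300, NDVI = 0.5)
  spread <- c(GDP = 300, population = 150, elevation = 800, slope = 6,
              temperature = 5, precipitation = 180, NPP = 120, NDVI = 0.15)
  surfaces <- lapply(indicatorNames(), function(nm) {
    f <- gaussianField(d["nr"], d["nc"], config$corLength)
    loc[[nm]] + spread[[nm]] * f
  })
  names(surfaces) <- indicatorNames()
  IndicatorStack(surfaces, xmin = extent[1], ymin = extent[2], res = res)
}

# standardized (mean 0, sd 1) smoothed Gaussian random field
gaussianField <- function(nr, nc, corLength) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  half <- max(1L, ceiling(3 * corLength))
  k <- exp(-((-half):half)^2 / (2 * corLength^2))
  k <- k / sum(k)
  z <- convolveRows(z, k)             # smooth along rows
  z <- t(convolveRows(t(z), k))       # then along columns
  (z - mean(z)) / max(sd(z), .Machine$double.eps)
}

# 1-D convolution along each row with edge renormalization
convolveRows <- function(m, k) {
  half <- (length(k) - 1L) %/% 2L
  nc <- ncol(m)
  out <- matrix(0, nrow(m), nc)
  wsum <- numeric(nc)
  for (j in seq_along(k)) {
    off <- j - half - 1L
    src <- seq_len(nc) + off
    ok <- src >= 1L & src <= nc
    out[, ok] <- out[, ok] + k[j] * m[, src[ok], drop = FALSE]
    wsum[ok] <- wsum[ok] + k[j]
  }
  sweep(out, 2L, wsum, "/")
}

#' Simulate urban growth on a land-cover map
#'
#' At each step the conversion frontier is the set of cropland pixels
#' 4-adjacent to existing urban pixels; a fraction \code{urbanRate} of the
#' frontier (rounded, sampled without replacement) converts to urban land.
#' Urban area is therefore non-decreasing. A map with no urban pixels has an
#' empty frontier and is returned unchanged.
#'
#' @param map a [LandCoverMap-class].
#' @param config a [synthConfig()]; uses \code{urbanRate} and \code{seed}.
#' @param steps number of steps (default \code{config$steps}).
#' @return List of \code{steps + 1} maps, the input first.
#' @export
evolveLandcover <- function(map, config, steps = config$steps) {
  stopifnot(is(map, "LandCoverMap"), inherits(config, "synthConfig"))
  rate <- config$urbanRate
  if (rate < 0 || rate > 1) stop("urbanRate must be in [0, 1]")
  set.seed(config$seed + 2L)
  urbanCode <- landClasses()[["urban"]]
  cropCode <- landClasses()[["cropland"]]
  out <- vector("list", steps + 1L)
  out[[1L]] <- map
  codes <- map@codes
  for (s in seq_len(steps)) {
    if (rate > 0) {
      urban <- !is.na(codes) & codes == urbanCode
      nearUrban <- Reduce(`|`, lapply(neighborOffsets(4L), function(o)
        shiftMatrix(urban, o[1], o[2], fill = FALSE)))
      frontier <- which(!is.na(codes) & codes == cropCode & nearUrban)
      nConv <- round(rate * length(frontier))
      if (nConv > 0) {
        conv <- if (nConv >= length(frontier)) frontier else
          frontier[sample.int(length(frontier), nConv)]
        codes[conv] <- urbanCode
      }
    }
    out[[s + 1L]] <- LandCoverMap(codes, map@xmin, map@ymin, map@res)
  }
  out
}
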