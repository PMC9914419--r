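# Independent oracles used to cross-check the implementation.

# patch counting by explicit breadth-first flood fill (no shared code with
# labelComponents, which uses minimum-label propagation)
floodFillCount <- function(window, class, connectivity = 8L) {
  mask <- !is.na(window) & window == class
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  offs <- if (connectivity == 4L)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  count <- 0L
  for (start in which(mask)) {
    if (seen[start]) next
    count <- count + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      r <- (cur - 1L) %% nr + 1L
      cc <- (cur - 1L) %/% nr + 1L
      for (o in offs) {
        r2 <- r + o[1]; c2 <- cc + o[2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
          idx <- (c2 - 1L) * nr + r2
          if (mask[idx] && !seen[idx]) {
            seen[idx] <- TRUE
            queue <- c(queue, idx)
          }
        }
      }
    }
  }
  count
}

# exhaustive optimal 1-D partition: tries every placement of class
# boundaries over the sorted values and minimizes total within-class SSE
jenksOracle <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  sse <- function(v) sum((v - mean(v))^2)
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf; bestBreaks <- NULL
  for (j in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, j], n)
    tot <- sum(vapply(seq_len(k), function(m)
      sse(x[(b[m] + 1):b[m + 1]]), numeric(1)))
    if (tot < best - 1e-12) {
      best <- tot
      bestBreaks <- x[cuts[, j] + 1]  # minimum of classes 2..k
    }
  }
  list(breaks = bestBreaks, sse = best)
}

# term-by-term LERI re-evaluation from a long metrics table and an F matrix
bruteLERI <- function(metrics, Fmat) {
  ids <- unique(metrics$cell_id)
  out <- numeric(length(ids))
  for (z in seq_along(ids)) {
    rows <- metrics[metrics$cell_id == ids[z], ]
    acc <- 0
    for (r in seq_len(nrow(rows))) {
      Fki <- Fmat[as.character(ids[z]), rows$class[r]]
      acc <- acc + rows$E[r] * Fki * rows$area_km2[r] / rows$cell_area_km2[r]
    }
    out[z] <- acc
  }
  setNames(out, ids)
}

# quick deterministic toy landscape: nr x nc codes drawn iid by proportion
randomToyMap <- function(nr, nc, seed, prop = rep(1 / 6, 6)) {
  set.seed(seed)
  LandCoverMap(matrix(sample.int(6L, nr * nc, TRUE, prob = prop), nr, nc))
}
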