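# Land-use transfer matrices between two dates.

#' Land-use transfer matrix
#'
#' Cross-tabulates pixel class pairs between two co-registered maps and
#' scales counts by the pixel area: \code{T[i, j]} is the area (km^2) that
#' was class i at the first date and class j at the second. Only pixels
#' valid at both dates enter, so row sums equal the first date's class
#' areas, column sums the second's, and the grand total the common valid
#' area — exactly.
#'
#' @param map1,map2 [LandCoverMap-class] objects sharing one registry.
#' @return 6 x 6 numeric matrix with class-name dimnames (from, to) and
#'   attribute \code{pixel_area_km2}.
#' @export
#' @examples
#' m <- LandCoverMap(matrix(c(1L, 5L, 1L, 4L), 2, 2))
#' transferMatrix(m, m)  # diagonal
transferMatrix <- function(map1, map2) {
  stopifnot(is(map1, "LandCoverMap"), is(map2, "LandCoverMap"))
  if (!sameRegistry(map1, map2)) stop(registryDiff(map1, map2))
  ok <- !is.na(map1@codes) & !is.na(map2@codes)
  tab <- table(from = factor(map1@codes[ok], levels = 1:6),
               to = factor(map2@codes[ok], levels = 1:6))
  out <- unclass(tab) * map1@res^2
  dimnames(out) <- list(from = names(landClasses()), to = names(landClasses()))
  attr(out, "pixel_area_km2") <- map1@res^2
  out
}

#' Net and gross class changes from a transfer matrix
#'
#' @param T a matrix from [transferMatrix()].
#' @return data.frame per class: area at both dates, gross gain (area gained
#'   from other classes), gross loss, and net change (gain - loss, km^2).
#'   Net changes sum to zero.
#' @export
netChange <- function(T) {
  stopifnot(is.matrix(T), all(dim(T) == c(6L, 6L)))
  a1 <- rowSums(T); a2 <- colSums(T)
  gain <- a2 - diag(T); loss <- a1 - diag(T)
  data.frame(class = names(landClasses()),
             area_t1_km2 = as.numeric(a1), area_t2_km2 = as.numeric(a2),
             gross_gain_km2 = as.numeric(gain),
             gross_loss_km2 = as.numeric(loss),
             net_km2 = as.numeric(a2 - a1), row.names = NULL)
}

#' Long-format view of a transfer matrix
#'
#' @param T a matrix from [transferMatrix()].
#' @param dropZero drop zero-area transitions (default TRUE).
#' @return data.frame (from, to, area_km2).
#' @export
transferLong <- function(T, dropZero = TRUE) {
  df <- data.frame(from = rep(rownames(T), times = 6),
                   to = rep(colnames(T), each = 6),
                   area_km2 = as.numeric(T))
  if (dropZero) df <- df[df$area_km2 > 0, , drop = FALSE]
  rownames(df) <- NULL
  df
}
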