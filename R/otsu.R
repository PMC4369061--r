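#' Otsu's automatic threshold
#'
#' Picks the intensity threshold that minimizes the combined within-class
#' variance of the background (values `<= t`) and foreground (values `> t`)
#' over the 256-bin histogram of an 8-bit channel. Ties are broken toward the
#' smaller threshold, so the result is reproducible on flat-variance plateaus.
#'
#' @param channel numeric matrix or vector of intensities in \[0, 255\];
#'   values are binned to integers.
#' @return list with `threshold` (integer in 0..255) and `degenerate`
#'   (`TRUE` when the image is constant, in which case the threshold equals
#'   the constant value and no separation is possible).
#' @examples
#' otsu_threshold(c(rep(10, 50), rep(200, 50)))$threshold  # 10
#' @export
otsu_threshold <- function(channel) {
  x <- as.vector(channel)
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("channel is empty")
  if (min(x) < 0 || max(x) > 255) stop("intensities must lie in [0, 255]")
  b <- pmin(pmax(as.integer(round(x)), 0L), 255L)
  if (all(b == b[1]))
    return(list(threshold = b[1], degenerate = TRUE))
  counts <- tabulate(b + 1L, nbins = 256L)
  n <- length(b)
  lev <- 0:255
  p <- counts / n
  w0 <- cumsum(p)                       # weight of class "<= t"
  mu <- cumsum(p * lev)                 # partial first moment
  m2 <- cumsum(p * lev^2)               # partial second moment
  muT <- mu[256]; m2T <- m2[256]
  w1 <- 1 - w0
  # within-class variance w0*var0 + w1*var1, guarding empty classes
  var0 <- ifelse(w0 > 0, m2 / w0 - (mu / w0)^2, 0)
  var1 <- ifelse(w1 > 0, (m2T - m2) / w1 - ((muT - mu) / w1)^2, 0)
  wcv <- w0 * var0 + w1 * var1
  t <- which.min(wcv) - 1L              # which.min takes the first minimum
  list(threshold = t, degenerate = FALSE)
}
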