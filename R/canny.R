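#' Canny edge detection
#'
#' Classic Canny edge tracking: Gaussian smoothing, Sobel gradients,
#' non-maximum suppression along the quantized gradient direction, and
#' double-threshold hysteresis (weak edge pixels are kept only when their
#' 8-connected component contains a strong pixel). The detector focuses on
#' exactly the structures hue thresholding loses — contours of offshoots one
#' or two pixels thick — and returns a thin (about 1 px) edge mask.
#'
#' @param gray numeric matrix of intensities in \[0, 255\].
#' @param low,high hysteresis thresholds on Sobel gradient magnitude
#'   (same intensity units as `gray`); `low <= high`.
#' @param sigma standard deviation (px) of the Gaussian smoothing; 0 skips
#'   smoothing, which preserves single-pixel lines best.
#' @return logical matrix of edge pixels.
#' @export
canny_edges <- function(gray, low = 20, high = 50, sigma = 1) {
  stopifnot(is.matrix(gray), low <= high, sigma >= 0)
  g <- gray
  if (sigma > 0)
    g <- EBImage::imageData(EBImage::gblur(EBImage::Image(g), sigma = sigma,
                                           boundary = "replicate"))
  # Sobel gradients via shifted matrices (replicated borders):
  # gx along columns, gy along rows
  s <- function(dr, dc) shift_mat(g, dr, dc)
  gx <- (s(-1, 1) + 2 * s(0, 1) + s(1, 1)) - (s(-1, -1) + 2 * s(0, -1) + s(1, -1))
  gy <- (s(1, -1) + 2 * s(1, 0) + s(1, 1)) - (s(-1, -1) + 2 * s(-1, 0) + s(-1, 1))
  mag <- sqrt(gx^2 + gy^2)

  # quantize gradient direction to 4 sectors on [0, pi)
  theta <- atan2(gy, gx) %% pi
  sector <- as.integer(floor((theta + pi / 8) / (pi / 4))) %% 4L
  dirs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  n1 <- matrix(0, nrow(g), ncol(g)); n2 <- n1
  for (k in 0:3) {
    d <- dirs[[k + 1]]
    sel <- sector == k
    if (!any(sel)) next
    fwd <- shift_mat(mag, d[1], d[2]); bwd <- shift_mat(mag, -d[1], -d[2])
    n1[sel] <- fwd[sel]; n2[sel] <- bwd[sel]
  }
  ridge <- mag >= n1 & mag >= n2 & mag > 0

  weak <- ridge & mag >= low
  strong <- ridge & mag >= high
  if (!any(strong)) return(matrix(FALSE, nrow(g), ncol(g)))
  lab <- label_components(weak, connectivity = 8)
  keep <- unique(lab[strong])
  lab > 0L & matrix(lab %in% keep, nrow(lab), ncol(lab))
}
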