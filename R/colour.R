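#' Convert an RGB raster to HSV channels
#'
#' Converts an 8-bit RGB image (values in \[0, 255\]) into hue, saturation and
#' value channels using the standard hexcone model. Hue is returned in degrees
#' on \[0, 360); achromatic pixels (R = G = B) get hue 0 by convention and
#' saturation 0.
#'
#' Plant/background discrimination is far easier in hue than in RGB: the
#' "plant green" region of RGB space collapses to a line segment on the hue
#' circle, so saturation and value can be ignored during thresholding.
#'
#' @param img numeric array `height x width x 3` with values in \[0, 255\],
#'   or a `height x width` matrix (treated as grayscale, hue 0).
#' @return list with matrices `h` (degrees, \[0, 360)), `s` and `v` (\[0, 1\]),
#'   class `"hsv_image"`.
#' @examples
#' px <- array(c(255, 0, 0), dim = c(1, 1, 3))
#' rgb_to_hsv_image(px)$h  # 0 degrees (red)
#' @export
rgb_to_hsv_image <- function(img) {
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  if (min(img) < 0 || max(img) > 255)
    stop("RGB values must lie in [0, 255]")
  d <- dim(img)[1:2]
  hsv <- grDevices::rgb2hsv(
    r = as.vector(img[, , 1]),
    g = as.vector(img[, , 2]),
    b = as.vector(img[, , 3]),
    maxColorValue = 255
  )
  out <- list(
    h = matrix(hsv[1, ] * 360, d[1], d[2]),
    s = matrix(hsv[2, ], d[1], d[2]),
    v = matrix(hsv[3, ], d[1], d[2])
  )
  class(out) <- "hsv_image"
  out
}

#' Threshold an image by a hue interval
#'
#' Marks a pixel as foreground iff its hue lies on the arc running from
#' `low_deg` to `high_deg` (wrap-around across 0 allowed, e.g. a red interval
#' `c(350, 10)`). Saturation and value are ignored, except that achromatic
#' pixels (saturation 0) are always background because their hue is undefined.
#'
#' @param hsv an `"hsv_image"` as returned by [rgb_to_hsv_image()].
#' @param interval numeric length-2, `c(low_deg, high_deg)` in \[0, 360).
#' @return logical matrix, the foreground mask.
#' @export
hue_threshold <- function(hsv, interval = c(80, 160)) {
  stopifnot(inherits(hsv, "hsv_image"), length(interval) == 2L)
  if (any(interval < 0) || any(interval >= 360))
    stop("hue interval bounds must lie in [0, 360)")
  lo <- interval[1]; hi <- interval[2]
  h <- hsv$h
  inside <- if (lo <= hi) h >= lo & h <= hi else h >= lo | h <= hi
  inside & hsv$s > 0
}
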