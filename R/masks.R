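#' Segmentation parameter set
#'
#' Collects every tunable of the green-mask pipeline. The defaults reflect
#' the pipeline's purpose of keeping 1-2 px tendrils: no median filtering or
#' morphological opening by default (a 3x3 median or opening erases a
#' single-pixel line), with small-component removal doing the speckle
#' clean-up instead.
#'
#' @param hue_interval foreground hue arc in degrees, default `c(80, 160)`
#'   ("plant green"); wrap-around allowed.
#' @param use_otsu if `TRUE`, threshold the hue channel with [otsu_threshold()]
#'   (foreground = hue above the threshold) instead of the fixed interval.
#' @param canny_low,canny_high hysteresis thresholds on gradient magnitude.
#' @param canny_sigma Gaussian smoothing scale (px) before edge detection.
#' @param median_radius median-filter half-width (px); 0 skips.
#' @param morph_close_radius,morph_open_radius radii (px) of the disc
#'   structuring elements for closing/opening; 0 skips.
#' @param min_component_px connected components smaller than this are dropped.
#' @param edge_close_radius radius (px) of the closing applied to the raw
#'   Canny mask before fusion. The Canny ridge of a 1-2 px structure sits on
#'   its two flanking contours; closing by 1 px fills the gap between them so
#'   the structure's own pixels enter the fused mask.
#' @param edge_hue_margin_deg edge pixels are admitted to the fusion only if
#'   their hue lies within the foreground interval widened by this margin on
#'   each side. This rejects the pure-background side of object contours
#'   (which would otherwise halo the mask) while keeping tendril pixels whose
#'   hue was dragged toward the background by partial pixel coverage.
#' @return list of class `"segmentation_params"`.
#' @export
segmentation_params <- function(hue_interval = c(80, 160),
                                use_otsu = FALSE,
                                canny_low = 15, canny_high = 35,
                                canny_sigma = 1,
                                median_radius = 0,
                                morph_close_radius = 0,
                                morph_open_radius = 0,
                                min_component_px = 8,
                                edge_close_radius = 1,
                                edge_hue_margin_deg = 30) {
  stopifnot(length(hue_interval) == 2, canny_low <= canny_high,
            median_radius >= 0, morph_close_radius >= 0,
            morph_open_radius >= 0, min_component_px >= 0,
            edge_close_radius >= 0, edge_hue_margin_deg >= 0)
  structure(list(hue_interval = hue_interval, use_otsu = isTRUE(use_otsu),
                 canny_low = canny_low, canny_high = canny_high,
                 canny_sigma = canny_sigma, median_radius = median_radius,
                 morph_close_radius = morph_close_radius,
                 morph_open_radius = morph_open_radius,
                 min_component_px = min_component_px,
                 edge_close_radius = edge_close_radius,
                 edge_hue_margin_deg = edge_hue_margin_deg),
            class = "segmentation_params")
}

#' Fuse a threshold mask with an edge mask
#'
#' Union of the threshold mask with those 8-connected edge components that
#' touch it. Edge components anchored to the plant body (tendril contours
#' attached to the stem) are recovered even where thresholding lost them,
#' while isolated background edges (pot rims, soil texture) are discarded.
#'
#' @param thresh,edges logical matrices of identical shape.
#' @return logical matrix: `thresh` plus the anchored edge components.
#' @export
fuse_masks <- function(thresh, edges) {
  if (!identical(dim(thresh), dim(edges)))
    stop("threshold and edge masks differ in shape")
  if (!any(edges) || !any(thresh)) return(thresh)
  lab <- label_components(edges, connectivity = 8)
  # "touching" = edge pixel within the 8-neighbourhood of a threshold pixel
  near <- EBImage::imageData(EBImage::dilate(
    EBImage::Image(thresh * 1), EBImage::makeBrush(3, "box"))) > 0.5
  anchored <- setdiff(unique(lab[near]), 0L)
  if (length(anchored) == 0L) return(thresh)
  thresh | matrix(lab %in% anchored, nrow(lab), ncol(lab))
}

#' Clean a binary mask
#'
#' Post-processing in a fixed order: median filter, morphological closing,
#' opening, then removal of connected components below a size floor. A zero
#' radius (or size floor 0) skips the corresponding step, so the all-zero
#' configuration is the identity map.
#'
#' @param mask logical matrix.
#' @param params a [segmentation_params()] object.
#' @return logical matrix.
#' @export
postprocess_mask <- function(mask, params = segmentation_params()) {
  stopifnot(is.matrix(mask))
  m <- mask
  if (params$median_radius > 0) {
    m <- EBImage::imageData(EBImage::medianFilter(EBImage::Image(m * 1),
                                                  params$median_radius)) > 0.5
  }
  if (params$morph_close_radius > 0) {
    k <- EBImage::makeBrush(2 * params$morph_close_radius + 1, "disc")
    m <- EBImage::imageData(EBImage::closing(EBImage::Image(m * 1), k)) > 0.5
  }
  if (params$morph_open_radius > 0) {
    k <- EBImage::makeBrush(2 * params$morph_open_radius + 1, "disc")
    m <- EBImage::imageData(EBImage::opening(EBImage::Image(m * 1), k)) > 0.5
  }
  if (params$min_component_px > 0 && any(m)) {
    lab <- label_components(m, connectivity = 8)
    keep <- which(component_sizes(lab) >= params$min_component_px)
    m <- matrix(lab %in% keep, nrow(m), ncol(m))
  }
  m
}

#' Split a tray mask into per-plant masks
#'
#' Trays carry a fixed number of pots side by side, so connected components
#' are assigned to `n_plants` vertical strips of equal width by the column
#' coordinate of their centroid; masks are returned in left-to-right order.
#'
#' @param mask logical matrix covering the whole tray.
#' @param n_plants number of pots/plants in the tray (default 2).
#' @return list of `n_plants` logical matrices. If a strip holds no
#'   component, its mask is empty and a warning is issued.
#' @export
split_tray <- function(mask, n_plants = 2) {
  stopifnot(is.matrix(mask), n_plants >= 1)
  out <- replicate(n_plants, matrix(FALSE, nrow(mask), ncol(mask)),
                   simplify = FALSE)
  lab <- label_components(mask, connectivity = 8)
  k <- max(lab)
  if (k > 0L) {
    nc <- ncol(mask)
    cols <- col(mask)
    for (i in seq_len(k)) {
      sel <- lab == i
      cx <- mean(cols[sel])
      strip <- min(max(1L, ceiling(cx / (nc / n_plants))), n_plants)
      out[[strip]] <- out[[strip]] | sel
    }
  }
  empty <- !vapply(out, any, logical(1))
  if (any(empty))
    warning(sprintf("no plant found in strip(s) %s",
                    paste(which(empty), collapse = ", ")))
  out
}

#' Segment one RGB view into a green mask
#'
#' The full per-view pipeline: RGB to HSV, hue thresholding (fixed interval,
#' or Otsu on the hue channel when `params$use_otsu`), Canny edge tracking on
#' the value channel, edge refinement (closing plus a widened-hue gate, see
#' [segmentation_params()]), fusion of the two masks, and post-processing.
#'
#' @param img numeric array `height x width x 3`, values in \[0, 255\].
#' @param params a [segmentation_params()] object.
#' @param stages if `TRUE`, return all intermediate masks.
#' @return logical matrix (the final mask), or when `stages = TRUE` a list
#'   with `threshold`, `edges` (raw Canny), `edges_refined`, `fused`,
#'   `final`.
#' @export
segment_view <- function(img, params = segmentation_params(), stages = FALSE) {
  hsv <- rgb_to_hsv_image(img)
  if (params$use_otsu) {
    ot <- otsu_threshold(hsv$h * 255 / 360)
    thr <- if (ot$degenerate) matrix(FALSE, nrow(hsv$h), ncol(hsv$h))
           else hsv$h * 255 / 360 > ot$threshold & hsv$s > 0
  } else {
    thr <- hue_threshold(hsv, params$hue_interval)
  }
  edges <- canny_edges(hsv$v * 255, low = params$canny_low,
                       high = params$canny_high, sigma = params$canny_sigma)
  er <- edges
  if (params$edge_close_radius > 0 && any(er)) {
    k <- EBImage::makeBrush(2 * params$edge_close_radius + 1, "disc")
    er <- EBImage::imageData(EBImage::closing(EBImage::Image(er * 1), k)) > 0.5
  }
  if (params$edge_hue_margin_deg > 0 && !params$use_otsu) {
    widened <- (params$hue_interval + c(-1, 1) * params$edge_hue_margin_deg) %% 360
    er <- er & hue_threshold(hsv, widened)
  }
  fused <- fuse_masks(thr, er)
  final <- postprocess_mask(fused, params)
  if (stages) list(threshold = thr, edges = edges, edges_refined = er,
                   fused = fused, final = final)
  else final
}

#' Read an 8-bit RGB image (PNG or TIFF)
#'
#' @param path file path; format chosen by extension.
#' @return numeric array `height x width x 3`, values in \[0, 255\].
#' @export
read_rgb_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext)
  )
  if (is.matrix(a)) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3] >= 3L) a <- a[, , 1:3, drop = FALSE]   # drop alpha
  a * 255
}

#' Write a binary mask as a 1-bit-style PNG
#' @param mask logical matrix.
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Write an overlay PNG with the mask outlined by a white border line
#' @param img RGB array in \[0, 255\].
#' @param mask logical matrix.
#' @param path output path.
#' @export
write_overlay_png <- function(img, mask, path) {
  er <- EBImage::imageData(EBImage::erode(EBImage::Image(mask * 1),
                                          EBImage::makeBrush(3, "box"))) > 0.5
  border <- mask & !er
  out <- img / 255
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[border] <- 1
    out[, , ch] <- plane
  }
  png::writePNG(out, path)
  invisible(path)
}
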