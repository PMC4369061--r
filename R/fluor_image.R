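#' Pixel-wise quenching analysis of an image stack
#'
#' Applies [extract_levels()] and [quantum_yields()] to every pixel of a
#' fluorescence image stack inside a region mask, producing parameter maps
#' and per-region summaries (median and lower/upper quartiles). Pixels whose
#' F0 falls below a noise floor are excluded to avoid division blow-ups on
#' background.
#'
#' @param stack numeric array `height x width x n_frames`, fluorescence per
#'   frame.
#' @param times numeric vector of frame times (s), length `n_frames`,
#'   strictly increasing.
#' @param timing a [protocol_timing()] object.
#' @param mask logical matrix `height x width` selecting the region; must
#'   select at least one pixel.
#' @param f0_floor minimum pixel F0 for a yield to be computed (instrument
#'   units; default 0 disables the floor).
#' @param fm_stat pulse summary statistic, see [extract_levels()].
#' @return list with `levels` (matrices F0, FM, Ft, FMp), `yields`
#'   (matrices phi_Po, phi_P, phi_PSII, q_P, phi_fD, phi_NPQ, F0p), and
#'   `stats` (data.frame parameter/q1/median/q3/n over valid pixels).
#'   Masked-out or below-floor pixels are `NA` everywhere.
#' @export
parameter_image <- function(stack, times, timing = protocol_timing(),
                            mask = NULL, f0_floor = 0,
                            fm_stat = c("max", "top_quartile_mean", "mean")) {
  fm_stat <- match.arg(fm_stat)
  stopifnot(length(dim(stack)) == 3L, dim(stack)[3] == length(times))
  h <- dim(stack)[1]; w <- dim(stack)[2]
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  if (!identical(dim(mask), c(h, w))) stop("stack and mask shapes differ")
  if (!any(mask)) stop("empty region mask")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")

  M <- matrix(stack, h * w, length(times))
  sel <- as.vector(mask)
  M <- M[sel, , drop = FALSE]

  row_stat <- function(idx, stat) {
    S <- M[, idx, drop = FALSE]
    switch(stat,
      mean = rowMeans(S),
      max = do.call(pmax, as.data.frame(S)),
      top_quartile_mean = apply(S, 1, function(v)
        mean(v[v >= stats::quantile(v, 0.75)]))
    )
  }
  pulse_stat <- fm_stat

  f0 <- row_stat(window_idx(times, timing$f0_window[1], timing$f0_window[2],
                            "f0"), "mean")
  fm <- row_stat(window_idx(times, timing$sp1_start_s,
                            timing$sp1_start_s + timing$sp_duration_s, "fm"),
                 pulse_stat)
  last_on <- timing$actinic_start_s + max(timing$sp_offsets_s)
  ft <- row_stat(window_idx(times, last_on - timing$ft_window_s, last_on,
                            "ft"), "mean")
  fmp <- row_stat(window_idx(times, last_on, last_on + timing$sp_duration_s,
                             "fmp"), pulse_stat)

  valid <- f0 > f0_floor & f0 > 0 & fm > 0 & fmp > 0
  nafy <- function(x) { x[!valid] <- NA_real_; x }
  f0 <- nafy(f0); fm <- nafy(fm); ft <- nafy(ft); fmp <- nafy(fmp)

  f0p <- f0 / ((fm - f0) / fm + f0 / fmp)
  yields <- list(
    phi_Po = (fm - f0) / fm,
    phi_P = (fmp - ft) / fmp,
    phi_PSII = (fmp - f0p) / fmp,
    q_P = (fmp - ft) / (fmp - f0p),
    phi_fD = ft / fm,
    phi_NPQ = ft / fmp - ft / fm,
    F0p = f0p
  )
  levels <- list(F0 = f0, FM = fm, Ft = ft, FMp = fmp)

  to_map <- function(x) {
    m <- matrix(NA_real_, h, w)
    m[sel] <- x
    m
  }
  level_maps <- lapply(levels, to_map)
  yield_maps <- lapply(yields, to_map)

  summarize <- function(name, x) {
    x <- x[!is.na(x)]
    q <- median_quartiles(x)
    data.frame(parameter = name, q1 = q$q1, median = q$median, q3 = q$q3,
               n = length(x))
  }
  all_params <- c(levels, yields)
  stats_df <- do.call(rbind, mapply(summarize, names(all_params), all_params,
                                    SIMPLIFY = FALSE))
  rownames(stats_df) <- NULL
  list(levels = level_maps, yields = yield_maps, stats = stats_df)
}

#' Render a parameter map in false colour
#'
#' Linear mapping of a parameter image onto a colour scale (viridis by
#' default); values are clipped to `scale`. `NA` pixels render black.
#'
#' @param map numeric matrix.
#' @param scale numeric length 2, `c(min, max)` of the colour scale,
#'   `min < max`, both finite.
#' @param palette vector of colours defining the ramp.
#' @param path optional PNG output path.
#' @return numeric array `height x width x 3` in \[0, 1\] (invisibly when
#'   `path` is given).
#' @export
render_false_colour <- function(map, scale = range(map, na.rm = TRUE),
                                palette = grDevices::hcl.colors(256, "viridis"),
                                path = NULL) {
  stopifnot(length(scale) == 2, all(is.finite(scale)), scale[1] < scale[2])
  x <- (map - scale[1]) / (scale[2] - scale[1])
  x <- pmin(pmax(x, 0), 1)
  ramp <- grDevices::colorRamp(palette)
  rgbv <- matrix(0, length(x), 3)
  ok <- !is.na(as.vector(x))
  if (any(ok)) rgbv[ok, ] <- ramp(as.vector(x)[ok]) / 255
  out <- array(rgbv, dim = c(nrow(map), ncol(map), 3))
  if (!is.null(path)) {
    png::writePNG(out, path)
    return(invisible(out))
  }
  out
}

#' Write a parameter map as 16-bit grayscale TIFF
#' @param map numeric matrix.
#' @param path output path.
#' @param scale values mapped linearly from `scale` to \[0, 1\] before writing.
#' @export
write_parameter_tiff <- function(map, path, scale = range(map, na.rm = TRUE)) {
  x <- (map - scale[1]) / max(scale[2] - scale[1], .Machine$double.eps)
  x <- pmin(pmax(x, 0), 1)
  x[is.na(x)] <- 0
  tiff::writeTIFF(x, path, bits.per.sample = 16L)
  invisible(path)
}
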