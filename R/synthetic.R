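#' Specification of a procedural plant image
#'
#' Parameters of the synthetic pea-like plant renderer: a branching skeleton
#' (stem plus leaf blobs) carrying thin tendrils one or two pixels wide, in
#' plant-green hue over a flat or soil-textured background. `tendril_coverage`
#' models partial pixel coverage of sub-pixel structures: each tendril pixel
#' is alpha-blended with the background with a coverage factor drawn from
#' this range, which drags its hue toward the background the way real thin
#' offshoots blend with soil — the mechanism that makes pure hue
#' thresholding lose tendrils while edge detection still sees them. Full
#' coverage `c(1, 1)` (default) renders crisp tendrils.
#'
#' @param stem_length_px stem length in pixels.
#' @param n_branches number of tendrils.
#' @param tendril_width_px tendril width, 1 or 2 px.
#' @param hue_deg plant hue centre (degrees).
#' @param hue_jitter_deg half-width of the uniform per-pixel hue jitter.
#' @param background `"flat"` or `"soil_texture"`.
#' @param noise_sd Gaussian pixel noise sd added to every RGB channel
#'   (0-255 scale).
#' @param tendril_coverage numeric length 2 in (0, 1\]: range of the
#'   per-pixel coverage (alpha) of tendril pixels.
#' @param width,height image size in pixels.
#' @param seed integer; fixes all randomness of the renderer.
#' @return list of class `"plant_spec"`.
#' @export
plant_spec <- function(stem_length_px = 60, n_branches = 5,
                       tendril_width_px = 1, hue_deg = 120,
                       hue_jitter_deg = 10,
                       background = c("flat", "soil_texture"),
                       noise_sd = 0, tendril_coverage = c(1, 1),
                       width = 128, height = 128, seed = 1) {
  background <- match.arg(background)
  stopifnot(tendril_width_px >= 1, noise_sd >= 0,
            length(tendril_coverage) == 2,
            all(tendril_coverage > 0), all(tendril_coverage <= 1),
            tendril_coverage[1] <= tendril_coverage[2])
  structure(list(stem_length_px = stem_length_px, n_branches = n_branches,
                 tendril_width_px = tendril_width_px, hue_deg = hue_deg,
                 hue_jitter_deg = hue_jitter_deg, background = background,
                 noise_sd = noise_sd, tendril_coverage = tendril_coverage,
                 width = width, height = height, seed = seed),
            class = "plant_spec")
}

#' Canonical tendril-erasure fixture
#'
#' The stress fixture for threshold/edge fusion: single-pixel tendrils with
#' partial pixel coverage (0.3-0.8) over textured dark soil and pixel noise
#' sd 8. Under these conditions hue thresholding loses a fraction of the
#' tendril pixels (their blended hue leaves the green interval), which
#' disconnects tendril fragments that mask clean-up then discards — while
#' the value-channel contrast keeps the tendrils visible to the edge
#' detector, so the fused pipeline recovers them.
#'
#' @param seed integer seed.
#' @return a [plant_spec()].
#' @export
tendril_fixture_spec <- function(seed = 1) {
  plant_spec(tendril_width_px = 1, noise_sd = 8, background = "soil_texture",
             tendril_coverage = c(0.3, 0.8), seed = seed)
}

# rasterize a jittered path; returns integer pixel matrix (row, col)
draw_path <- function(r0, c0, angle, length_px, jitter_sd, nr, nc) {
  pos <- c(r0, c0)
  a <- angle
  pts <- matrix(0L, 0, 2)
  for (i in seq_len(round(length_px))) {
    a <- a + stats::rnorm(1, 0, jitter_sd)
    pos <- pos + c(-cos(a), sin(a))
    p <- round(pos)
    if (p[1] < 1 || p[1] > nr || p[2] < 1 || p[2] > nc) break
    pts <- rbind(pts, p)
  }
  unique(pts)
}

pts_to_mask <- function(pts, nr, nc) {
  m <- matrix(FALSE, nr, nc)
  if (nrow(pts) > 0) m[pts] <- TRUE
  m
}

disc_mask <- function(r0, c0, radius, nr, nc) {
  rr <- row(matrix(0, nr, nc)); cc <- col(matrix(0, nr, nc))
  (rr - r0)^2 + (cc - c0)^2 <= radius^2
}

smooth_noise_field <- function(nr, nc, sigma) {
  f <- EBImage::imageData(EBImage::gblur(
    EBImage::Image(matrix(stats::runif(nr * nc), nr, nc)), sigma = sigma))
  rng <- range(f)
  if (diff(rng) == 0) return(matrix(0.5, nr, nc))
  (f - rng[1]) / diff(rng)
}

# render one view; returns list(image, mask, tendrils)
render_view <- function(spec, view, seed) {
  nr <- spec$height; nc <- spec$width
  with_seed(seed, {
    stem <- matrix(FALSE, nr, nc)
    tendril <- matrix(FALSE, nr, nc)
    leaf <- matrix(FALSE, nr, nc)
    anchor_pts <- NULL
    if (view == "top") {
      # rosette seen from above: radial arms from the centre
      r0 <- round(nr / 2); c0 <- round(nc / 2)
      n_arm <- 4
      for (k in seq_len(n_arm)) {
        a <- 2 * pi * (k - 1) / n_arm + stats::runif(1, -0.3, 0.3)
        pts <- draw_path(r0, c0, a, spec$stem_length_px / 2, 0.08, nr, nc)
        stem <- stem | pts_to_mask(pts, nr, nc)
        if (nrow(pts) > 2) anchor_pts <- rbind(anchor_pts, pts)
      }
      stem <- stem | disc_mask(r0, c0, 2, nr, nc)
    } else {
      # upright shoot: stem growing from the bottom centre
      r0 <- nr - 4
      c0 <- round(nc / 2 + stats::runif(1, -nc / 10, nc / 10))
      pts <- draw_path(r0, c0, 0, spec$stem_length_px, 0.06, nr, nc)
      stem <- pts_to_mask(pts, nr, nc)
      # a 3 px wide stem body
      stem <- stem | pts_to_mask(cbind(pts[, 1], pmin(pts[, 2] + 1L, nc)), nr, nc) |
        pts_to_mask(cbind(pts[, 1], pmax(pts[, 2] - 1L, 1L)), nr, nc)
      anchor_pts <- pts
    }
    # leaf blobs at random skeleton points
    if (!is.null(anchor_pts) && nrow(anchor_pts) > 4) {
      for (k in 1:2) {
        p <- anchor_pts[sample.int(nrow(anchor_pts), 1), ]
        leaf <- leaf | disc_mask(p[1], p[2], 3, nr, nc)
      }
      # tendrils: thin curling offshoots from skeleton points
      for (k in seq_len(spec$n_branches)) {
        p <- anchor_pts[sample.int(nrow(anchor_pts), 1), ]
        side <- sample(c(-1, 1), 1)
        a0 <- if (view == "top") stats::runif(1, 0, 2 * pi)
              else side * stats::runif(1, pi / 6, pi / 2.2)
        len <- stats::runif(1, 0.25, 0.5) * spec$stem_length_px
        pts_t <- draw_path(p[1], p[2], a0, len, 0.12, nr, nc)
        tw <- pts_to_mask(pts_t, nr, nc)
        if (spec$tendril_width_px >= 2 && nrow(pts_t) > 0)
          tw <- tw | pts_to_mask(cbind(pts_t[, 1], pmin(pts_t[, 2] + 1L, nc)),
                                 nr, nc)
        tendril <- tendril | tw
      }
    }
    body <- stem | leaf
    tendril_only <- tendril & !body
    truth <- body | tendril

    # background
    img <- array(0, dim = c(nr, nc, 3))
    if (spec$background == "flat") {
      bg <- grDevices::col2rgb(grDevices::hsv(30 / 360, 0.5, 0.45))
      for (ch in 1:3) img[, , ch] <- bg[ch]
    } else {
      vfield <- 0.2 + 0.2 * smooth_noise_field(nr, nc, 6)
      hfield <- 20 + 20 * smooth_noise_field(nr, nc, 8)
      speck <- matrix(stats::runif(nr * nc) < 0.01, nr, nc)
      vfield[speck] <- 0.7
      cols <- grDevices::col2rgb(grDevices::hsv(as.vector(hfield) / 360, 0.5,
                                                as.vector(vfield)))
      for (ch in 1:3) img[, , ch] <- matrix(cols[ch, ], nr, nc)
    }

    # paint plant pixels in jittered green
    paint <- function(sel_mask, alpha) {
      npx <- sum(sel_mask)
      if (npx == 0) return(invisible())
      h <- (spec$hue_deg +
              stats::runif(npx, -spec$hue_jitter_deg, spec$hue_jitter_deg)) %% 360
      s <- stats::runif(npx, 0.55, 0.85)
      v <- stats::runif(npx, 0.6, 0.78)
      cols <- grDevices::col2rgb(grDevices::hsv(h / 360, s, v))
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[sel_mask] <- alpha * cols[ch, ] + (1 - alpha) * plane[sel_mask]
        img[, , ch] <<- plane
      }
    }
    paint(body, 1)
    cov <- stats::runif(sum(tendril_only), spec$tendril_coverage[1],
                        spec$tendril_coverage[2])
    paint(tendril_only, cov)

    if (spec$noise_sd > 0)
      img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim(img))
    img <- round(pmin(pmax(img, 0), 255))
    list(image = img, mask = truth, tendrils = tendril_only)
  })
}

#' Render the three views of a synthetic plant with ground truth
#'
#' Top, front and side views are independent seeded renders with
#' view-specific silhouettes (a rosette seen from above, upright shoots from
#' the sides). Ground-truth masks are the rendered skeletons themselves —
#' constructed, never segmented — so segmentation accuracy can be scored
#' exactly. The same seed always reproduces bit-identical output.
#'
#' @param spec a [plant_spec()].
#' @return list with `images`, `masks` and `tendrils` (each a named list
#'   over `top`, `front`, `side`), plus the `spec`.
#' @export
make_plant_views <- function(spec = plant_spec()) {
  views <- c("top", "front", "side")
  rendered <- lapply(seq_along(views), function(i)
    render_view(spec, views[i], spec$seed * 3 + i))
  names(rendered) <- views
  list(images = lapply(rendered, `[[`, "image"),
       masks = lapply(rendered, `[[`, "mask"),
       tendrils = lapply(rendered, `[[`, "tendrils"),
       spec = spec)
}

#' Synthetic exponential growth series
#'
#' Per-plant green-area trajectories `W_i(d) = W0 * exp(r * d) * eps_i(d)`
#' with multiplicative lognormal noise, emulating a cohort measured on a
#' fixed schedule of days. The defaults emulate a fast-growing cultivar
#' whose day-21 normalized green area is about 3.5x (r = ln(3.5)/20 per day
#' over measuring days 1..21); `r_per_day = log(2.5)/20` gives the ~2.5x
#' regime of a slower cultivar.
#'
#' @param r_per_day generative relative growth rate (1/day).
#' @param W0 area at day 0 (mm^2).
#' @param days measurement days, strictly increasing.
#' @param n_plants cohort size.
#' @param lognormal_sd sd of the log-noise (0 = deterministic growth).
#' @param seed integer seed.
#' @param plant_prefix prefix for plant ids.
#' @return data.frame with `plant_id`, `day`, `area`.
#' @export
make_growth_series <- function(r_per_day = log(3.5) / 20, W0 = 100,
                               days = c(1, 5, 8, 12, 15, 19, 21),
                               n_plants = 15, lognormal_sd = 0.05,
                               seed = 1, plant_prefix = "plant") {
  stopifnot(W0 > 0, !is.unsorted(days, strictly = TRUE))
  grid <- expand.grid(day = days, plant = seq_len(n_plants))
  with_seed(seed, {
    eps <- exp(stats::rnorm(nrow(grid), 0, lognormal_sd))
    data.frame(
      plant_id = sprintf("%s%02d", plant_prefix, grid$plant),
      day = grid$day,
      area = W0 * exp(r_per_day * grid$day) * eps
    )
  })
}

#' Specification of a synthetic quenching trace
#'
#' Generative fluorescence levels and acquisition settings for
#' [make_trace()]. Invariants `FM >= F0 > 0`, `FMp <= FM`, `Ft > 0` are
#' enforced.
#'
#' @param F0,FM,Ft,FMp generative fluorescence levels (instrument units).
#' @param timing a [protocol_timing()].
#' @param sample_rate_hz sampling rate of the recording.
#' @param noise_sd Gaussian noise sd on the signal.
#' @param seed integer seed.
#' @return list of class `"trace_spec"`.
#' @export
trace_spec <- function(F0 = 200, FM = 1000, Ft = 400, FMp = 700,
                       timing = protocol_timing(), sample_rate_hz = 20,
                       noise_sd = 0, seed = 1) {
  stopifnot(F0 > 0, FM >= F0, FMp <= FM, FMp > 0, Ft > 0,
            sample_rate_hz > 0, noise_sd >= 0)
  structure(list(F0 = F0, FM = FM, Ft = Ft, FMp = FMp, timing = timing,
                 sample_rate_hz = sample_rate_hz, noise_sd = noise_sd,
                 seed = seed),
            class = "trace_spec")
}

#' Synthesize a quenching trace with known levels
#'
#' Builds a piecewise induction curve under the protocol timing: an F0
#' plateau, the FM plateau during the first saturation pulse, finite-time
#' dark relaxation back to F0, a rise to the Ft steady state under actinic
#' light, saturation-pulse plateaus (decaying from near FM to exactly FMp at
#' the last pulse, as quenching builds up), and finite-time post-pulse
#' recoveries. All transients decay to their target levels in finite time,
#' so in the noiseless case [extract_levels()] recovers the generative
#' levels exactly.
#'
#' @param spec a [trace_spec()].
#' @return data.frame with `time_s`, `signal`.
#' @export
make_trace <- function(spec = trace_spec()) {
  tm <- spec$timing
  dt <- 1 / spec$sample_rate_hz
  t <- seq(0, tm$total_s, by = dt)
  dec <- function(dtau, tau) pmax(0, 1 - dtau / tau)^2
  y <- rep(spec$F0, length(t))

  p1_end <- tm$sp1_start_s + tm$sp_duration_s
  y[t >= tm$sp1_start_s & t < p1_end] <- spec$FM
  relax_tau <- min(4, tm$relax_s)
  rel <- t >= p1_end & t < tm$actinic_start_s
  y[rel] <- spec$F0 + (spec$FM - spec$F0) * dec(t[rel] - p1_end, relax_tau)

  act_end <- tm$actinic_start_s + tm$actinic_duration_s
  act <- t >= tm$actinic_start_s & t < act_end
  rise_tau <- min(5, max(tm$sp_offsets_s[1] - 1, 1))
  y[act] <- spec$Ft +
    (spec$F0 - spec$Ft) * dec(t[act] - tm$actinic_start_s, rise_tau)

  offs <- tm$sp_offsets_s
  np <- length(offs)
  for (k in seq_len(np)) {
    on <- tm$actinic_start_s + offs[k]
    pk <- if (k == np) spec$FMp else
      spec$FMp + (spec$FM - spec$FMp) * 0.4 * (np - k) / max(np - 1, 1)
    y[t >= on & t < on + tm$sp_duration_s] <- pk
    rec_tau <- 3
    rec <- t >= on + tm$sp_duration_s &
      t < min(on + tm$sp_duration_s + rec_tau, act_end)
    y[rec] <- spec$Ft +
      (pk - spec$Ft) * dec(t[rec] - (on + tm$sp_duration_s), rec_tau)
  }
  if (spec$noise_sd > 0)
    y <- pmax(0, with_seed(spec$seed,
                           y + stats::rnorm(length(y), 0, spec$noise_sd)))
  data.frame(time_s = t, signal = y)
}

#' Synthesize a pixel-wise fluorescence stack
#'
#' Replicates [make_trace()] per pixel with spatially varying generative
#' levels, for testing pixel-wise quenching analysis. `level_maps` gives
#' matrices `F0`, `FM`, `Ft`, `FMp` (all the same shape); pixel noise is
#' i.i.d. Gaussian.
#'
#' @param level_maps list of matrices `F0`, `FM`, `Ft`, `FMp`.
#' @param timing a [protocol_timing()].
#' @param sample_rate_hz frames per second.
#' @param noise_sd per-pixel Gaussian noise sd.
#' @param seed integer seed.
#' @return list with `stack` (array h x w x n_frames) and `times`.
#' @export
make_stack <- function(level_maps, timing = protocol_timing(),
                       sample_rate_hz = 5, noise_sd = 0, seed = 1) {
  stopifnot(all(c("F0", "FM", "Ft", "FMp") %in% names(level_maps)))
  d <- dim(level_maps$F0)
  npx <- prod(d)
  # one normalized template per unit level-quadruple is not possible (the
  # curve mixes all four levels), so build per-pixel curves from the four
  # basis responses of the piecewise generator
  base_tm <- trace_spec(timing = timing, sample_rate_hz = sample_rate_hz)
  times <- make_trace(base_tm)$time_s
  nt <- length(times)
  M <- matrix(0, npx, nt)
  f0v <- as.vector(level_maps$F0); fmv <- as.vector(level_maps$FM)
  ftv <- as.vector(level_maps$Ft); fmpv <- as.vector(level_maps$FMp)
  # group identical quadruples to avoid one make_trace call per pixel
  key <- paste(f0v, fmv, ftv, fmpv)
  for (k in unique(key)) {
    i <- which(key == k)[1]
    tr <- make_trace(trace_spec(F0 = f0v[i], FM = fmv[i], Ft = ftv[i],
                                FMp = fmpv[i], timing = timing,
                                sample_rate_hz = sample_rate_hz))
    M[key == k, ] <- matrix(tr$signal, sum(key == k), nt, byrow = TRUE)
  }
  if (noise_sd > 0)
    M <- with_seed(seed, pmax(0, M + matrix(stats::rnorm(length(M), 0, noise_sd),
                                            npx, nt)))
  list(stack = array(M, dim = c(d[1], d[2], nt)), times = times)
}
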