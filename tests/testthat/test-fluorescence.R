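test_that("protocol timing derives the actinic phase and validates windows", {
  tm <- protocol_timing()
  expect_equal(tm$actinic_start_s, 22.8)
  expect_equal(tm$total_s, 92.8)
  expect_error(protocol_timing(f0_window = c(0, 6)), "first saturation pulse")
  expect_error(protocol_timing(sp_offsets_s = c(8, 75)), "actinic")
})

test_that("noiseless synthetic trace returns the generative levels exactly", {
  sp <- trace_spec(F0 = 200, FM = 1000, Ft = 400, FMp = 700)
  lv <- extract_levels(make_trace(sp))
  expect_identical(lv$F0, 200)
  expect_identical(lv$FM, 1000)
  expect_identical(lv$Ft, 400)
  expect_identical(lv$FMp, 700)
  expect_identical(lv$FV, 800)
})

test_that("noisy levels converge at the plateau-mean rate", {
  sd_noise <- 5
  sp <- trace_spec(noise_sd = sd_noise, sample_rate_hz = 25, seed = 3)
  tr <- make_trace(sp)
  lv <- extract_levels(tr, fm_stat = "mean")
  tm <- protocol_timing()
  n_in <- function(from, to) sum(tr$time_s >= from & tr$time_s < to)
  tol <- function(n) 3 * sd_noise / sqrt(n)
  expect_lt(abs(lv$F0 - 200), tol(n_in(0, 5)))
  expect_lt(abs(lv$FM - 1000), tol(n_in(5, 5.8)))
  last_on <- tm$actinic_start_s + 68
  expect_lt(abs(lv$FMp - 700), tol(n_in(last_on, last_on + 0.8)))
  expect_lt(abs(lv$Ft - 400), tol(n_in(last_on - 1, last_on)))
})

test_that("a truncated trace raises an error naming the missing window", {
  tr <- make_trace(trace_spec())
  short <- tr[tr$time_s < 85, ]
  expect_error(extract_levels(short), "window ft")
})

test_that("demodulation subtracts the pre-flash baseline", {
  raw <- data.frame(time_s = 1:3, during_flash = c(10, 12, 14),
                    before_flash = c(1, 2, 3))
  expect_equal(demodulate_trace(raw)$signal, c(9, 10, 11))
})

test_that("F0' follows the quenching formula and its no-quenching limit", {
  expect_identical(f0_prime(200, 1000, 1000), 200)
  expect_equal(f0_prime(1, 5, 4), 1 / (0.8 + 0.25))
  # 1-homogeneity: scaling all levels scales F0'
  expect_equal(f0_prime(2, 10, 8), 2 * f0_prime(1, 5, 4))
  expect_error(f0_prime(0, 5, 4), "positive")
})

test_that("the six yields match hand-computed values on the reference levels", {
  lv <- list(F0 = 200, FM = 1000, Ft = 400, FMp = 700)
  qy <- quantum_yields(lv)
  expect_equal(qy$phi_Po, 0.8)
  expect_equal(qy$phi_P, 3 / 7)
  expect_equal(qy$phi_fD, 0.4)
  expect_equal(qy$phi_NPQ, 4 / 7 - 0.4)
  expect_equal(qy$phi_P + qy$phi_fD + qy$phi_NPQ, 1)
  expect_equal(qy$q_P * qy$phi_PSII, qy$phi_P, tolerance = 1e-14)
})

test_that("the dark-adapted limit gives phi_P = phi_Po and zero NPQ yield", {
  qy <- quantum_yields(list(F0 = 150, FM = 900, Ft = 150, FMp = 900))
  expect_equal(qy$phi_P, qy$phi_Po)
  expect_equal(qy$phi_NPQ, 0)
})

test_that("yields are invariant to a common rescaling of all levels", {
  lv <- list(F0 = 180, FM = 950, Ft = 420, FMp = 640)
  q1 <- quantum_yields(lv)
  q2 <- quantum_yields(lapply(lv, `*`, 3.7))
  for (p in c("phi_Po", "phi_P", "phi_PSII", "q_P", "phi_fD", "phi_NPQ"))
    expect_equal(q1[[p]], q2[[p]], tolerance = 1e-12)
})

test_that("pixel-wise analysis matches region analysis and honours the mask", {
  f0 <- matrix(200, 6, 6); fm <- matrix(1000, 6, 6)
  fm[, 4:6] <- 800
  maps <- list(F0 = f0, FM = fm, Ft = 0.4 * fm, FMp = 0.7 * fm)
  st <- make_stack(maps, sample_rate_hz = 5)
  res <- parameter_image(st$stack, st$times)
  # uniform left region: every pixel equals the generative phi_Po
  expect_true(all(abs(res$yields$phi_Po[, 1:3] - 0.8) < 1e-12))
  expect_true(all(abs(res$yields$phi_Po[, 4:6] - 0.75) < 1e-12))
  # per-region medians recover generative parameters
  left <- matrix(FALSE, 6, 6); left[, 1:3] <- TRUE
  res_l <- parameter_image(st$stack, st$times, mask = left)
  expect_equal(res_l$stats$median[res_l$stats$parameter == "phi_Po"], 0.8)
  # masked-out pixels are absent everywhere
  expect_true(all(is.na(res_l$yields$phi_P[, 4:6])))
  expect_equal(res_l$stats$n[1], 18)
  expect_error(parameter_image(st$stack, st$times,
                               mask = matrix(FALSE, 6, 6)), "empty")
})

test_that("false-colour rendering is monotone and respects the scale", {
  ramp <- matrix(seq(0, 1, length.out = 64), 8, 8)
  img <- render_false_colour(ramp, scale = c(0, 1))
  expect_equal(dim(img), c(8, 8, 3))
  # constant map renders a single colour
  flat <- render_false_colour(matrix(0.5, 4, 4), scale = c(0, 1))
  expect_equal(length(unique(as.vector(flat[, , 1]))), 1)
  # endpoint values map to the palette endpoints even when clipped
  lo <- render_false_colour(matrix(-2, 1, 1), scale = c(0, 1))
  hi <- render_false_colour(matrix(99, 1, 1), scale = c(0, 1))
  pal <- grDevices::col2rgb(grDevices::hcl.colors(256, "viridis")) / 255
  expect_equal(as.vector(lo[1, 1, ]), unname(pal[, 1]), tolerance = 1e-6)
  expect_equal(as.vector(hi[1, 1, ]), unname(pal[, 256]), tolerance = 1e-6)
  # monotone progression along a linear ramp (green channel for viridis)
  g <- img[, , 2][order(ramp)]
  expect_true(all(diff(g) > -1e-9))
  expect_error(render_false_colour(ramp, scale = c(1, 1)))
})
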