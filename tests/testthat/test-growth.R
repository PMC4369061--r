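test_that("calibration averages per-view reference ratios", {
  one <- calibrate(data.frame(view = "front", px_count = 400, known_mm2 = 100))
  expect_equal(one$front, 0.25)
  two <- calibrate(data.frame(view = c("front", "front"),
                              px_count = c(400, 200), known_mm2 = c(100, 50)))
  expect_equal(two$front, 0.25)
  mixed <- calibrate(data.frame(view = c("front", "front"),
                                px_count = c(400, 400), known_mm2 = c(100, 120)))
  expect_equal(mixed$front, 0.275)
  expect_error(apply_calibration(one, "top", 10), "top")
  expect_error(calibrate(data.frame(view = "top", px_count = 0, known_mm2 = 1)),
               "positive")
})

test_that("total green area is the Euclidean combination of projections", {
  expect_equal(total_green_area(3, 4, 0), 5)
  expect_equal(total_green_area(0, 0, 0), 0)
  expect_equal(total_green_area(10, 10, 10), sqrt(300))
  expect_error(total_green_area(-1, 0, 0), "non-negative")
  expect_warning(a <- total_green_area(3, NA, 4), "missing view")
  expect_equal(a, 5)
})

test_that("total green area is symmetric, 1-homogeneous, >= max projection", {
  set.seed(3)
  for (i in 1:20) {
    p <- runif(3, 0, 100)
    a <- total_green_area(p[1], p[2], p[3])
    expect_equal(a, total_green_area(p[3], p[1], p[2]))
    expect_equal(total_green_area(2 * p[1], 2 * p[2], 2 * p[3]), 2 * a)
    expect_gte(a, max(p))
  }
})

test_that("NGA divides by the first-day area and starts at 1", {
  expect_equal(normalized_green_area(c(1, 5, 8), c(10, 25, 35)), c(1, 2.5, 3.5))
  expect_equal(normalized_green_area(c(1, 2), c(7, 7)), c(1, 1))
  expect_equal(normalized_green_area(c(1, 2), c(8, 2)), c(1, 0.25))
  expect_error(normalized_green_area(c(1, 2), c(0, 5)), "positive")
  expect_error(normalized_green_area(c(2, 1), c(5, 5)), "increasing")
})

test_that("NGA is invariant to the calibration factor", {
  areas <- c(12, 30, 42)
  expect_equal(normalized_green_area(1:3, areas),
               normalized_green_area(1:3, areas * 0.17))
})

test_that("RGR is the difference of mean log areas over elapsed time", {
  expect_equal(relative_growth_rate(c(5, 9), c(5, 9), 1, 3), 0)
  expect_equal(relative_growth_rate(c(exp(1), exp(1)), c(exp(3), exp(3)), 0, 2), 1)
  expect_equal(relative_growth_rate(c(10, 20), c(30, 50), 0, 4),
               (mean(log(c(30, 50))) - mean(log(c(10, 20)))) / 4)
  expect_error(relative_growth_rate(c(0, 1), c(2, 3), 0, 1), "positive")
  expect_error(relative_growth_rate(c(1, 2), c(2, 3), 3, 3), "exceed")
})

test_that("mean-of-logs differs from log-of-means when growth is heterogeneous", {
  a1 <- c(10, 20); a2 <- c(30, 90)
  mean_logs <- relative_growth_rate(a1, a2, 0, 1)
  log_means <- log(mean(a2) / mean(a1))
  expect_false(isTRUE(all.equal(mean_logs, log_means)))
})

test_that("RGR recovers the generative rate exactly for exponential growth", {
  g <- make_growth_series(r_per_day = 0.0713, lognormal_sd = 0, n_plants = 6,
                          seed = 2)
  days <- sort(unique(g$day))
  for (i in seq_len(length(days) - 1)) {
    a1 <- g$area[g$day == days[i]]
    a2 <- g$area[g$day == days[i + 1]]
    expect_equal(relative_growth_rate(a1, a2, days[i], days[i + 1]), 0.0713,
                 tolerance = 1e-12)
  }
})

test_that("noisy growth series recover the rate within sampling error", {
  r <- log(3.5) / 20
  ests <- vapply(1:50, function(s) {
    g <- make_growth_series(r_per_day = r, lognormal_sd = 0.05, n_plants = 15,
                            seed = s)
    a1 <- g$area[g$day == 1]; a2 <- g$area[g$day == 21]
    relative_growth_rate(a1, a2, 1, 21)
  }, numeric(1))
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - r), 2 * se + 1e-6)
})

test_that("growth table combines views and computes per-plant NGA", {
  areas <- expand.grid(plant_id = c("a", "b"), day = c(1, 5),
                       view = c("top", "front", "side"),
                       stringsAsFactors = FALSE)
  areas$area_px <- c(300, 300, 400, 400)[match(paste(areas$plant_id, areas$day),
                                               c("a 1", "b 1", "a 5", "b 5"))]
  tab <- growth_table(areas)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$a_total[tab$plant_id == "a" & tab$day == 1], sqrt(3) * 300)
  expect_equal(tab$nga[tab$plant_id == "a" & tab$day == 5], 4 / 3)
  # calibrated: all views 0.25 mm2/px scales areas but not NGA
  cal <- calibrate(data.frame(view = c("top", "front", "side"),
                              px_count = 400, known_mm2 = 100))
  tab2 <- growth_table(areas, cal)
  expect_equal(tab2$a_total, tab$a_total * 0.25)
  expect_equal(tab2$nga, tab$nga)
})

test_that("rgr series covers consecutive or anchored intervals", {
  g <- make_growth_series(lognormal_sd = 0, n_plants = 3)
  tab <- data.frame(plant_id = g$plant_id, day = g$day, a_total = g$area)
  rs <- rgr_series(tab)
  expect_equal(nrow(rs), 6)
  expect_equal(rs$rgr, rep(log(3.5) / 20, 6), tolerance = 1e-12)
  ra <- rgr_series(tab, anchored = TRUE)
  expect_true(all(ra$day1 == 1))
})
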