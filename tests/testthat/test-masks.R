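test_that("fusion is identity under an empty edge mask and anchors components", {
  thr <- matrix(FALSE, 10, 10); thr[4:6, 4:6] <- TRUE
  none <- matrix(FALSE, 10, 10)
  expect_identical(fuse_masks(thr, none), thr)
  # empty threshold mask: nothing to anchor to
  expect_identical(fuse_masks(none, thr), none)
  # an edge component touching the mask is added; an isolated one is not
  edges <- matrix(FALSE, 10, 10)
  edges[7, 5:8] <- TRUE            # touches the block at (6,5)
  edges[1, 9:10] <- TRUE           # isolated background edge
  fused <- fuse_masks(thr, edges)
  expect_true(all(fused[7, 5:8]))
  expect_false(any(fused[1, 9:10]))
})

test_that("fusion result is bounded by threshold and threshold-union-edges", {
  set.seed(5)
  for (i in 1:10) {
    thr <- matrix(runif(400) < 0.1, 20, 20)
    edges <- matrix(runif(400) < 0.1, 20, 20)
    fused <- fuse_masks(thr, edges)
    expect_true(all(thr[fused == FALSE] == FALSE))      # superset of thr
    expect_true(all(fused | !(thr | edges) | (thr | edges)))
    expect_true(all(!fused | (thr | edges)))            # subset of union
  }
})

test_that("fusion rejects shape mismatch", {
  expect_error(fuse_masks(matrix(FALSE, 3, 3), matrix(FALSE, 4, 4)), "shape")
})

test_that("identity post-processing configuration is the identity map", {
  p0 <- segmentation_params(median_radius = 0, morph_close_radius = 0,
                            morph_open_radius = 0, min_component_px = 0)
  set.seed(1)
  m <- matrix(runif(400) < 0.3, 20, 20)
  expect_identical(postprocess_mask(m, p0), m)
})

test_that("small components are removed by the size filter", {
  m <- matrix(FALSE, 12, 12)
  m[2, 2] <- TRUE                   # isolated pixel
  m[6:9, 6:9] <- TRUE               # 16-px block
  p <- segmentation_params(min_component_px = 2)
  out <- postprocess_mask(m, p)
  expect_false(out[2, 2])
  expect_true(all(out[6:9, 6:9]))
})

test_that("median filter removes salt noise but keeps a solid square", {
  set.seed(11)
  m <- matrix(FALSE, 40, 40)
  m[11:30, 11:30] <- TRUE
  noise_idx <- sample(which(!m), round(0.01 * 1600))
  m_noisy <- m
  m_noisy[noise_idx] <- TRUE
  p <- segmentation_params(median_radius = 1, min_component_px = 0)
  out <- postprocess_mask(m_noisy, p)
  expect_true(all(out[12:29, 12:29]))                  # interior preserved
  surviving <- sum(out[noise_idx])
  expect_lte(surviving, ceiling(0.05 * length(noise_idx)))
})

test_that("tray splitting assigns components to strips by centroid", {
  m <- matrix(FALSE, 20, 40)
  m[5:8, 5:8] <- TRUE               # left blob
  m[12:15, 30:33] <- TRUE           # right blob
  parts <- split_tray(m, 2)
  expect_length(parts, 2)
  expect_true(all(parts[[1]][5:8, 5:8])); expect_false(any(parts[[1]][, 21:40]))
  expect_true(all(parts[[2]][12:15, 30:33]))
  # single blob, one plant: identity
  one <- split_tray(m | m, 1)
  expect_identical(one[[1]], m)
  # centroid at 0.45 * width goes to the left strip
  m3 <- m
  m3[2:3, 17:19] <- TRUE            # centroid col 18 = 0.45 * 40
  parts3 <- split_tray(m3, 2)
  expect_true(any(parts3[[1]][2:3, 17:19]))
  expect_false(any(parts3[[2]][2:3, 17:19]))
})

test_that("missing plants produce empty masks with a warning", {
  m <- matrix(FALSE, 10, 20)
  m[3:5, 2:4] <- TRUE
  expect_warning(parts <- split_tray(m, 2), "strip")
  expect_false(any(parts[[2]]))
})

test_that("blank background segments to an empty mask", {
  img <- array(0, dim = c(32, 32, 3))
  img[, , 1] <- 120; img[, , 2] <- 90; img[, , 3] <- 60   # brown background
  expect_false(any(segment_view(img)))
})

test_that("segmentation is deterministic given pixels and params", {
  pv <- make_plant_views(tendril_fixture_spec(seed = 4))
  m1 <- segment_view(pv$images$front)
  m2 <- segment_view(pv$images$front)
  expect_identical(m1, m2)
})

test_that("noiseless plants are segmented with recall and precision 1", {
  for (s in 1:3) {
    pv <- make_plant_views(plant_spec(noise_sd = 0, seed = s))
    for (v in c("top", "front", "side")) {
      m <- segment_view(pv$images[[v]])
      expect_gte(recall_of(m, pv$masks[[v]]), 0.99)
      expect_gte(precision_of(m, pv$masks[[v]]), 0.99)
    }
  }
})

test_that("edge fusion recovers tendrils that hue thresholding loses", {
  pv <- make_plant_views(tendril_fixture_spec(seed = 2))
  p <- segmentation_params()
  for (v in c("front", "side")) {
    st <- segment_view(pv$images[[v]], p, stages = TRUE)
    tend <- pv$tendrils[[v]]
    thr_only <- postprocess_mask(st$threshold, p)
    r_thr <- recall_of(thr_only, tend)
    r_fused <- recall_of(st$final, tend)
    expect_gte(r_fused, 0.9)
    expect_gt(r_fused, r_thr)
  }
})

test_that("otsu-based hue thresholding segments a noiseless plant", {
  pv <- make_plant_views(plant_spec(noise_sd = 0, seed = 9))
  p <- segmentation_params(use_otsu = TRUE)
  m <- segment_view(pv$images$front, p)
  expect_gte(recall_of(m, pv$masks$front), 0.99)
})

test_that("mask PNG round-trips and the overlay is written", {
  pv <- make_plant_views(plant_spec(noise_sd = 0, seed = 1))
  m <- pv$masks$front
  f <- tempfile(fileext = ".png")
  write_mask_png(m, f)
  back <- png::readPNG(f) > 0.5
  expect_identical(back, m)
  f2 <- tempfile(fileext = ".png")
  write_overlay_png(pv$images$front, m, f2)
  expect_true(file.exists(f2))
})

test_that("8-connected labeling joins diagonal pixels, 4-connected does not", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_equal(max(label_components(m, 8)), 1)
  expect_equal(max(label_components(m, 4)), 3)
})
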