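# Detection chain: projection, thresholds, QC gates, find-spot.

test_that("best-focus projection is the pixelwise maximum", {
  planes <- lapply(1:9, function(i) matrix(as.integer(i * 10), 4, 5))
  expect_identical(best_focus_projection(planes), planes[[9]])
  identical9 <- replicate(9, matrix(7L, 4, 5), simplify = FALSE)
  expect_identical(best_focus_projection(identical9), identical9[[1]])
  fx <- make_field_scene(10, seed = 23, acq = small_acq)
  st <- render_field_stack(fx$scene, fx$field, fx$acq)
  proj <- best_focus_projection(st)
  for (p in st$planes) expect_true(all(proj >= p))
  expect_identical(max(proj), max(vapply(st$planes, max, integer(1))))
})

test_that("auto-threshold separates two-valued images and flags constants", {
  img <- matrix(c(rep(100L, 30), rep(2000L, 70)), 10, 10)
  lv <- auto_threshold(img)
  expect_gt(lv, 100); expect_lt(lv, 2000)
  const <- matrix(500L, 8, 8)
  lc <- auto_threshold(const)
  expect_identical(as.integer(lc), 500L)
  expect_true(attr(lc, "degenerate"))
})

test_that("auto-threshold equals the exhaustive between-class search", {
  set.seed(61)
  for (i in 1:4) {
    img <- matrix(as.integer(pmax(0, round(c(rnorm(800, 300, 40),
                                             rnorm(200, 1200, 150))))),
                  40, 25)
    expect_identical(as.integer(auto_threshold(img)), brute_otsu(img))
  }
})

test_that("QC gates fire on constructed pathologies and record all failures", {
  params <- detection_params()
  dark <- matrix(0L, 64, 64)
  qc <- field_qc(dark, params)
  expect_false(qc$accepted)
  expect_true("TOO_DARK" %in% qc$reasons)
  # bright uniform background, no objects: degenerate threshold
  bright <- matrix(9000L, 64, 64)
  qc2 <- field_qc(bright, params)
  expect_false(qc2$accepted)
  expect_true("TOO_FEW_PRELIM_OBJECTS" %in% qc2$reasons)
  expect_true("AREA_PCT_OUT_OF_RANGE" %in% qc2$reasons)
})

test_that("a constructed good field passes QC with hand-checked measures", {
  img <- matrix(400L, 128, 128)
  centers <- expand.grid(y = c(20, 64, 108), x = c(20, 64, 108))
  for (k in seq_len(nrow(centers)))
    img <- paint_disc(img, centers$y[k], centers$x[k], 6, 8000L)
  qc <- field_qc(img, detection_params())
  expect_true(qc$accepted)
  expect_equal(qc$measures$mean_intensity, mean(img))
  lv <- qc$measures$threshold
  expect_equal(qc$measures$area_pct, 100 * mean(img > lv))
  expect_identical(qc$measures$n_prelim, 9L)
  expect_equal(qc$measures$bg_mean, mean(img[img <= lv]))
})

test_that("tile-local thresholding adapts to brightness gradients", {
  params <- detection_params(tile_grid = 2L)
  # brightness ramp across tiles plus one equal-contrast spot per tile
  base <- matrix(as.integer(round(rep(seq(200, 800, length.out = 96),
                                      each = 96))), 96, 96)
  img <- base
  for (cc in list(c(24, 24), c(24, 72), c(72, 24), c(72, 72)))
    img <- paint_disc(img, cc[1], cc[2], 5, img[cc[1], cc[2]] + 5000L)
  enh <- local_threshold_enhance(img, params)
  # oracle: independent per-tile Otsu with the global floor
  global <- brute_otsu(img)
  for (ti in 1:2) for (tj in 1:2) {
    ri <- ((ti - 1) * 48 + 1):(ti * 48)
    ci <- ((tj - 1) * 48 + 1):(tj * 48)
    lvl <- max(brute_otsu(img[ri, ci]), global)
    exp_tile <- img[ri, ci]
    exp_tile[exp_tile < lvl] <- 0L
    expect_identical(enh[ri, ci], exp_tile)
  }
  # every spot survives
  for (cc in list(c(24, 24), c(24, 72), c(72, 24), c(72, 72)))
    expect_gt(enh[cc[1], cc[2]], 0)
  # background below every tile level is zeroed
  expect_true(all(enh[img == base] == 0L))
})

test_that("tile_grid = 1 reduces to global thresholding", {
  set.seed(4)
  img <- matrix(as.integer(c(rpois(500, 300), rpois(100, 3000))), 30, 20)
  enh <- local_threshold_enhance(img, detection_params(tile_grid = 1L))
  lvl <- as.integer(auto_threshold(img))
  manual <- img; manual[manual < lvl] <- 0L
  expect_identical(enh, manual)
})

test_that("find_spots counts disjoint discs exactly (labeling oracle)", {
  params <- detection_params(spot_size = 500, int_min = 1000,
                             spot_cutoff = 0.2)
  img <- matrix(0L, 128, 128)
  centers <- expand.grid(y = c(25, 64, 103), x = c(30, 95))
  for (k in seq_len(nrow(centers)))
    img <- paint_disc(img, centers$y[k], centers$x[k], 7, 6000L)
  spots <- find_spots(img, params)
  expect_identical(sum(spots$status == "COUNTED"), 6L)
  oracle <- flood_fill_count(img > 0)
  expect_identical(nrow(spots), oracle$n)
  # centroid order is (y, x); centroids match the painted centers
  ord <- order(centers$y, centers$x)
  expect_equal(spots$cx_px, centers$x[ord], tolerance = 0.1)
  expect_equal(spots$cy_px, centers$y[ord], tolerance = 0.1)
  expect_true(all(spots$circularity > 0.8 & spots$circularity <= 1))
})

test_that("empty images yield no objects", {
  expect_identical(nrow(find_spots(matrix(0L, 32, 32), detection_params())),
                   0L)
})

test_that("an unsplittable giant blob is rejected as a cluster", {
  params <- detection_params()
  img <- paint_disc(matrix(0L, 128, 128), 64, 64, 33, 6000L)  # area ~3400
  spots <- find_spots(img, params)
  expect_identical(sum(spots$status == "COUNTED"), 0L)
  expect_identical(sum(spots$status == "REJECTED_CLUSTER"), 1L)
})

test_that("detected counts are translation equivariant", {
  params <- detection_params(spot_size = 500)
  img <- matrix(0L, 128, 128)
  for (cc in list(c(40, 40), c(50, 88), c(90, 60)))
    img <- paint_disc(img, cc[1], cc[2], 6, 6000L)
  s0 <- find_spots(img, params)
  shifted <- matrix(0L, 128, 128)
  shifted[11:128, 8:128] <- img[1:118, 1:121]
  s1 <- find_spots(shifted, params)
  expect_identical(nrow(s1), nrow(s0))
  expect_equal(sort(s1$cx_px), sort(s0$cx_px) + 7, tolerance = 1e-6)
  expect_equal(sort(s1$cy_px), sort(s0$cy_px) + 10, tolerance = 1e-6)
  expect_identical(sum(s1$status == "COUNTED"), sum(s0$status == "COUNTED"))
})

test_that("tightening the filters never increases accepted objects", {
  fx <- make_field_scene(150, seed = 29)
  st <- render_field_stack(fx$scene, fx$field, fx$acq)
  base <- count_field(st, detection_params())
  expect_true(base$qc$accepted)
  stricter <- list(detection_params(int_min = 3000),
                   detection_params(spot_cutoff = 0.8),
                   detection_params(surf_spot = 150, cluster = 320))
  for (dp in stricter) {
    res <- count_field(st, dp)
    expect_lte(res$count, base$count)
  }
  # raising dark_max far enough excludes the field entirely
  res_dark <- count_field(st, detection_params(dark_max = 60000))
  expect_false(res_dark$qc$accepted)
  expect_true(is.na(res_dark$count))
})

test_that("count_field recovers well-separated simulated cones", {
  fx <- make_field_scene(40, seed = 37, hardcore_radius_um = 10)
  st <- render_field_stack(fx$scene, fx$field, fx$acq)
  res <- count_field(st, detection_params())
  expect_true(res$qc$accepted)
  expect_equal(res$field_area_mm2, 0.037568, tolerance = 1e-4)
  expect_lte(abs(res$count - fx$truth), ceiling(0.05 * fx$truth))
  expect_equal(res$density_per_mm2, res$count / res$field_area_mm2)
})

test_that("excluded fields carry reasons and no count", {
  p <- synthetic_params(base_density = 0, retina_radius_mm = 0.1,
                        bg_mean = 30, bg_gradient_amp = 0, noise_scale = 0.2,
                        dark_patch_fraction = 0, n_incisions = 0L, seed = 41)
  sc <- generate_scene(p)
  st <- render_field_stack(sc, field_coordinate(0L, 0L, 0, 0), small_acq)
  res <- count_field(st, detection_params())
  expect_false(res$qc$accepted)
  expect_true("TOO_DARK" %in% res$qc$reasons)
  expect_true(is.na(res$count))
  expect_true(is.na(res$density_per_field))
})
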