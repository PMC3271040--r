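# Density estimators: global, counting frame, systematic sampling.

mk_obj <- function(cx, cy, r = 0, status = "COUNTED") {
  data.frame(cx_px = cx, cy_px = cy, area_px = pi * r^2,
             mean_intensity = 5000, peak_intensity = 8000, circularity = 1,
             r_eq_px = r, status = status, stringsAsFactors = FALSE)
}

test_that("the forbidden-edge rule excludes left/top contacts only", {
  fr <- counting_frame()
  rect <- conecounter:::frame_rect_px(fr, fx_acq)
  # strictly interior object
  inside <- mk_obj((rect["x0"] + rect["x1"]) / 2, (rect["y0"] + rect["y1"]) / 2,
                   r = 3)
  expect_identical(frame_count(inside, fr, fx_acq)$count, 1L)
  # overlapping the left forbidden edge
  left <- mk_obj(rect["x0"], (rect["y0"] + rect["y1"]) / 2, r = 3)
  res <- frame_count(left, fr, fx_acq)
  expect_identical(res$count, 0L)
  expect_identical(res$status, "EXCLUDED_FRAME")
  # touching only the permitted right edge
  right <- mk_obj(rect["x1"], (rect["y0"] + rect["y1"]) / 2, r = 3)
  expect_identical(frame_count(right, fr, fx_acq)$count, 1L)
  # rejected objects are never counted
  rej <- mk_obj((rect["x0"] + rect["x1"]) / 2, (rect["y0"] + rect["y1"]) / 2,
                r = 3, status = "REJECTED_SHAPE")
  expect_identical(frame_count(rej, fr, fx_acq)$count, 0L)
  expect_error(frame_count(inside, counting_frame(500, 500), fx_acq),
               "larger than the field")
})

test_that("tiling by frames counts every object exactly once", {
  set.seed(91)
  # frames tile a 6 x 6 block; objects are discs well inside the block
  fr <- counting_frame()
  rect <- conecounter:::frame_rect_px(fr, fx_acq, offset_px = c(0, 0))
  sx <- unname(rect["x1"]); sy <- unname(rect["y1"])
  n <- 80L
  objs <- mk_obj(runif(n, 1.2 * sx, 4.8 * sx),
                 runif(n, 1.2 * sy, 4.8 * sy),
                 r = runif(n, 0.5, 5))
  total <- 0L
  for (i in 0:5) for (j in 0:5)
    total <- total + frame_count(objs, fr, fx_acq,
                                 offset_px = c(j * sx, i * sy))$count
  expect_identical(total, n)
})

test_that("mean frame count is unbiased on Poisson patterns", {
  set.seed(17)
  fr <- counting_frame()
  pxx <- fx_acq$field_width_um / fx_acq$width
  lambda_um2 <- 0.02
  n_pat <- 20; n_place <- 50
  means <- numeric(n_pat)
  area_px <- fx_acq$width * fx_acq$height
  lam_px <- lambda_um2 * pxx^2
  for (k in seq_len(n_pat)) {
    n <- rpois(1, lam_px * area_px)
    objs <- mk_obj(runif(n, 0, fx_acq$width), runif(n, 0, fx_acq$height),
                   r = 0)
    side <- fr$width_um / pxx
    cnt <- numeric(n_place)
    for (m in seq_len(n_place))
      cnt[m] <- frame_count(objs, fr, fx_acq,
                            offset_px = c(runif(1, 0, fx_acq$width - side),
                                          runif(1, 0, fx_acq$height - side)))$count
    means[k] <- mean(cnt)
  }
  expected <- lambda_um2 * fr$width_um * fr$height_um
  expect_lt(abs(mean(means) - expected) / expected, 0.05)
})

test_that("global density averages accepted fields only", {
  mk_res <- function(count, accepted = TRUE) {
    qc <- structure(list(accepted = accepted,
                         reasons = if (accepted) character(0) else "TOO_DARK",
                         measures = list()), class = "qc_decision")
    structure(list(field = field_coordinate(0L, 0L, 0, 0), qc = qc,
                   count = if (accepted) count else NA_integer_,
                   objects = NULL,
                   density_per_field = if (accepted) count else NA_real_,
                   density_per_mm2 = NA_real_,
                   field_area_mm2 = field_area_mm2(fx_acq, NULL)),
              class = "field_result")
  }
  res <- list(mk_res(40L), mk_res(60L), mk_res(0L, accepted = FALSE))
  ds <- global_density(res)
  expect_equal(ds$mean_density_per_field, 50)
  expect_identical(ds$n_fields_excluded, 1L)
  expect_equal(round(ds$field_area_mm2, 4), 0.0376)
  expect_error(global_density(list(mk_res(0L, accepted = FALSE))),
               "no accepted fields")
})

test_that("stereological frame estimator agrees with ground truth", {
  sc <- generate_scene(synthetic_params(base_density = 8000,
                                        retina_radius_mm = 0.6,
                                        n_incisions = 0L,
                                        dark_patch_fraction = 0,
                                        cluster_fraction = 0, seed = 53))
  grid <- build_grid(sc, fx_acq, "draughtboard")
  res <- truth_field_results(sc, grid)
  ds <- stereo_automated_density(res, counting_frame(), fx_acq)
  expect_equal(ds$frame_area_um2, 900)
  # 8000 / mm^2 = 7.2 per 900 um^2 frame
  expect_lt(abs(ds$mean_density_per_frame - 7.2) / 7.2, 0.25)
  expect_equal(ds$mean_density_per_field_equiv,
               ds$mean_density_per_frame *
                 fx_acq$field_width_um * fx_acq$field_height_um / 900)
})

test_that("all-empty frames give zero density over counted fields", {
  sc <- generate_scene(synthetic_params(base_density = 0,
                                        retina_radius_mm = 0.5, seed = 2))
  grid <- build_grid(sc, fx_acq, "draughtboard")
  res <- truth_field_results(sc, grid)
  ds <- stereo_automated_density(res, counting_frame(), fx_acq)
  expect_equal(ds$mean_density_per_frame, 0)
  expect_gt(ds$n_fields_counted, 0)
})

test_that("systematic random sampling yields 50-80 disjoint in-disc fields", {
  sc <- generate_scene(synthetic_params(base_density = 0,
                                        retina_radius_mm = 2.4,
                                        n_incisions = 0L, seed = 3))
  for (seed in c(1L, 2L)) {
    f <- systematic_random_sample(sc, c(0, 0), seed = seed)
    expect_gte(nrow(f), 50); expect_lte(nrow(f), 80)
    expect_true(all(f$side_um == 35))
    expect_equal(unique(f$side_um)^2, 1225)
    # all inside the 2 mm disc
    cx <- f$x0 + 17.5; cy <- f$y0 + 17.5
    expect_true(all(sqrt(cx^2 + cy^2) + 35 / sqrt(2) <= 2000 + 1e-9))
    # pairwise disjoint
    if (nrow(f) > 1) {
      for (i in seq_len(nrow(f) - 1)) {
        overl <- abs(f$x0[-(1:i)] - f$x0[i]) < 35 &
                 abs(f$y0[-(1:i)] - f$y0[i]) < 35
        expect_false(any(overl))
      }
    }
  }
  f1 <- systematic_random_sample(sc, c(0, 0), seed = 1L)
  f2 <- systematic_random_sample(sc, c(0, 0), seed = 2L)
  expect_false(identical(f1$x0[1], f2$x0[1]))
  tiny <- generate_scene(synthetic_params(base_density = 0,
                                          retina_radius_mm = 0.1, seed = 4))
  expect_error(systematic_random_sample(tiny, c(0, 0)), "achievable")
})

test_that("sampled stereology recovers the scene density", {
  sc <- generate_scene(synthetic_params(base_density = 3000,
                                        retina_radius_mm = 2.3,
                                        n_incisions = 0L,
                                        dark_patch_fraction = 0,
                                        cluster_fraction = 0, seed = 59))
  f <- systematic_random_sample(sc, c(0, 0), seed = 5L)
  ds <- sampled_stereo_density(sc, f)
  expect_lt(abs(ds$mean_density_per_mm2 - 3000) / 3000, 0.2)
})
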