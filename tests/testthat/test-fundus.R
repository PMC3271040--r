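# Virtual eye fundus: centre location, annulus binning, radial profiles,
# regional dorsal/ventral comparison.

# fabricate a results table for a full rectangular grid of accepted fields
mk_table <- function(n_row, n_col, density, acq = fx_acq,
                     accepted = NULL) {
  gg <- expand.grid(col = seq_len(n_col) - 1L, row = seq_len(n_row) - 1L)
  w <- acq$field_width_um; h <- acq$field_height_um
  tab <- data.frame(field_index = seq_len(nrow(gg)), row = gg$row,
                    col = gg$col,
                    x_um = (gg$col + 0.5) * w, y_um = (gg$row + 0.5) * h,
                    z_um = 0, accepted = TRUE, reasons = "",
                    count = NA_integer_, density = NA_real_,
                    density_per_mm2 = NA_real_, mean_intensity = NA_real_,
                    threshold = NA_integer_, area_pct = NA_real_,
                    n_prelim = NA_integer_, bg_mean = NA_real_)
  tab$density <- if (is.function(density))
    density(tab$x_um, tab$y_um) else density
  tab$count <- round(tab$density)
  if (!is.null(accepted)) tab$accepted <- accepted
  tab
}

test_that("locate_center matches the arithmetic centroid", {
  t1 <- mk_table(1, 1, 100)
  expect_equal(unname(locate_center(t1)),
               c(fx_acq$field_width_um / 2, fx_acq$field_height_um / 2))
  t3 <- mk_table(3, 3, 100)
  ctr <- locate_center(t3)
  expect_equal(unname(ctr["x_um"]), 1.5 * fx_acq$field_width_um)
  # ring-shaped acceptance: centroid of the accepted subset
  t5 <- mk_table(5, 5, 100)
  on_ring <- t5$row %in% c(0, 4) | t5$col %in% c(0, 4)
  t5$accepted <- on_ring
  ctr5 <- locate_center(t5)
  expect_equal(unname(ctr5["x_um"]), mean(t5$x_um[on_ring]))
  expect_equal(unname(ctr5["y_um"]), mean(t5$y_um[on_ring]))
  expect_equal(unname(locate_center(t5, override = c(7, 9))), c(7, 9))
  t5$accepted <- FALSE
  expect_error(locate_center(t5), "no accepted fields")
})

test_that("colour bins are a step function with breakpoints at 45s", {
  cfg <- fundus_config()
  expect_identical(cfg$bin_edges, 45 * (1:9))
  d <- c(0, 1, 45, 45.01, 90, 100, 135, 360, 405, 500)
  expect_identical(conecounter:::density_bin(d, cfg),
                   c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 8L, 9L, 9L))
})

test_that("a uniform retina maps every cell to the same bin", {
  tab <- mk_table(9, 9, 100)
  map <- build_fundus(tab)
  expect_true(all(map$cells$bin == 3L))          # 100 in (90, 135]
  prof <- radial_profile(map)
  expect_length(prof, 9L)
  expect_true(all(abs(prof - 100) < 1e-9, na.rm = TRUE))
})

test_that("every field maps to exactly one fundus cell", {
  tab <- mk_table(8, 10, function(x, y) 50 + x / 20)
  tab$accepted[c(3, 17)] <- FALSE
  map <- build_fundus(tab)
  expect_identical(nrow(map$cells), nrow(tab))
  expect_setequal(map$cells$field_index, tab$field_index)
  expect_identical(sum(map$cells$excluded), 2L)
  # within each annulus, segments are 1..n
  for (rr in unique(map$cells$row)) {
    seg <- sort(map$cells$segment[map$cells$row == rr])
    expect_identical(seg, seq_along(seg))
  }
})

test_that("radial profile recovers a radial density gradient", {
  sc <- generate_scene(synthetic_params(base_density = 8000,
                                        radial_gradient = 0.3,
                                        retina_radius_mm = 1.0,
                                        n_incisions = 0L,
                                        dark_patch_fraction = 0,
                                        cluster_fraction = 0, seed = 71))
  grid <- build_grid(sc, fx_acq, "full")
  res <- truth_field_results(sc, grid)
  map <- build_fundus(res, center = c(0, 0))
  prof <- radial_profile(map)
  # oracle: brute-force per-annulus mean of the same per-field truths
  tab <- conecounter:::results_table(res)
  r <- sqrt(tab$x_um^2 + tab$y_um^2)
  ann <- pmin(9L, pmax(1L, ceiling(r / (max(r) / 9))))
  oracle <- as.numeric(tapply(tab$density, factor(ann, levels = 1:9), mean))
  expect_equal(prof, oracle, tolerance = 1e-9, ignore_attr = TRUE)
  # centre denser than periphery, profile decreasing overall
  expect_gt(prof[1], prof[9])
  expect_lt(cor(seq_len(9), prof), -0.9)
})

test_that("rotating the layout with updated labels leaves profiles invariant", {
  tab <- mk_table(9, 9, function(x, y) 40 + x / 15 + y / 30)
  map <- build_fundus(tab, fundus_orientation("up", "left"))
  rot <- tab
  rot$x_um <- -tab$y_um; rot$y_um <- tab$x_um    # 90 degree rotation
  rot$row <- tab$col; rot$col <- max(tab$row) - tab$row
  map_rot <- build_fundus(rot, fundus_orientation("right", "up"))
  expect_equal(radial_profile(map_rot), radial_profile(map),
               ignore_attr = TRUE)
})

test_that("fundus exports produce a CSV and a PNG rendering", {
  tab <- mk_table(6, 6, 120)
  map <- build_fundus(tab)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_fundus_csv(map, csv)
  back <- read.csv(csv)
  expect_identical(nrow(back), nrow(tab))
  png <- withr::local_tempfile(fileext = ".png")
  plot_fundus(map, png)
  expect_gt(file.info(png)$size, 0)
})

test_that("regional geometry reproduces the printed areas and gap", {
  tabs <- lapply(1:3, function(i) mk_table(16, 13, 150))
  rc <- regional_comparison(tabs, acq = hq_acq)
  expect_equal(rc$region_area_mm2, 2.48)
  expect_equal(rc$gap_um, 335.4)
  expect_identical(rc$n_fields_per_region, 66L)
  small <- mk_table(6, 13, 150)
  expect_error(regional_comparison(list(small, small)),
               "insufficient grid extent")
})

test_that("a mirror-symmetric retina shows no dorsoventral difference", {
  set.seed(85)
  tabs <- lapply(1:8, function(i)
    mk_table(16, 13, function(x, y) 150 + rnorm(length(x), 0, 5)))
  rc <- regional_comparison(tabs)
  expect_lt(abs(mean(rc$per_retina$difference)), 5)
  expect_gt(rc$paired_test$p, 0.05)
})

test_that("a built-in ventral deficit is detected", {
  set.seed(87)
  h <- fx_acq$field_height_um
  tabs <- lapply(1:8, function(i)
    mk_table(16, 13, function(x, y)
      ifelse(y > 8 * h, 0.65, 1) * 200 + rnorm(length(x), 0, 6)))
  rc <- regional_comparison(tabs)
  expect_gt(rc$dorsal_mean, rc$ventral_mean)
  expect_lt(rc$paired_test$p, 0.05)
})
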