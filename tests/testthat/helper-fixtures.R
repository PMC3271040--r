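# Shared fixtures: all synthetic, built in code at test time.

fx_acq <- acquisition_config("coolsnap_fx")
hq_acq <- acquisition_config("coolsnap_hq")

# small camera for autofocus / rendering tests (same optics, fewer pixels)
small_acq <- acquisition_config("coolsnap_fx", width = 160L, height = 128L,
                                field_width_um = 53.6, field_height_um = 42.9)

# single-field scene: a small retina with one centred FX field
make_field_scene <- function(density_per_field, seed, acq = fx_acq, ...) {
  area <- field_area_mm2(acq, NULL)
  params <- synthetic_params(base_density = density_per_field / area,
                             retina_radius_mm = 0.25, n_incisions = 0L,
                             dark_patch_fraction = 0, cluster_fraction = 0,
                             seed = seed, ...)
  scene <- generate_scene(params)
  field <- field_coordinate(0L, 0L, 0, 0, index = 1L)
  truth <- field_truth_count(scene, -acq$field_width_um / 2,
                             -acq$field_height_um / 2,
                             acq$field_width_um, acq$field_height_um)
  list(scene = scene, field = field, truth = truth, acq = acq)
}

# independent connected-component labeling oracle: BFS flood fill,
# 4-connectivity (no dependence on the package's labeling path)
flood_fill_count <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  n <- 0L
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (!mask[i, j] || lab[i, j] > 0L) next
      n <- n + 1L
      queue <- list(c(i, j))
      lab[i, j] <- n
      while (length(queue) > 0) {
        p <- queue[[length(queue)]]
        queue[[length(queue)]] <- NULL
        for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 &&
              q[2] <= ncol(mask) && mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
            lab[q[1], q[2]] <- n
            queue[[length(queue) + 1L]] <- q
          }
        }
      }
    }
  }
  list(n = n, labels = lab)
}

# exhaustive Otsu oracle: direct between-class variance at every candidate
# level; the midpoint of the maximizing plateau is the threshold
brute_otsu <- function(img) {
  v <- as.numeric(img)
  n <- length(v)
  cands <- min(v):(max(v) - 1)
  bcv <- vapply(cands, function(t) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) return(-Inf)
    w0 <- length(lo) / n
    w0 * (1 - w0) * (mean(lo) - mean(hi))^2
  }, numeric(1))
  top <- which(bcv >= max(bcv) * (1 - 1e-12))
  cands[floor((min(top) + max(top)) / 2)]
}

# paint a filled disc of a given intensity onto an integer image matrix
paint_disc <- function(img, cy, cx, r, value) {
  ii <- pmax(1, floor(cy - r)):pmin(nrow(img), ceiling(cy + r))
  jj <- pmax(1, floor(cx - r)):pmin(ncol(img), ceiling(cx + r))
  for (i in ii) for (j in jj)
    if ((i - cy)^2 + (j - cx)^2 <= r^2) img[i, j] <- value
  img
}
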