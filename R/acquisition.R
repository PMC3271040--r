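# Acquisition geometry: grid construction, two-stage autofocus, stack I/O.

#' Build the acquisition grid over the retina
#'
#' Tiles the bounding box with non-overlapping, axis-aligned fields of the
#' camera's physical size, anchored at the top-left corner of the bounds.
#' `mode = "full"` keeps every cell intersecting the bounds (or the retinal
#' disc when a scene is supplied); `mode = "draughtboard"` keeps the
#' checkerboard subset with `(row + col)` even.
#'
#' @param x either a `retina_scene` (cells are kept if they intersect the
#'   retinal disc) or a numeric `c(xmin, xmax, ymin, ymax)` bounds vector
#'   in um.
#' @param acq an [acquisition_config()].
#' @param mode `"full"` or `"draughtboard"`.
#' @return An object of class `acquisition_grid`: list of
#'   [field_coordinate()]s plus `mode`, `acq` and `field_area_mm2`.
#' @examples
#' g <- build_grid(c(0, 435.5, 0, 345.06), acquisition_config("coolsnap_fx"))
#' length(g$fields)   # 2 x 2 fields
#' @export
build_grid <- function(x, acq, mode = c("full", "draughtboard")) {
  mode <- match.arg(mode)
  disc <- NULL
  if (inherits(x, "retina_scene")) {
    R <- x$radius_um
    bounds <- c(-R, R, -R, R)
    disc <- c(0, 0, R)
  } else {
    bounds <- as.numeric(x)
    stopifnot(length(bounds) == 4L)
  }
  w <- acq$field_width_um; h <- acq$field_height_um
  if (bounds[2] <= bounds[1] || bounds[4] <= bounds[3])
    stop("empty acquisition bounds")
  n_col <- max(1L, ceiling((bounds[2] - bounds[1]) / w - 1e-9))
  n_row <- max(1L, ceiling((bounds[4] - bounds[3]) / h - 1e-9))
  fields <- list()
  idx <- 0L
  for (r in seq_len(n_row) - 1L) {
    for (cc in seq_len(n_col) - 1L) {
      if (mode == "draughtboard" && (r + cc) %% 2L != 0L) next
      x0 <- bounds[1] + cc * w
      y0 <- bounds[3] + r * h
      if (!is.null(disc)) {
        # exact rectangle-disc intersection test
        dx <- max(x0 - disc[1], 0, disc[1] - (x0 + w))
        dy <- max(y0 - disc[2], 0, disc[2] - (y0 + h))
        if (dx^2 + dy^2 > disc[3]^2) next
      }
      idx <- idx + 1L
      fields[[idx]] <- field_coordinate(r, cc, x0 + w / 2, y0 + h / 2,
                                        index = idx)
    }
  }
  if (idx == 0L) stop("no grid cell intersects the retina")
  structure(list(fields = fields, mode = mode, acq = acq,
                 field_area_mm2 = field_area_mm2(acq, NULL)),
            class = "acquisition_grid")
}

#' @export
print.acquisition_grid <- function(x, ...) {
  cat(sprintf("acquisition_grid [%s]: %d fields of %.4f mm^2\n",
              x$mode, length(x$fields), x$field_area_mm2))
  invisible(x)
}

# Sharpness statistic for autofocus: pixel-intensity variance.
# Offset-invariant, so the focus decision is unaffected by a constant
# illumination shift.
focus_metric <- function(img) var(as.numeric(img))

#' Two-stage autofocus
#'
#' Recovers the focal plane of a field by two argmax scans of the focus
#' metric: a coarse pass of `af$coarse_n` planes spaced `af$coarse_step_um`
#' around `z_start_um` (three below, the start, and the remainder above),
#' then a fine pass of `af$fine_n` planes spaced `af$fine_step_um` around
#' the coarse optimum. Probe planes are rendered noise-free so the decision
#' is deterministic. Ties (e.g. a coneless, structureless field) return
#' `z_start_um` with `tie = TRUE`; among distinct maxima the lowest z wins.
#'
#' @param scene a `retina_scene`.
#' @param field a [field_coordinate()].
#' @param z_start_um starting focal position, um.
#' @param af an [autofocus_config()].
#' @param acq an [acquisition_config()].
#' @return List with `z_best_um`, `tie` (logical), `coarse_z_um`, and the
#'   probed `z` / metric values of both stages.
#' @export
two_stage_autofocus <- function(scene, field, z_start_um,
                                af = autofocus_config(),
                                acq = acquisition_config()) {
  scan <- function(z_center, n, step) {
    below <- ceiling((n - 1) / 2)
    zs <- z_center + (seq_len(n) - 1L - below) * step
    vals <- vapply(zs, function(z)
      focus_metric(render_plane(scene, field, acq, z)), numeric(1))
    list(z = zs, metric = vals)
  }
  s1 <- scan(z_start_um, af$coarse_n, af$coarse_step_um)
  tie1 <- diff(range(s1$metric)) <= 1e-9 * max(1, max(s1$metric))
  if (tie1)
    return(list(z_best_um = z_start_um, tie = TRUE,
                coarse_z_um = z_start_um, coarse = s1, fine = NULL))
  z1 <- s1$z[which.max(s1$metric)]   # which.max: lowest index on ties
  s2 <- scan(z1, af$fine_n, af$fine_step_um)
  tie2 <- diff(range(s2$metric)) <= 1e-9 * max(1, max(s2$metric))
  z2 <- if (tie2) z1 else s2$z[which.max(s2$metric)]
  list(z_best_um = z2, tie = FALSE, coarse_z_um = z1, coarse = s1, fine = s2)
}

#' Write a Z-stack as a multi-page 16-bit TIFF
#'
#' One grayscale page per focal plane, written uncompressed. Files are named
#' `YYYYMMDD_<zero-padded index>.tif` (date of the day, overridable for
#' reproducibility). Stage coordinates are recorded in the per-acquisition
#' CSV index `stack_index.csv` alongside the stacks, from which
#' [read_stack()] recovers them.
#'
#' @param stack a `zstack`.
#' @param directory output directory (created if missing).
#' @param index acquisition increment used in the filename; defaults to the
#'   field's index.
#' @param date a `Date` for the filename prefix; defaults to today.
#' @return The path of the written TIFF, invisibly.
#' @export
write_stack <- function(stack, directory, index = stack$field$index,
                        date = Sys.Date()) {
  stopifnot(inherits(stack, "zstack"), !is.na(index))
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  fn <- sprintf("%s_%04d.tif", format(date, "%Y%m%d"), as.integer(index))
  path <- file.path(directory, fn)
  tiff::writeTIFF(lapply(stack$planes, function(m) m / 65535),
                  path, bits.per.sample = 16L, compression = "none")
  idx_path <- file.path(directory, "stack_index.csv")
  row <- data.frame(field_index = as.integer(index),
                    row = stack$field$row, col = stack$field$col,
                    x_um = stack$field$x_um, y_um = stack$field$y_um,
                    z_um = stack$z_center_um, filename = fn)
  if (file.exists(idx_path)) {
    old <- read.csv(idx_path)
    old <- old[old$filename != fn, , drop = FALSE]
    row <- rbind(old, row)
    row <- row[order(row$field_index), , drop = FALSE]
  }
  write.csv(row, idx_path, row.names = FALSE)
  invisible(path)
}

#' Read a multi-page TIFF Z-stack
#'
#' Validates page count and bit depth against the acquisition configuration
#' and recovers the stage coordinates from the `stack_index.csv` sitting
#' next to the file (if present). `read_stack(write_stack(s))` is
#' bit-identical to `s`.
#'
#' @param path TIFF path.
#' @param acq an [acquisition_config()]; page count and bit depth are
#'   checked against it.
#' @return A `zstack`.
#' @export
read_stack <- function(path, acq = acquisition_config()) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (length(pages) != acq$n_planes)
    stop(sprintf("format error in '%s': %d pages, expected %d",
                 path, length(pages), acq$n_planes))
  bps <- attr(pages[[1]], "bits.per.sample")
  if (!is.null(bps) && bps != acq$bit_depth)
    stop(sprintf("format error in '%s': %d bits per sample, expected %d",
                 path, bps, acq$bit_depth))
  planes <- lapply(pages, function(p) {
    m <- matrix(as.integer(p), nrow(p), ncol(p))
    if (nrow(m) != acq$height || ncol(m) != acq$width)
      stop(sprintf("format error in '%s': page is %d x %d px, expected %d x %d",
                   path, ncol(m), nrow(m), acq$width, acq$height))
    m
  })
  fld <- field_coordinate(NA_integer_, NA_integer_, NA_real_, NA_real_)
  z_center <- NA_real_
  idx_path <- file.path(dirname(path), "stack_index.csv")
  if (file.exists(idx_path)) {
    idx <- read.csv(idx_path)
    hit <- idx[idx$filename == basename(path), , drop = FALSE]
    if (nrow(hit) == 1) {
      fld <- field_coordinate(hit$row, hit$col, hit$x_um, hit$y_um,
                              hit$z_um, hit$field_index)
      z_center <- hit$z_um
    }
  }
  structure(list(planes = planes, field = fld, acq = acq,
                 z_center_um = z_center,
                 z_offsets_um = plane_offsets_um(acq)),
            class = "zstack")
}
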