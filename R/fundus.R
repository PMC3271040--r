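# Virtual eye fundus: annulus-by-segment spatial density representation,
# radial profiles, and the dorsal-versus-ventral regional comparison.

#' Retina orientation on the acquisition grid
#'
#' Records which grid axis points dorsally and which nasally (they must be
#' perpendicular), and which eye the retina comes from. Grid coordinates
#' have x rightward and y downward, so `dorsal = "up"` means dorsal fields
#' have smaller y.
#'
#' @param dorsal one of `"up"`, `"down"`, `"left"`, `"right"`.
#' @param nasal one of the two directions perpendicular to `dorsal`.
#' @param eye `"left"` or `"right"`.
#' @return An object of class `fundus_orientation`.
#' @export
fundus_orientation <- function(dorsal = "up", nasal = NULL,
                               eye = c("left", "right")) {
  dorsal <- match.arg(dorsal, c("up", "down", "left", "right"))
  perp <- if (dorsal %in% c("up", "down")) c("left", "right")
          else c("up", "down")
  if (is.null(nasal)) nasal <- perp[1]
  nasal <- match.arg(nasal, perp)
  structure(list(dorsal = dorsal, nasal = nasal, eye = match.arg(eye)),
            class = "fundus_orientation")
}

#' Fundus configuration
#'
#' Nine concentric annuli around the optic nerve; per-cell densities are
#' colour-binned at multiples of 45: (0, 45], (45, 90], ..., (360, 405]
#' cones per field area. Densities at an exact bin edge go to the lower bin;
#' a count of 0 maps to the lowest bin; densities above 405 saturate in the
#' top bin. Excluded fields are rendered grey.
#'
#' @param n_rows number of annuli (9).
#' @param bin_step colour-bin step (45).
#' @param n_bins number of bins (9; upper edges 45..405).
#' @return An object of class `fundus_config`.
#' @export
fundus_config <- function(n_rows = 9L, bin_step = 45, n_bins = 9L) {
  stopifnot(n_rows >= 1, bin_step > 0, n_bins >= 1)
  structure(list(n_rows = as.integer(n_rows), bin_step = bin_step,
                 n_bins = as.integer(n_bins),
                 bin_edges = bin_step * seq_len(n_bins)),
            class = "fundus_config")
}

# Colour bin of a density: left-open intervals, 0 -> bin 1, cap at n_bins.
density_bin <- function(d, cfg = fundus_config()) {
  as.integer(pmin(cfg$n_bins, pmax(1L, ceiling(d / cfg$bin_step))))
}

# Normalize a list of field_result (or an already-tabular data frame) into
# the per-field results table.
results_table <- function(results) {
  if (is.data.frame(results)) return(results)
  rows <- lapply(results, function(r) {
    data.frame(field_index = r$field$index, row = r$field$row,
               col = r$field$col, x_um = r$field$x_um, y_um = r$field$y_um,
               z_um = r$field$z_um,
               accepted = r$qc$accepted,
               reasons = paste(r$qc$reasons, collapse = ";"),
               count = ifelse(r$qc$accepted, r$count, NA_integer_),
               density = ifelse(r$qc$accepted, r$density_per_field, NA_real_),
               density_per_mm2 = ifelse(r$qc$accepted, r$density_per_mm2,
                                        NA_real_),
               mean_intensity = r$qc$measures$mean_intensity,
               threshold = r$qc$measures$threshold,
               area_pct = r$qc$measures$area_pct,
               n_prelim = r$qc$measures$n_prelim,
               bg_mean = r$qc$measures$bg_mean,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Locate the optic nerve centre from the field coordinates
#'
#' Centroid of the accepted-field stage coordinates, overridable by an
#' explicit operator-supplied centre.
#'
#' @param results list of `field_result`s or a results table.
#' @param override optional `c(x, y)` um to use instead.
#' @return Named numeric `c(x_um, y_um)`.
#' @export
locate_center <- function(results, override = NULL) {
  if (!is.null(override))
    return(c(x_um = override[1], y_um = override[2]))
  tab <- results_table(results)
  acc <- tab[tab$accepted, , drop = FALSE]
  if (nrow(acc) == 0) stop("no accepted fields: cannot locate the centre")
  c(x_um = mean(acc$x_um), y_um = mean(acc$y_um))
}

#' Build the virtual eye fundus map
#'
#' Assigns every field to one of nine concentric annuli by the radial
#' distance of its centre from the optic nerve (equal radial widths,
#' `r_step = max radius / 9`; row 9 outermost) and to a grid-aligned
#' angular segment (fields within an annulus ordered by angle). Accepted
#' fields carry their density and colour bin; excluded fields are flagged
#' (grey in the rendering).
#'
#' @param results list of `field_result`s or a results table.
#' @param orientation a [fundus_orientation()].
#' @param cfg a [fundus_config()].
#' @param center optional explicit centre `c(x, y)` um.
#' @return An object of class `fundus_map`: `cells` data frame (`row`,
#'   `segment`, `field_index`, `r_um`, `angle`, `density`, `bin`,
#'   `excluded`), `center`, `orientation`, `cfg`, `r_step_um`.
#' @export
build_fundus <- function(results, orientation = fundus_orientation(),
                         cfg = fundus_config(), center = NULL) {
  tab <- results_table(results)
  ctr <- locate_center(tab, override = center)
  dx <- tab$x_um - ctr["x_um"]
  dy <- tab$y_um - ctr["y_um"]
  r <- sqrt(dx^2 + dy^2)
  rmax <- max(r[tab$accepted], r)
  r_step <- max(rmax, 1e-9) / cfg$n_rows
  row_ann <- pmin(cfg$n_rows, pmax(1L, ceiling(r / r_step)))
  angle <- atan2(dy, dx) %% (2 * pi)
  cells <- data.frame(row = row_ann, angle = angle, r_um = r,
                      field_index = tab$field_index,
                      density = tab$density,
                      excluded = !tab$accepted,
                      x_um = tab$x_um, y_um = tab$y_um,
                      stringsAsFactors = FALSE)
  cells <- cells[order(cells$row, cells$angle), , drop = FALSE]
  cells$segment <- stats::ave(seq_len(nrow(cells)), cells$row,
                              FUN = seq_along)
  cells$bin <- ifelse(cells$excluded, NA_integer_,
                      density_bin(cells$density, cfg))
  rownames(cells) <- NULL
  structure(list(cells = cells, center = ctr, orientation = orientation,
                 cfg = cfg, r_step_um = r_step),
            class = "fundus_map")
}

#' @export
print.fundus_map <- function(x, ...) {
  cat(sprintf("fundus_map: %d fields in %d annuli around (%.0f, %.0f) um (r_step %.0f um)\n",
              nrow(x$cells), x$cfg$n_rows, x$center["x_um"], x$center["y_um"],
              x$r_step_um))
  invisible(x)
}

#' Per-annulus radial density profile
#'
#' Mean density of the accepted cells in each of the nine annuli.
#'
#' @param map a [build_fundus()] result.
#' @param from `"central"` (row 1 first) or `"peripheral"` (row 9 first).
#' @return Numeric vector of length `n_rows` (NA with attribute
#'   `empty_rows` where an annulus holds no accepted field).
#' @export
radial_profile <- function(map, from = c("central", "peripheral")) {
  from <- match.arg(from)
  cfg <- map$cfg
  acc <- map$cells[!map$cells$excluded, , drop = FALSE]
  prof <- rep(NA_real_, cfg$n_rows)
  if (nrow(acc) > 0) {
    m <- tapply(acc$density, factor(acc$row, levels = seq_len(cfg$n_rows)),
                mean)
    prof <- as.numeric(m)
  }
  if (from == "peripheral") prof <- rev(prof)
  structure(prof, empty_rows = which(is.na(prof)))
}

#' Export a fundus map as CSV
#' @param map a `fundus_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fundus_csv <- function(map, path) {
  write.csv(map$cells[, c("row", "segment", "field_index", "r_um", "angle",
                          "density", "bin", "excluded")],
            path, row.names = FALSE)
  invisible(path)
}

#' Render the virtual eye fundus
#'
#' Disk rendering with one annular sector per field, coloured by the
#' 9-level scale (dark blue through yellow to dark red at multiples of 45);
#' excluded fields are grey. Dorsal/ventral/nasal/temporal labels follow
#' the orientation.
#'
#' @param map a `fundus_map`.
#' @param file optional PNG path; `NULL` draws on the current device.
#' @return The colour palette used, invisibly.
#' @export
plot_fundus <- function(map, file = NULL) {
  pal <- colorRampPalette(c("#08306b", "#2171b5", "#41b6c4", "#a1dab4",
                            "#ffffb2", "#fecc5c", "#fd8d3c", "#e31a1c",
                            "#800026"))(map$cfg$n_bins)
  if (!is.null(file)) {
    grDevices::png(file, width = 700, height = 700)
    on.exit(grDevices::dev.off())
  }
  plot.new()
  R <- map$cfg$n_rows * map$r_step_um
  plot.window(c(-1.25 * R, 1.25 * R), c(-1.25 * R, 1.25 * R), asp = 1)
  cells <- map$cells
  for (rr in seq_len(map$cfg$n_rows)) {
    ring <- cells[cells$row == rr, , drop = FALSE]
    if (nrow(ring) == 0) next
    # sector boundaries midway between neighbouring field angles
    a <- ring$angle
    bnd <- if (nrow(ring) == 1) cbind(a - pi, a + pi) else {
      mid <- (a + c(a[-1], a[1] + 2 * pi)) / 2
      cbind(c(mid[length(mid)] - 2 * pi, mid[-length(mid)]), mid)
    }
    for (i in seq_len(nrow(ring))) {
      th <- seq(bnd[i, 1], bnd[i, 2], length.out = 20)
      r0 <- (rr - 1) * map$r_step_um; r1 <- rr * map$r_step_um
      col <- if (ring$excluded[i]) gray(0.6) else pal[ring$bin[i]]
      polygon(c(r0 * cos(th), rev(r1 * cos(th))),
              c(r0 * sin(th), rev(r1 * sin(th))), col = col, border = NA)
    }
  }
  lab <- switch(map$orientation$dorsal, up = c("D", "V"), down = c("V", "D"),
                left = c("D", "V"), right = c("V", "D"))
  nas <- switch(map$orientation$nasal, left = c("N", "T"),
                right = c("T", "N"), up = c("N", "T"), down = c("T", "N"))
  if (map$orientation$dorsal %in% c("up", "down")) {
    text(0, -1.15 * R, lab[1]); text(0, 1.15 * R, lab[2])
    text(-1.15 * R, 0, nas[1]); text(1.15 * R, 0, nas[2])
  } else {
    text(-1.15 * R, 0, lab[1]); text(1.15 * R, 0, lab[2])
    text(0, -1.15 * R, nas[1]); text(0, 1.15 * R, nas[2])
  }
  invisible(pal)
}

#' Dorsal-versus-ventral regional comparison
#'
#' Builds two mirrored blocks of `n_rows x n_cols` fields (66 by default),
#' centred on the dorso-ventral axis, equidistant from the optic nerve and
#' separated by a two-row gap, and compares their mean densities across
#' retinas with a paired t-test (pairing by retina).
#'
#' @param results_list list with one element per retina, each a list of
#'   `field_result`s or a results table.
#' @param orientation a [fundus_orientation()].
#' @param acq an [acquisition_config()] (region area, gap in um).
#' @param n_rows,n_cols block geometry (6 x 11 = 66 fields).
#' @param gap_rows rows separating the blocks (2).
#' @return An object of class `regional_comparison`: per-retina dorsal and
#'   ventral means, paired differences, the [paired_t()] result, region
#'   area in mm^2, and the gap in um.
#' @export
regional_comparison <- function(results_list,
                                orientation = fundus_orientation(),
                                acq = acquisition_config(),
                                n_rows = 6L, n_cols = 11L, gap_rows = 2L) {
  if (inherits(results_list, "field_result") || is.data.frame(results_list) ||
      (is.list(results_list) && length(results_list) > 0 &&
       inherits(results_list[[1]], "field_result")))
    results_list <- list(results_list)
  one <- function(results) {
    tab <- results_table(results)
    ctr <- locate_center(tab)
    # canonical coordinates: v increases toward ventral, u along the blocks
    sw <- switch(orientation$dorsal,
                 up = list(v = tab$row, u = tab$col),
                 down = list(v = -tab$row, u = tab$col),
                 left = list(v = tab$col, u = tab$row),
                 right = list(v = -tab$col, u = tab$row))
    # centre field = nearest accepted field to the centroid
    d2 <- (tab$x_um - ctr["x_um"])^2 + (tab$y_um - ctr["y_um"])^2
    i0 <- which.min(d2)
    v0 <- sw$v[i0]; u0 <- sw$u[i0]
    gap_lo <- v0 - floor(gap_rows / 2) + 1L   # gap rows: gap_lo..gap_lo+gap_rows-1
    dorsal_v <- (gap_lo - n_rows):(gap_lo - 1L)
    ventral_v <- (gap_lo + gap_rows):(gap_lo + gap_rows + n_rows - 1L)
    ucols <- (u0 - (n_cols - 1L) %/% 2L):(u0 + n_cols %/% 2L)
    pick <- function(vs) {
      sel <- sw$v %in% vs & sw$u %in% ucols
      if (sum(sel) < n_rows * n_cols)
        stop(sprintf(paste0("insufficient grid extent for the regional ",
                            "blocks: %d of %d fields present (need %d rows ",
                            "x %d cols per block)"),
                     sum(sel), n_rows * n_cols, n_rows, n_cols))
      tab[sel, , drop = FALSE]
    }
    dor <- pick(dorsal_v); ven <- pick(ventral_v)
    c(dorsal = mean(dor$density, na.rm = TRUE),
      ventral = mean(ven$density, na.rm = TRUE))
  }
  per <- t(vapply(results_list, one, numeric(2)))
  test <- if (nrow(per) >= 2)
    paired_t(per[, "dorsal"], per[, "ventral"]) else NULL
  structure(list(per_retina = data.frame(retina = seq_len(nrow(per)),
                                         dorsal = per[, "dorsal"],
                                         ventral = per[, "ventral"],
                                         difference = per[, "dorsal"] -
                                           per[, "ventral"]),
                 dorsal_mean = mean(per[, "dorsal"]),
                 ventral_mean = mean(per[, "ventral"]),
                 paired_test = test,
                 n_fields_per_region = n_rows * n_cols,
                 region_area_mm2 = round(n_rows * n_cols *
                                           field_area_mm2(acq, NULL), 2),
                 gap_um = gap_rows * acq$field_height_um),
            class = "regional_comparison")
}

#' @export
print.regional_comparison <- function(x, ...) {
  cat(sprintf("regional_comparison: dorsal %.1f vs ventral %.1f cones/field over %d retinas (region %.2f mm^2, gap %.1f um)\n",
              x$dorsal_mean, x$ventral_mean, nrow(x$per_retina),
              x$region_area_mm2, x$gap_um))
  if (!is.null(x$paired_test))
    cat(sprintf("  paired t: t = %.3f, df = %d, p = %.4g\n",
                x$paired_test$t, x$paired_test$df, x$paired_test$p))
  invisible(x)
}
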