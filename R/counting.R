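# Retina-level density estimation: global, automated-stereological
# (unbiased counting frame), and systematic-random-sampling stereology.

#' Unbiased counting frame
#'
#' A square frame drawn inside each field with two forbidden ("exclusion")
#' edges -- left and top: objects in contact with either are not counted, so
#' that over a tiling of the plane each object is counted exactly once.
#'
#' @param width_um,height_um frame size, um (default 30 x 30 um, 900 um^2).
#' @param placement `"centered"`: the frame is centred in the field.
#' @return An object of class `counting_frame`.
#' @export
counting_frame <- function(width_um = 30, height_um = 30,
                           placement = "centered") {
  stopifnot(width_um > 0, height_um > 0)
  structure(list(width_um = width_um, height_um = height_um,
                 placement = match.arg(placement, "centered"),
                 forbidden = c("left", "top")),
            class = "counting_frame")
}

# Frame rectangle in field pixel coordinates: c(x0, y0, x1, y1).
frame_rect_px <- function(frame, acq, offset_px = NULL) {
  pxx <- acq$field_width_um / acq$width
  pxy <- acq$field_height_um / acq$height
  w <- frame$width_um / pxx
  h <- frame$height_um / pxy
  if (w > acq$width || h > acq$height)
    stop("counting frame larger than the field")
  if (is.null(offset_px))
    offset_px <- c((acq$width - w) / 2, (acq$height - h) / 2)
  c(x0 = offset_px[1], y0 = offset_px[2],
    x1 = offset_px[1] + w, y1 = offset_px[2] + h)
}

# Distance from points to an axis-aligned segment.
dist_point_vseg <- function(px, py, x, y0, y1) {
  dy <- pmax(y0 - py, 0, py - y1)
  sqrt((px - x)^2 + dy^2)
}
dist_point_hseg <- function(px, py, y, x0, x1) {
  dx <- pmax(x0 - px, 0, px - x1)
  sqrt((py - y)^2 + dx^2)
}

#' Count objects inside an unbiased counting frame
#'
#' Applies the forbidden-edge rule to detected objects, each represented by
#' its centroid and equivalent-disc footprint radius: an object is counted
#' if its footprint intersects the frame and does not touch the left or top
#' (forbidden) edge; touching only the right/bottom (permitted) edges is
#' allowed. Objects already rejected by the detection filters are ignored;
#' frame-excluded objects are reported with status `EXCLUDED_FRAME`.
#'
#' @param objects a spot-object data frame from [find_spots()] (needs
#'   `cx_px`, `cy_px`, `r_eq_px`, `status`).
#' @param frame a [counting_frame()].
#' @param acq an [acquisition_config()] (frame placement and unit
#'   conversion).
#' @param offset_px optional frame top-left corner in px (default centered).
#' @return List: `count`, `status` (per input object: `COUNTED`,
#'   `EXCLUDED_FRAME`, `OUTSIDE_FRAME`, or the original rejection code) and
#'   the frame rectangle in px.
#' @export
frame_count <- function(objects, frame, acq = acquisition_config(),
                        offset_px = NULL) {
  rect <- frame_rect_px(frame, acq, offset_px)
  n <- nrow(objects)
  status <- rep("OUTSIDE_FRAME", n)
  if (n > 0) {
    keep <- objects$status == "COUNTED"
    status[!keep] <- objects$status[!keep]
    cx <- objects$cx_px; cy <- objects$cy_px; r <- objects$r_eq_px
    # footprint intersects the frame rectangle?
    ddx <- pmax(rect["x0"] - cx, 0, cx - rect["x1"])
    ddy <- pmax(rect["y0"] - cy, 0, cy - rect["y1"])
    hits <- keep & (ddx^2 + ddy^2 <= r^2)
    touch_left <- dist_point_vseg(cx, cy, rect["x0"], rect["y0"],
                                  rect["y1"]) <= r
    touch_top <- dist_point_hseg(cx, cy, rect["y0"], rect["x0"],
                                 rect["x1"]) <= r
    status[hits & (touch_left | touch_top)] <- "EXCLUDED_FRAME"
    status[hits & !(touch_left | touch_top)] <- "COUNTED"
  }
  list(count = sum(status == "COUNTED"), status = status, rect_px = rect)
}

#' Global density over the counted fields
#'
#' Mean per-field cone count over the accepted fields; excluded fields
#' contribute to neither numerator nor denominator.
#'
#' @param results list of `field_result`s.
#' @return An object of class `density_summary`: number of counted and
#'   excluded fields, mean density per field area, density per mm^2, total
#'   count, and the field area used.
#' @export
global_density <- function(results) {
  acc <- Filter(function(r) isTRUE(r$qc$accepted), results)
  n_exc <- length(results) - length(acc)
  if (length(acc) == 0)
    stop("no accepted fields: cannot estimate a density")
  counts <- vapply(acc, function(r) as.numeric(r$count), numeric(1))
  area <- acc[[1]]$field_area_mm2
  structure(list(method = "global",
                 n_fields_counted = length(acc),
                 n_fields_excluded = n_exc,
                 total_count = sum(counts),
                 mean_density_per_field = mean(counts),
                 mean_density_per_mm2 = mean(counts) / area,
                 field_area_mm2 = area),
            class = "density_summary")
}

#' @export
print.density_summary <- function(x, ...) {
  cat(sprintf("density_summary [%s]: %.2f cones per %.4f mm^2 field (%d counted, %d excluded)\n",
              x$method, x$mean_density_per_field, x$field_area_mm2,
              x$n_fields_counted, x$n_fields_excluded))
  if (!is.null(x$mean_density_per_frame))
    cat(sprintf("  frame: %.3f cones per %.0f um^2 frame (%.2f per field-area equivalent)\n",
                x$mean_density_per_frame, x$frame_area_um2,
                x$mean_density_per_field_equiv))
  invisible(x)
}

#' Automated stereological density
#'
#' Counting-frame estimate on draughtboard fields: within each accepted
#' field a centred unbiased frame is applied to the detected objects and the
#' per-frame counts are averaged. Densities are reported per frame area
#' (900 um^2 by default) and rescaled to the per-field-area unit for
#' comparison with the global method.
#'
#' @param results list of `field_result`s (typically from a draughtboard
#'   grid).
#' @param frame a [counting_frame()].
#' @param acq an [acquisition_config()].
#' @return A `density_summary` with per-frame and per-field-equivalent
#'   densities.
#' @export
stereo_automated_density <- function(results, frame = counting_frame(),
                                     acq = acquisition_config()) {
  acc <- Filter(function(r) isTRUE(r$qc$accepted), results)
  n_exc <- length(results) - length(acc)
  if (length(acc) == 0)
    stop("no accepted fields: cannot estimate a density")
  fcounts <- vapply(acc, function(r)
    as.numeric(frame_count(r$objects, frame, acq)$count), numeric(1))
  frame_area <- frame$width_um * frame$height_um
  field_area_um2 <- acq$field_width_um * acq$field_height_um
  structure(list(method = "stereo_automated",
                 n_fields_counted = length(acc),
                 n_fields_excluded = n_exc,
                 total_count = sum(fcounts),
                 mean_density_per_frame = mean(fcounts),
                 frame_area_um2 = frame_area,
                 mean_density_per_field_equiv =
                   mean(fcounts) * field_area_um2 / frame_area,
                 mean_density_per_field =
                   mean(fcounts) * field_area_um2 / frame_area,
                 mean_density_per_mm2 = mean(fcounts) / (frame_area / 1e6),
                 field_area_mm2 = field_area_um2 / 1e6),
            class = "density_summary")
}

#' Systematic random sampling of stereological fields
#'
#' Places 35 x 35 um (1,225 um^2) non-overlapping fields on a square
#' lattice with a seeded random start offset, keeping those falling inside
#' the retinal mask intersected with a disc of `radius_um` around the optic
#' nerve centre. The lattice stride is chosen so that between 50 and 80
#' fields are expected (target 65).
#'
#' @param scene a `retina_scene` (supplies the tissue mask).
#' @param optic_center_um `c(x, y)` of the optic nerve head, um.
#' @param n_fields_target target number of fields (default 65).
#' @param field_side_um field side, um (default 35: 1,225 um^2).
#' @param radius_um sampling radius around the centre (default 2000).
#' @param seed integer seed for the start offset.
#' @return Data frame of field rectangles: `x0`, `y0`, `side_um`.
#' @export
systematic_random_sample <- function(scene, optic_center_um = c(0, 0),
                                     n_fields_target = 65,
                                     field_side_um = 35,
                                     radius_um = 2000, seed = 1L) {
  stopifnot(inherits(scene, "retina_scene"))
  R <- radius_um
  stride <- ceiling(sqrt(pi * R^2 / n_fields_target))
  local_seed(seed, {
    off <- runif(2, 0, stride)
    xs <- seq(optic_center_um[1] - R + off[1], optic_center_um[1] + R,
              by = stride)
    ys <- seq(optic_center_um[2] - R + off[2], optic_center_um[2] + R,
              by = stride)
    gg <- expand.grid(x0 = xs, y0 = ys)
    # keep fields fully inside the sampling disc and on tissue (all corners)
    cx <- gg$x0 + field_side_um / 2 - optic_center_um[1]
    cy <- gg$y0 + field_side_um / 2 - optic_center_um[2]
    half_diag <- field_side_um / sqrt(2)
    inside_disc <- sqrt(cx^2 + cy^2) + half_diag <= R
    on_tissue <- point_in_mask(scene$params, gg$x0, gg$y0) &
      point_in_mask(scene$params, gg$x0 + field_side_um, gg$y0) &
      point_in_mask(scene$params, gg$x0, gg$y0 + field_side_um) &
      point_in_mask(scene$params, gg$x0 + field_side_um,
                    gg$y0 + field_side_um)
    out <- gg[inside_disc & on_tissue, , drop = FALSE]
    if (nrow(out) < 50)
      stop(sprintf(paste0("mask too small for systematic sampling: only %d ",
                          "fields achievable (50 required)"), nrow(out)))
    if (nrow(out) > 80) out <- out[seq_len(80), , drop = FALSE]
    out$side_um <- field_side_um
    rownames(out) <- NULL
    out
  })
}

#' Ground-truth field results from a scene
#'
#' Builds the per-field results the estimators consume directly from the
#' simulator's ground truth (every cone becomes a counted object at its
#' true position), bypassing image rendering and detection. Useful for
#' validating the aggregation and counting-frame layer at scales where
#' rendering every field would be wasteful.
#'
#' @param scene a `retina_scene`.
#' @param grid an [build_grid()] result.
#' @return List of `field_result`s (all accepted).
#' @export
truth_field_results <- function(scene, grid) {
  acq <- grid$acq
  pxx <- acq$field_width_um / acq$width
  pxy <- acq$field_height_um / acq$height
  qc <- structure(list(accepted = TRUE, reasons = character(0),
                       measures = list(mean_intensity = NA_real_,
                                       dark_measure = NA_real_,
                                       threshold = NA_integer_,
                                       threshold_degenerate = FALSE,
                                       area_pct = NA_real_,
                                       n_prelim = NA_integer_,
                                       bg_mean = NA_real_)),
                  class = "qc_decision")
  area_mm2 <- field_area_mm2(acq, NULL)
  lapply(grid$fields, function(f) {
    rect <- field_rect(f, acq)
    co <- scene$cones
    sel <- co$x_um >= rect["x0"] & co$x_um < rect["x0"] + rect["w"] &
           co$y_um >= rect["y0"] & co$y_um < rect["y0"] + rect["h"]
    co <- co[sel, , drop = FALSE]
    objects <- data.frame(cx_px = (co$x_um - rect["x0"]) / pxx,
                          cy_px = (co$y_um - rect["y0"]) / pxy,
                          area_px = pi * (co$radius_um / pxx)^2,
                          mean_intensity = co$intensity,
                          peak_intensity = co$intensity,
                          circularity = rep(1, nrow(co)),
                          r_eq_px = co$radius_um / pxx,
                          status = rep("COUNTED", nrow(co)),
                          stringsAsFactors = FALSE)
    structure(list(field = f, qc = qc, count = nrow(co), objects = objects,
                   density_per_field = nrow(co),
                   density_per_mm2 = nrow(co) / area_mm2,
                   field_area_mm2 = area_mm2),
              class = "field_result")
  })
}

#' Stereological density from a systematic random sample
#'
#' Ground-truth-free estimator on sampled 1,225 um^2 fields: counts the
#' objects (or ground-truth cones, when given a scene) per sampled field
#' and averages.
#'
#' @param scene a `retina_scene`.
#' @param fields data frame from [systematic_random_sample()].
#' @return A `density_summary` (per 1,225 um^2 field and per mm^2).
#' @export
sampled_stereo_density <- function(scene, fields) {
  counts <- mapply(function(x0, y0, s)
    field_truth_count(scene, x0, y0, s, s),
    fields$x0, fields$y0, fields$side_um)
  area_um2 <- fields$side_um[1]^2
  structure(list(method = "stereo_sampled",
                 n_fields_counted = nrow(fields),
                 n_fields_excluded = 0L,
                 total_count = sum(counts),
                 mean_density_per_field = mean(counts),
                 mean_density_per_mm2 = mean(counts) / (area_um2 / 1e6),
                 field_area_mm2 = area_um2 / 1e6),
            class = "density_summary")
}
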