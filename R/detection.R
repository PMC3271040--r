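# The counting chain: projection, auto-threshold, field QC, tile-local
# thresholding, and find-spot object detection.

#' Best-focus projection of a Z-stack
#'
#' Pixelwise maximum across the planes: one sharp composite in which each
#' cone appears once as a transversal section through the cell body,
#' whatever its orientation or twist in depth.
#'
#' @param stack a `zstack` (or a plain list of equally sized matrices).
#' @return Integer matrix with the shape and bit depth of one plane.
#' @export
best_focus_projection <- function(stack) {
  planes <- if (inherits(stack, "zstack")) stack$planes else stack
  stopifnot(length(planes) >= 1)
  out <- planes[[1]]
  for (p in planes[-1]) out <- pmax(out, p)
  out
}

#' Otsu auto-threshold on the 16-bit histogram
#'
#' Exhaustively maximizes the between-class variance over the integer
#' histogram (0..65535); the returned level `t` separates background
#' (`x <= t`) from signal (`x > t`). Deterministic; when the between-class
#' variance is maximized on a plateau of levels (e.g. a gap between two
#' populations) the plateau midpoint is returned, placing the cut between
#' the classes. A constant image returns that constant with attribute
#' `degenerate = TRUE`.
#'
#' @param image integer matrix (0..65535).
#' @return Integer threshold level, with attribute `degenerate`.
#' @export
auto_threshold <- function(image) {
  v <- as.integer(image)
  stopifnot(length(v) > 0, all(v >= 0), all(v <= 65535))
  lo <- min(v); hi <- max(v)
  if (lo == hi)
    return(structure(lo, degenerate = TRUE))
  counts <- tabulate(v - lo + 1L, nbins = hi - lo + 1L)
  n <- length(v)
  levels <- seq.int(lo, hi)
  w0 <- cumsum(counts)
  m0 <- cumsum(counts * as.numeric(levels))
  mt <- m0[length(m0)]
  valid <- w0 > 0 & w0 < n
  # between-class variance: (mt*w0/n - m0)^2 / (w0/n * (1 - w0/n)) / n
  bcv <- rep(-Inf, length(levels))
  bcv[valid] <- (mt * w0[valid] / n - m0[valid])^2 /
    (w0[valid] * (1 - w0[valid] / n))
  top <- which(bcv >= max(bcv) * (1 - 1e-12))
  structure(levels[floor((min(top) + max(top)) / 2)], degenerate = FALSE)
}

qc_codes <- c("TOO_DARK", "LOW_AVG_INTENSITY", "AREA_PCT_OUT_OF_RANGE",
              "TOO_FEW_PRELIM_OBJECTS", "BACKGROUND_TOO_BRIGHT")

#' Field quality control
#'
#' Applies the exclusion gates to the best-focus projection, in order:
#' (a) dark gate -- fields dominated by pigmented-epithelium residue
#' (`Dark_max`); (b) minimum best-focus average intensity; (c) percentage of
#' pixels above the auto-threshold within the admissible window;
#' (d) minimum number of preliminary objects (connected components above the
#' auto-threshold) against both `prelim_cells_min` and `nb_objects_min`;
#' (e) background (space between objects) not brighter than `FondMax`. All
#' failed gates are recorded, not only the first; all measured values are
#' returned.
#'
#' @param projection integer matrix from [best_focus_projection()].
#' @param params a [detection_params()].
#' @return An object of class `qc_decision`: `accepted`, `reasons`
#'   (character subset of the gate codes), and `measures`.
#' @export
field_qc <- function(projection, params) {
  stopifnot(inherits(params, "detection_params"))
  reasons <- character(0)
  mean_int <- mean(projection)
  if (params$dark_gate == "mean") {
    if (mean_int < params$dark_max) reasons <- c(reasons, "TOO_DARK")
    dark_measure <- mean_int
  } else {
    dark_frac <- mean(projection < params$dark_max)
    if (dark_frac > 0.5) reasons <- c(reasons, "TOO_DARK")
    dark_measure <- dark_frac
  }
  if (mean_int < params$best_focus_avg_intensity)
    reasons <- c(reasons, "LOW_AVG_INTENSITY")
  level <- auto_threshold(projection)
  above <- projection > level
  area_pct <- 100 * mean(above)
  if (area_pct < params$autothreshold_area_pct[1] ||
      area_pct > params$autothreshold_area_pct[2])
    reasons <- c(reasons, "AREA_PCT_OUT_OF_RANGE")
  n_prelim <- if (any(above))
    max(EBImage::bwlabel(EBImage::Image(t(above)))) else 0L
  if (n_prelim < params$prelim_cells_min ||
      n_prelim < params$nb_objects_min)
    reasons <- c(reasons, "TOO_FEW_PRELIM_OBJECTS")
  bg_mean <- if (all(above)) 0 else mean(projection[!above])
  if (bg_mean > params$fond_max)
    reasons <- c(reasons, "BACKGROUND_TOO_BRIGHT")
  structure(list(accepted = length(reasons) == 0L,
                 reasons = reasons,
                 measures = list(mean_intensity = mean_int,
                                 dark_measure = dark_measure,
                                 threshold = as.integer(level),
                                 threshold_degenerate =
                                   isTRUE(attr(level, "degenerate")),
                                 area_pct = area_pct,
                                 n_prelim = n_prelim,
                                 bg_mean = bg_mean)),
            class = "qc_decision")
}

#' @export
print.qc_decision <- function(x, ...) {
  cat(sprintf("qc_decision: %s%s\n",
              if (x$accepted) "accepted" else "excluded",
              if (x$accepted) "" else paste0(" [", paste(x$reasons,
                                                         collapse = ", "), "]")))
  invisible(x)
}

#' Tile-local thresholding with contrast adjustment
#'
#' Divides the projection into `tile_grid x tile_grid` tiles and thresholds
#' each tile at its own Otsu level, zeroing pixels below it, to overcome
#' brightness differences within an image and discriminate cells from
#' background. Tiles whose local level is degenerate, or falls below the
#' global level (background-only tiles, where a local Otsu would split the
#' noise), inherit the global level. `tile_grid = 1` reduces to global
#' thresholding.
#'
#' @param projection integer matrix.
#' @param params a [detection_params()].
#' @return Integer matrix: `projection` with sub-threshold pixels set to 0.
#' @export
local_threshold_enhance <- function(projection, params) {
  tg <- params$tile_grid
  global <- as.integer(auto_threshold(projection))
  out <- projection
  h <- nrow(projection); w <- ncol(projection)
  rb <- round(seq(0, h, length.out = tg + 1))
  cb <- round(seq(0, w, length.out = tg + 1))
  for (i in seq_len(tg)) {
    for (j in seq_len(tg)) {
      ri <- (rb[i] + 1):rb[i + 1]
      ci <- (cb[j] + 1):cb[j + 1]
      tile <- projection[ri, ci]
      lv <- auto_threshold(tile)
      level <- if (isTRUE(attr(lv, "degenerate"))) global
               else max(as.integer(lv), global)
      sub <- out[ri, ci]
      sub[sub < level] <- 0L
      out[ri, ci] <- sub
    }
  }
  out
}

spot_status_levels <- c("COUNTED", "REJECTED_SIZE", "REJECTED_SURFACE",
                        "REJECTED_INTENSITY", "REJECTED_SHAPE",
                        "REJECTED_CLUSTER", "EXCLUDED_FRAME")

empty_spots <- function() {
  data.frame(cx_px = numeric(0), cy_px = numeric(0), area_px = numeric(0),
             mean_intensity = numeric(0), peak_intensity = numeric(0),
             circularity = numeric(0), r_eq_px = numeric(0),
             status = character(0), stringsAsFactors = FALSE)
}

#' Find-spot object detection
#'
#' Detects, dissociates and filters candidate cones on the locally
#' thresholded image: (1) a morphological white top-hat with a disc
#' structuring element suppresses residual slow background, making the count
#' robust to cone orientation and twist; (2) connected components are
#' labelled; (3) components larger than `spot_size` ("Spotsize") are
#' dissociated by watershed on the distance transform (neighbouring cells in
#' contact); (4) each object is filtered by footprint area ("Cluster", then
#' "SurfSpot"), mean intensity ("IntMin") and circularity ("Spotcutoff").
#' Objects are returned in deterministic (y, x) centroid order.
#'
#' @param enhanced integer matrix from [local_threshold_enhance()].
#' @param params a [detection_params()].
#' @param reference intensity image for object measurements (default: the
#'   enhanced image itself; the pipeline passes the projection).
#' @param tophat_radius_px radius of the top-hat disc element, px (about the
#'   largest expected cone footprint).
#' @return A data frame of spot objects: centroid (`cx_px`, `cy_px`), area,
#'   mean/peak intensity, circularity, equivalent-disc radius `r_eq_px`, and
#'   `status` (`COUNTED` or a rejection code).
#' @export
find_spots <- function(enhanced, params, reference = enhanced,
                       tophat_radius_px = 35L) {
  stopifnot(inherits(params, "detection_params"))
  if (!any(enhanced > 0)) return(empty_spots())
  # EBImage works in [0,1] with x as the first dimension
  img <- EBImage::Image(t(enhanced) / 65535)
  brush <- EBImage::makeBrush(2L * as.integer(tophat_radius_px) + 1L, "disc")
  th <- EBImage::whiteTopHat(img, brush)
  mask <- EBImage::imageData(th) > 1e-7 & t(enhanced) > 0
  if (!any(mask)) return(empty_spots())
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  n_lab <- max(lab)
  areas <- tabulate(lab[lab > 0], nbins = n_lab)
  big <- which(areas > params$spot_size)
  if (length(big) > 0) {
    # dissociate touching cells: watershed on the distance transform,
    # restricted to the oversized components
    big_mask <- matrix(lab %in% big, nrow(lab), ncol(lab))
    dm <- EBImage::distmap(EBImage::Image(big_mask))
    wsd <- EBImage::imageData(EBImage::watershed(dm, tolerance = 1, ext = 1))
    lab[big_mask] <- wsd[big_mask] + n_lab   # keep split pieces distinct
  }
  ids <- sort(unique(lab[lab > 0]))
  lab <- matrix(match(lab, ids, nomatch = 0L), nrow(lab), ncol(lab))

  ref_t <- t(reference) / 65535
  shape <- EBImage::computeFeatures.shape(lab)
  mom <- EBImage::computeFeatures.moment(lab, ref_t)
  area <- shape[, "s.area"]
  perim <- shape[, "s.perimeter"]
  circ <- pmin(1, ifelse(perim > 0, 4 * pi * area / perim^2, 1))
  nz <- lab > 0
  mean_int <- as.numeric(tapply(t(reference)[nz], lab[nz], mean))
  peak_int <- as.numeric(tapply(t(reference)[nz], lab[nz], max))

  status <- rep("COUNTED", length(area))
  status[circ < params$spot_cutoff] <- "REJECTED_SHAPE"
  status[mean_int < params$int_min] <- "REJECTED_INTENSITY"
  status[area > params$surf_spot] <- "REJECTED_SURFACE"
  status[area > params$cluster] <- "REJECTED_CLUSTER"
  # unbiased-frame rule at the image border: objects touching the left or
  # top edge are excluded so that fields tiling the retina count each cone
  # exactly once (cones straddling the right/bottom edges belong here)
  n_obj <- length(area)
  touches <- logical(n_obj)
  edge_ids <- unique(c(lab[1, ], lab[, 1]))   # transposed: [x, y]
  touches[edge_ids[edge_ids > 0]] <- TRUE
  status[touches] <- "EXCLUDED_FRAME"

  out <- data.frame(cx_px = mom[, "m.cx"], cy_px = mom[, "m.cy"],
                    area_px = area,
                    mean_intensity = mean_int, peak_intensity = peak_int,
                    circularity = circ, r_eq_px = sqrt(area / pi),
                    status = status, stringsAsFactors = FALSE)
  out <- out[order(out$cy_px, out$cx_px), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full per-field counting
#'
#' Composes the chain: best-focus projection, auto-threshold, field quality
#' control, tile-local thresholding, find-spot detection. Excluded fields
#' carry their QC reasons and no count (never a count of 0); accepted fields
#' carry the count and the density per field area.
#'
#' @param stack a `zstack`.
#' @param params a [detection_params()].
#' @return An object of class `field_result`: `field`, `qc`, `count`
#'   (`NA` for excluded fields), `objects`, `density_per_field` (cones per
#'   field area) and `density_per_mm2`, plus `field_area_mm2`.
#' @export
count_field <- function(stack, params = detection_params()) {
  stopifnot(inherits(stack, "zstack"))
  proj <- best_focus_projection(stack)
  qc <- field_qc(proj, params)
  area_mm2 <- field_area_mm2(stack$acq, NULL)
  if (!qc$accepted)
    return(structure(list(field = stack$field, qc = qc, count = NA_integer_,
                          objects = NULL, density_per_field = NA_real_,
                          density_per_mm2 = NA_real_,
                          field_area_mm2 = area_mm2),
                     class = "field_result"))
  enhanced <- local_threshold_enhance(proj, params)
  objects <- find_spots(enhanced, params, reference = proj)
  count <- sum(objects$status == "COUNTED")
  structure(list(field = stack$field, qc = qc, count = as.integer(count),
                 objects = objects,
                 density_per_field = count,
                 density_per_mm2 = count / area_mm2,
                 field_area_mm2 = area_mm2),
            class = "field_result")
}

#' @export
print.field_result <- function(x, ...) {
  if (x$qc$accepted)
    cat(sprintf("field_result (row %s, col %s): %d cones / %.4f mm^2\n",
                x$field$row, x$field$col, x$count, x$field_area_mm2))
  else
    cat(sprintf("field_result (row %s, col %s): excluded [%s]\n",
                x$field$row, x$field$col, paste(x$qc$reasons, collapse = ", ")))
  invisible(x)
}
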