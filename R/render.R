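# Rendering of per-field Z-stacks from a ground-truth scene.

#' Field coordinate
#'
#' Stage position of one acquisition field. `x_um`/`y_um` are the field
#' centre in scene coordinates (origin at the optic nerve / retina centre,
#' x rightward, y downward); `row`/`col` are 0-based grid indices.
#'
#' @param row,col 0-based grid indices.
#' @param x_um,y_um field centre, um.
#' @param z_um recorded focal position, um (may be `NA` before autofocus).
#' @param index acquisition index (1-based), used in file naming.
#' @return An object of class `field_coordinate`.
#' @export
field_coordinate <- function(row, col, x_um, y_um, z_um = NA_real_,
                             index = NA_integer_) {
  structure(list(row = as.integer(row), col = as.integer(col),
                 x_um = x_um, y_um = y_um, z_um = z_um,
                 index = as.integer(index)),
            class = "field_coordinate")
}

#' Field rectangle (top-left corner and size, um)
#' @param field a [field_coordinate()].
#' @param acq an [acquisition_config()].
#' @return Named numeric `c(x0, y0, w, h)`.
#' @export
field_rect <- function(field, acq) {
  c(x0 = field$x_um - acq$field_width_um / 2,
    y0 = field$y_um - acq$field_height_um / 2,
    w = acq$field_width_um, h = acq$field_height_um)
}

# Per-field static frame: pixel centre coordinates, background and
# attenuation (dark patches, off-tissue), computed once per stack.
field_frame <- function(scene, field, acq) {
  rect <- field_rect(field, acq)
  px <- acq$field_width_um / acq$width
  py <- acq$field_height_um / acq$height
  xs <- rect["x0"] + (seq_len(acq$width) - 0.5) * px
  ys <- rect["y0"] + (seq_len(acq$height) - 0.5) * py
  p <- scene$params
  R <- scene$radius_um
  a <- scene$bg_gradient_angle
  # background: planar gradient across the whole retina
  bg <- p$bg_mean + p$bg_gradient_amp / R *
    outer(ys * sin(a), xs * cos(a), "+")
  gx <- rep(xs, each = acq$height)
  gy <- rep(ys, times = acq$width)
  atten <- rep(1, acq$height * acq$width)
  atten[!point_in_mask(p, gx, gy)] <- 0.15
  dp <- scene$dark_patches
  if (nrow(dp) > 0) {
    near <- which(abs(dp$x_um - field$x_um) <
                    acq$field_width_um / 2 + dp$radius_um &
                  abs(dp$y_um - field$y_um) <
                    acq$field_height_um / 2 + dp$radius_um)
    for (i in near) {
      hit <- (gx - dp$x_um[i])^2 + (gy - dp$y_um[i])^2 <= dp$radius_um[i]^2
      atten[hit] <- pmin(atten[hit], dp$factor[i])
    }
  }
  list(rect = rect, px = px, py = py, xs = xs, ys = ys,
       bg = bg * matrix(atten, acq$height, acq$width))
}

# Defocus blur: sigma grows linearly with distance from the cone's own plane.
BLUR_SIGMA_PER_UM <- 0.35   # um of Gaussian sigma per um of defocus
CONE_SIGMA_FACTOR <- 1.5    # in-focus sigma = radius / 1.5

# Add cone contributions for one focal plane onto `img` (noise-free).
render_cones_onto <- function(img, scene, frame, acq, z_um) {
  cones <- scene$cones
  if (nrow(cones) == 0) return(img)
  rect <- frame$rect
  sigma0 <- cones$radius_um / CONE_SIGMA_FACTOR
  sigma <- sigma0 + BLUR_SIGMA_PER_UM * abs(z_um - cones$z_um)
  margin <- 4 * sigma
  sel <- which(cones$x_um > rect["x0"] - margin &
               cones$x_um < rect["x0"] + rect["w"] + margin &
               cones$y_um > rect["y0"] - margin &
               cones$y_um < rect["y0"] + rect["h"] + margin)
  if (length(sel) == 0) return(img)
  hx <- frame$px / 2; hy <- frame$py / 2
  for (i in sel) {
    s <- sigma[i]
    peak <- cones$intensity[i] * (sigma0[i] / s)^2
    cx <- cones$x_um[i]; cy <- cones$y_um[i]
    jj <- which(abs(frame$xs - cx) <= 4 * s)
    ii <- which(abs(frame$ys - cy) <= 4 * s)
    if (length(jj) == 0 || length(ii) == 0) next
    # pixel-averaged Gaussian, exact per-pixel integral of the profile
    gxv <- (pnorm((frame$xs[jj] + hx - cx) / s) -
            pnorm((frame$xs[jj] - hx - cx) / s)) * s * sqrt(2 * pi) / frame$px
    gyv <- (pnorm((frame$ys[ii] + hy - cy) / s) -
            pnorm((frame$ys[ii] - hy - cy) / s)) * s * sqrt(2 * pi) / frame$py
    img[ii, jj] <- img[ii, jj] + peak * outer(gyv, gxv)
  }
  img
}

#' Render one focal plane of a field (noise-free)
#'
#' Background model plus defocused cone footprints at focal position `z_um`.
#' Used by the autofocus probes and by [render_field_stack()].
#'
#' @param scene a `retina_scene`.
#' @param field a [field_coordinate()].
#' @param acq an [acquisition_config()].
#' @param z_um focal position, um.
#' @return Numeric matrix `acq$height` x `acq$width` (intensity units,
#'   unquantized).
#' @export
render_plane <- function(scene, field, acq, z_um) {
  frame <- field_frame(scene, field, acq)
  render_cones_onto(frame$bg, scene, frame, acq, z_um)
}

#' Render the 9-plane Z-stack of one field
#'
#' Renders `acq$n_planes` 16-bit pages centred on the focal position
#' `z_center_um` (default: the scene's focal surface at the field centre),
#' spaced by `acq$plane_spacing_um`. Cone footprints are blurred by a
#' defocus kernel whose width grows with the distance between the plane and
#' the cone's own depth; photon noise (s.d. = sqrt(noise_scale * signal)) is
#' added per pixel and the result quantized to 16 bits. A pure function of
#' `(scene, field, acq, seed)`.
#'
#' @param scene a `retina_scene`.
#' @param field a [field_coordinate()].
#' @param acq an [acquisition_config()].
#' @param z_center_um focal centre of the stack; default
#'   `scene_surface_z(scene, field$x_um, field$y_um)`.
#' @param seed noise seed; default derived from the scene seed and the field
#'   grid indices.
#' @return An object of class `zstack`: `planes` (list of integer matrices,
#'   height x width, 0..65535), `field`, `acq`, `z_center_um`,
#'   `z_offsets_um`.
#' @export
render_field_stack <- function(scene, field, acq, z_center_um = NULL,
                               seed = NULL) {
  stopifnot(inherits(scene, "retina_scene"),
            inherits(field, "field_coordinate"),
            inherits(acq, "acquisition_config"))
  R <- scene$radius_um
  if (abs(field$x_um) > R + acq$field_width_um ||
      abs(field$y_um) > R + acq$field_height_um)
    stop("field lies outside the scene bounds")
  if (is.null(z_center_um))
    z_center_um <- scene_surface_z(scene, field$x_um, field$y_um)
  if (is.null(seed)) {
    idx <- (max(field$row, 0L) * 4096L + max(field$col, 0L)) %% 1000003L
    seed <- (scene$params$seed * 10007L + idx * 97L) %% .Machine$integer.max
  }
  frame <- field_frame(scene, field, acq)
  offs <- plane_offsets_um(acq)
  ns <- scene$params$noise_scale
  planes <- local_seed(seed, {
    lapply(offs, function(dz) {
      img <- render_cones_onto(frame$bg, scene, frame, acq, z_center_um + dz)
      if (ns > 0)
        img <- img + rnorm(length(img)) * sqrt(ns * pmax(img, 0))
      m <- matrix(as.integer(pmin(pmax(round(img), 0), 65535)),
                  acq$height, acq$width)
      m
    })
  })
  structure(list(planes = planes,
                 field = field_coordinate(field$row, field$col, field$x_um,
                                          field$y_um, z_center_um,
                                          field$index),
                 acq = acq,
                 z_center_um = z_center_um,
                 z_offsets_um = offs),
            class = "zstack")
}

#' @export
print.zstack <- function(x, ...) {
  cat(sprintf("zstack: %d planes of %d x %d px, field (row %d, col %d) at (%.1f, %.1f) um, z %.2f um\n",
              length(x$planes), ncol(x$planes[[1]]), nrow(x$planes[[1]]),
              x$field$row, x$field$col, x$field$x_um, x$field$y_um,
              x$z_center_um))
  invisible(x)
}
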