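# Synthetic flat-mounted retina: ground-truth world model.

# Evaluate an expression with a temporary RNG state.
local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Cone intensity function lambda(x, y) in cones/um^2 (0 outside the mask).
scene_lambda <- function(params, x, y, mask = TRUE) {
  R <- params$retina_radius_mm * 1000
  r <- sqrt(x^2 + y^2)
  lam <- params$base_density / 1e6
  lam <- lam * (1 + (params$radial_gradient - 1) * pmin(r / R, 1))
  rho <- params$dorsoventral_gradient
  if (rho != 1) {
    # smooth dorsal (y < 0) -> ventral (y > 0) transition; plateau ratio =
    # rho; the band is kept narrow relative to the radius so the half-disc
    # count ratio stays close to the plateau ratio
    band <- R / 24
    lam <- lam * (rho + (1 - rho) / (1 + exp(y / band)))
  }
  if (isTRUE(mask)) lam[!point_in_mask(params, x, y)] <- 0
  lam
}

# Is a point on retinal tissue (disc minus incision wedges)?
point_in_mask <- function(params, x, y) {
  R <- params$retina_radius_mm * 1000
  r <- sqrt(x^2 + y^2)
  inside <- r <= R
  if (params$n_incisions > 0L && params$incision_depth > 0) {
    half_angle <- 2 * pi / 180          # 2 degree half-width wedges
    theta <- atan2(y, x)
    cuts <- 2 * pi * (seq_len(params$n_incisions) - 1) / params$n_incisions
    in_wedge <- rep(FALSE, length(x))
    for (a in cuts) {
      d <- abs(((theta - a + pi) %% (2 * pi)) - pi)
      in_wedge <- in_wedge | (d < half_angle & r > R * (1 - params$incision_depth))
    }
    inside <- inside & !in_wedge
  }
  inside
}

# Smooth focal-depth undulation z(x, y), um.
scene_surface_z <- function(scene, x, y) {
  s <- scene$surface
  z <- 0
  for (k in seq_along(s$wavelength_um)) {
    ph <- 2 * pi * (x * cos(s$angle[k]) + y * sin(s$angle[k])) /
      s$wavelength_um[k] + s$phase[k]
    z <- z + sin(ph)
  }
  s$amplitude_um * z / max(1, length(s$wavelength_um))
}

# Hard-core dart throwing with an occupancy-grid neighbourhood lookup.
# Returns a matrix of accepted (x, y); errors if packing is infeasible.
place_hardcore <- function(params, n_target, lam_max) {
  R <- params$retina_radius_mm * 1000
  h <- params$hardcore_radius_um
  if (n_target == 0L) return(matrix(numeric(0), ncol = 2))
  if (h > 0) {
    # random sequential adsorption jams near 0.547 disc coverage
    mask_area <- pi * R^2
    n_max <- 0.52 * mask_area / (pi * (h / 2)^2)
    if (n_target > n_max)
      stop(sprintf(paste0("impossible packing: %d cones requested but at most ",
                          "~%d fit with a %.1f um hard-core spacing"),
                   n_target, floor(n_max), h))
  }
  cell <- max(h, 1e-6)
  grid <- new.env(hash = TRUE, parent = emptyenv())
  pts <- matrix(NA_real_, nrow = n_target, ncol = 2)
  n_acc <- 0L
  attempts <- 0L
  max_attempts <- 200L * n_target + 1000L
  batch <- max(1000L, n_target)
  while (n_acc < n_target && attempts < max_attempts) {
    m <- min(batch, max_attempts - attempts)
    cx <- runif(m, -R, R); cy <- runif(m, -R, R)
    attempts <- attempts + m
    keep <- point_in_mask(params, cx, cy)
    keep <- keep & (runif(m) * lam_max <= scene_lambda(params, cx, cy, mask = FALSE))
    cx <- cx[keep]; cy <- cy[keep]
    for (i in seq_along(cx)) {
      if (n_acc >= n_target) break
      x <- cx[i]; y <- cy[i]
      ok <- TRUE
      if (h > 0) {
        ix <- floor(x / cell); iy <- floor(y / cell)
        for (dx in -1:1) {
          for (dy in -1:1) {
            key <- paste(ix + dx, iy + dy)
            nb <- get0(key, envir = grid)
            if (!is.null(nb) &&
                any((nb[, 1] - x)^2 + (nb[, 2] - y)^2 < h^2)) {
              ok <- FALSE; break
            }
          }
          if (!ok) break
        }
      }
      if (ok) {
        n_acc <- n_acc + 1L
        pts[n_acc, ] <- c(x, y)
        if (h > 0) {
          key <- paste(floor(x / cell), floor(y / cell))
          nb <- get0(key, envir = grid)
          assign(key, rbind(nb, c(x, y)), envir = grid)
        }
      }
    }
  }
  if (n_acc < n_target)
    stop(sprintf(paste0("impossible packing: placed %d of %d cones before the ",
                        "attempt budget ran out (hard-core %.1f um too tight ",
                        "for the requested density)"), n_acc, n_target, h))
  pts[seq_len(n_acc), , drop = FALSE]
}

#' Generate a ground-truth synthetic retina scene
#'
#' Places fluorescently labelled cones on a flat-mounted retinal disc by a
#' hard-core point process whose intensity is the base density modulated by
#' the centro-peripheral and dorso-ventral gradients, then attaches the
#' nuisance structures (dark pigmented-epithelium patches, touching cone
#' clusters) and a smooth focal-depth surface. Deterministic given
#' `params$seed`.
#'
#' @param params a [synthetic_params()] object.
#' @return An object of class `retina_scene` with elements `params`,
#'   `radius_um`, `cones` (data frame `x_um`, `y_um`, `z_um`, `radius_um`,
#'   `intensity`, `cluster_member`), `dark_patches`, `surface`, and
#'   `bg_gradient_angle`.
#' @examples
#' sc <- generate_scene(synthetic_params(base_density = 800,
#'                                       retina_radius_mm = 0.5, seed = 7))
#' nrow(sc$cones)
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  local_seed(params$seed, {
    R <- params$retina_radius_mm * 1000

    surface <- list(
      amplitude_um = params$surface_amplitude_um,
      wavelength_um = runif(3, 3000, 6000),
      angle = runif(3, 0, 2 * pi),
      phase = runif(3, 0, 2 * pi))
    bg_gradient_angle <- runif(1, 0, 2 * pi)

    # expected count: grid integral of the intensity over the mask
    step <- R / 200
    gx <- seq(-R + step / 2, R - step / 2, by = step)
    gg <- expand.grid(x = gx, y = gx)
    lam_total <- sum(scene_lambda(params, gg$x, gg$y)) * step^2
    lam_max <- max(params$base_density / 1e6 *
                     max(1, params$radial_gradient) *
                     max(1, params$dorsoventral_gradient), 1e-300)

    n_total <- if (lam_total <= 0) 0L else rpois(1, lam_total)
    n_cluster <- round(params$cluster_fraction * n_total)
    n_hard <- n_total - n_cluster

    pts <- place_hardcore(params, n_hard, lam_max)
    cluster_member <- rep(FALSE, nrow(pts))

    radius <- runif(n_total, params$cone_radius_range_um[1],
                    params$cone_radius_range_um[2])

    # cluster members: attached in contact with a randomly chosen anchor,
    # exempt from the hard-core constraint
    if (n_cluster > 0L && nrow(pts) > 0L) {
      anchors <- sample.int(nrow(pts), n_cluster, replace = TRUE)
      ang <- runif(n_cluster, 0, 2 * pi)
      sep <- 0.9 * (radius[anchors] + radius[n_hard + seq_len(n_cluster)])
      px <- pts[anchors, 1] + sep * cos(ang)
      py <- pts[anchors, 2] + sep * sin(ang)
      ok <- point_in_mask(params, px, py)
      px[!ok] <- pts[anchors[!ok], 1]   # fall back onto the anchor ring inward
      py[!ok] <- pts[anchors[!ok], 2] - sep[!ok]
      pts <- rbind(pts, cbind(px, py))
      cluster_member <- c(cluster_member, rep(TRUE, n_cluster))
    }

    intensity <- pmin(rlnorm(nrow(pts), params$intensity_meanlog,
                             params$intensity_sdlog), 60000)

    scene <- structure(list(
      params = params,
      radius_um = R,
      surface = surface,
      bg_gradient_angle = bg_gradient_angle,
      dark_patches = data.frame(x_um = numeric(0), y_um = numeric(0),
                                radius_um = numeric(0), factor = numeric(0)),
      cones = NULL), class = "retina_scene")

    if (nrow(pts) > 0) {
      z <- scene_surface_z(scene, pts[, 1], pts[, 2])
      scene$cones <- data.frame(x_um = pts[, 1], y_um = pts[, 2], z_um = z,
                                radius_um = radius[seq_len(nrow(pts))],
                                intensity = intensity,
                                cluster_member = cluster_member)
    } else {
      scene$cones <- data.frame(x_um = numeric(0), y_um = numeric(0),
                                z_um = numeric(0), radius_um = numeric(0),
                                intensity = numeric(0),
                                cluster_member = logical(0))
    }

    if (params$dark_patch_fraction > 0) {
      mask_area <- pi * R^2
      target <- params$dark_patch_fraction * mask_area
      radii <- numeric(0)
      while (sum(pi * radii^2) < target)
        radii <- c(radii, runif(1, 30, 80))
      cxy <- matrix(runif(2 * length(radii), -R, R), ncol = 2)
      keep <- point_in_mask(params, cxy[, 1], cxy[, 2])
      scene$dark_patches <- data.frame(x_um = cxy[keep, 1], y_um = cxy[keep, 2],
                                       radius_um = radii[keep],
                                       factor = rep(0.25, sum(keep)))
    }
    scene
  })
}

#' @export
print.retina_scene <- function(x, ...) {
  cat(sprintf("retina_scene: radius %.0f um, %d cones, %d dark patches (seed %d)\n",
              x$radius_um, nrow(x$cones), nrow(x$dark_patches),
              x$params$seed))
  invisible(x)
}

#' Ground-truth cone count inside a rectangular field
#'
#' Counts cones whose centres fall in the half-open rectangle
#' `[x0, x0 + w) x [y0, y0 + h)` so that counts over an exact tiling sum to
#' the scene total.
#'
#' @param scene a [generate_scene()] result.
#' @param x0,y0 top-left corner, um (scene coordinates, origin at centre).
#' @param w,h field width and height, um.
#' @return Integer count.
#' @export
field_truth_count <- function(scene, x0, y0, w, h) {
  c0 <- scene$cones
  sum(c0$x_um >= x0 & c0$x_um < x0 + w & c0$y_um >= y0 & c0$y_um < y0 + h)
}

#' Export ground-truth cone coordinates as CSV
#'
#' One row per cone: `x_um`, `y_um`, `z_um`, `radius_um`, `intensity`.
#'
#' @param scene a `retina_scene`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(scene, path) {
  write.csv(scene$cones[, c("x_um", "y_um", "z_um", "radius_um", "intensity")],
            path, row.names = FALSE)
  invisible(path)
}
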