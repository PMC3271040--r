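#' Acquisition configuration
#'
#' Geometry of one imaging field and of the Z-stack acquired for it. The two
#' camera presets reproduce the physical field of view of the CCD cameras the
#' platform was built around: CoolSNAP FX (217.75 x 172.53 um) and CoolSNAP
#' HQ (224.46 x 167.70 um), both 650 x 515 pixels at 16 bits, with nine
#' Z-planes spaced 0.7 um.
#'
#' @param camera preset name, `"coolsnap_fx"` or `"coolsnap_hq"`.
#' @param n_planes number of Z-planes per stack (odd).
#' @param plane_spacing_um spacing between consecutive planes, um.
#' @param width,height image size in pixels.
#' @param field_width_um,field_height_um physical field size, um. Defaults
#'   come from the camera preset.
#' @param bit_depth bits per pixel (16).
#' @return An object of class `acquisition_config`.
#' @examples
#' acq <- acquisition_config("coolsnap_fx")
#' field_area_mm2(acq)   # 0.0376 mm^2 (rounded for display)
#' @export
acquisition_config <- function(camera = c("coolsnap_fx", "coolsnap_hq"),
                               n_planes = 9L, plane_spacing_um = 0.7,
                               width = 650L, height = 515L,
                               field_width_um = NULL, field_height_um = NULL,
                               bit_depth = 16L) {
  camera <- match.arg(camera)
  preset <- switch(camera,
    coolsnap_fx = c(217.75, 172.53),
    coolsnap_hq = c(224.46, 167.70))
  if (is.null(field_width_um))  field_width_um  <- preset[1]
  if (is.null(field_height_um)) field_height_um <- preset[2]
  n_planes <- as.integer(n_planes)
  stopifnot(n_planes %% 2L == 1L, n_planes >= 1L,
            plane_spacing_um > 0, width >= 1L, height >= 1L,
            field_width_um > 0, field_height_um > 0,
            bit_depth %in% c(8L, 16L))
  structure(list(camera = camera,
                 n_planes = n_planes,
                 plane_spacing_um = plane_spacing_um,
                 width = as.integer(width), height = as.integer(height),
                 field_width_um = field_width_um,
                 field_height_um = field_height_um,
                 bit_depth = as.integer(bit_depth)),
            class = "acquisition_config")
}

#' Field area in mm^2
#'
#' @param acq an [acquisition_config()].
#' @param digits decimal places for display rounding; `NULL` returns full
#'   precision.
#' @return Field area in mm^2.
#' @export
field_area_mm2 <- function(acq, digits = 4) {
  a <- acq$field_width_um * acq$field_height_um / 1e6
  if (is.null(digits)) a else round(a, digits)
}

#' Z-plane offsets of a stack, um, symmetric about the focal position
#' @param acq an [acquisition_config()].
#' @return Numeric vector of length `acq$n_planes`.
#' @export
plane_offsets_um <- function(acq) {
  k <- (acq$n_planes - 1L) / 2L
  seq(-k, k) * acq$plane_spacing_um
}

#' Pixel size in um (isotropic assumed; width-based)
#' @param acq an [acquisition_config()].
#' @return um per pixel along x.
#' @export
pixel_size_um <- function(acq) acq$field_width_um / acq$width

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf("acquisition_config [%s]: %d x %d px, %.2f x %.2f um (%.4f mm^2), %d planes @ %.1f um\n",
              x$camera, x$width, x$height, x$field_width_um, x$field_height_um,
              field_area_mm2(x, NULL), x$n_planes, x$plane_spacing_um))
  invisible(x)
}

#' Two-stage autofocus configuration
#'
#' The focal plane of each field is recovered in two passes: a coarse scan of
#' six planes spaced 60 um through the depth of the specimen, then a fine
#' scan of eight planes spaced 15 um around the coarse optimum.
#'
#' @param coarse_n,coarse_step_um coarse pass: number of planes and spacing.
#' @param fine_n,fine_step_um fine pass: number of planes and spacing.
#' @param focus_metric name of the sharpness statistic; `"variance"` (pixel
#'   intensity variance, offset-invariant) is the only built-in.
#' @return An object of class `autofocus_config`.
#' @export
autofocus_config <- function(coarse_n = 6L, coarse_step_um = 60,
                             fine_n = 8L, fine_step_um = 15,
                             focus_metric = "variance") {
  stopifnot(coarse_n >= 2L, fine_n >= 2L,
            coarse_step_um > 0, fine_step_um > 0,
            coarse_step_um > fine_step_um)
  focus_metric <- match.arg(focus_metric, "variance")
  structure(list(coarse_n = as.integer(coarse_n),
                 coarse_step_um = coarse_step_um,
                 fine_n = as.integer(fine_n),
                 fine_step_um = fine_step_um,
                 focus_metric = focus_metric),
            class = "autofocus_config")
}

#' Detection parameters: the eleven empirically set variables
#'
#' The counting algorithm is governed by eleven ordered variables that gate
#' field exclusion and object acceptance. Names follow the platform's
#' vocabulary:
#'
#' \describe{
#'   \item{best_focus_avg_intensity}{minimum mean intensity of the best-focus
#'     projection for a field to be analysable (variable 1).}
#'   \item{autothreshold_area_pct}{admissible window, in percent, for the
#'     fraction of pixels above the auto-threshold (variable 2).}
#'   \item{prelim_cells_min}{minimum number of preliminary objects detected
#'     on the thresholded projection before treatment (variable 3).}
#'   \item{spot_cutoff}{"Spotcutoff": minimum circularity (4 pi A / P^2) for
#'     an object not to be rejected as aberrant (variable 4).}
#'   \item{spot_size}{"Spotsize": component area in pixels above which a
#'     connected component is dissociated by watershed (variable 5).}
#'   \item{surf_spot}{"SurfSpot": object footprint area in pixels above which
#'     an object is rejected (variable 6).}
#'   \item{int_min}{"IntMin": minimum mean intensity for an object to be
#'     retained (variable 7).}
#'   \item{nb_objects_min}{"NBObjectsMin": minimum number of objects a
#'     projected image must contain (variable 8).}
#'   \item{fond_max}{"FondMax": maximum mean intensity of the space between
#'     objects -- fields with brighter background are excluded (variable 9).}
#'   \item{cluster}{"Cluster": area above which an unsplittable object is
#'     rejected as a cell cluster (variable 10).}
#'   \item{dark_max}{"Dark_max": minimum mean intensity of the projection;
#'     darker fields (pigmented-epithelium residue) are excluded
#'     (variable 11).}
#' }
#'
#' Defaults were fixed once against the built-in simulator and ship in the
#' packaged configuration; every value is overridable.
#'
#' @param best_focus_avg_intensity intensity units (0-65535 scale).
#' @param autothreshold_area_pct numeric length-2, percent window `[min, max]`.
#' @param prelim_cells_min count.
#' @param spot_cutoff dimensionless circularity in `[0, 1]`.
#' @param spot_size pixels.
#' @param surf_spot pixels.
#' @param int_min intensity units.
#' @param nb_objects_min count.
#' @param fond_max intensity units.
#' @param cluster pixels.
#' @param dark_max intensity units.
#' @param tile_grid tiles per axis for the local threshold.
#' @param dark_gate one of `"mean"` (mean projection intensity below
#'   `dark_max` excludes the field) or `"fraction"` (fraction of pixels below
#'   `dark_max` above 50\% excludes it).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(best_focus_avg_intensity = 150,
                             autothreshold_area_pct = c(0.02, 60),
                             prelim_cells_min = 3,
                             spot_cutoff = 0.25,
                             spot_size = 320,
                             surf_spot = 1500,
                             int_min = 1000,
                             nb_objects_min = 3,
                             fond_max = 6000,
                             cluster = 3000,
                             dark_max = 250,
                             tile_grid = 4L,
                             dark_gate = c("mean", "fraction")) {
  dark_gate <- match.arg(dark_gate)
  stopifnot(length(autothreshold_area_pct) == 2L,
            autothreshold_area_pct[1] <= autothreshold_area_pct[2],
            all(c(best_focus_avg_intensity, autothreshold_area_pct,
                  prelim_cells_min, spot_cutoff, spot_size, surf_spot,
                  int_min, nb_objects_min, fond_max, cluster,
                  dark_max) >= 0),
            spot_size <= cluster, tile_grid >= 1L)
  structure(list(best_focus_avg_intensity = best_focus_avg_intensity,
                 autothreshold_area_pct = as.numeric(autothreshold_area_pct),
                 prelim_cells_min = prelim_cells_min,
                 spot_cutoff = spot_cutoff,
                 spot_size = spot_size,
                 surf_spot = surf_spot,
                 int_min = int_min,
                 nb_objects_min = nb_objects_min,
                 fond_max = fond_max,
                 cluster = cluster,
                 dark_max = dark_max,
                 tile_grid = as.integer(tile_grid),
                 dark_gate = dark_gate),
            class = "detection_params")
}

#' @export
print.detection_params <- function(x, ...) {
  cat("detection_params (11 variables + tile_grid):\n")
  for (nm in setdiff(names(x), "dark_gate"))
    cat(sprintf("  %-26s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  invisible(x)
}

#' Synthetic-retina generator parameters
#'
#' World model for a flat-mounted retina: a disc of tissue (four radial
#' incisions flatten the cup) carrying fluorescently labelled cones placed by
#' a hard-core point process, with optional centro-peripheral and
#' dorso-ventral density gradients, residual retinal-pigment-epithelium dark
#' patches, and a fraction of cones in touching pairs/triples. Intensity
#' statistics of labelled cones are free parameters of the simulator, not
#' claims about any particular specimen.
#'
#' @param base_density cones per mm^2 before gradient modulation. The default
#'   5000/mm^2 corresponds to ~190 cones per 0.0376 mm^2 field, mid-range of
#'   the 45-405 per-field span the pipeline is designed for.
#' @param radial_gradient multiplicative centre-to-periphery density factor
#'   (1 = homogeneous; the density at the retinal edge is
#'   `radial_gradient` times the central density, linear in radius).
#' @param dorsoventral_gradient ventral/dorsal density ratio. Realized as a
#'   narrow logistic transition across the horizontal midline so the
#'   half-retina count ratio closely tracks this value.
#' @param retina_radius_mm radius of the flat-mounted disc, mm.
#' @param n_incisions radial flattening incisions (wedge cuts in the mask).
#' @param incision_depth fraction of the radius the incisions reach inward.
#' @param dark_patch_fraction fraction of tissue area covered by dark
#'   pigmented-epithelium patches, in `[0, 1]`.
#' @param cluster_fraction fraction of cones placed as members of touching
#'   pairs/triples (exempt from the hard-core constraint), in `[0, 1]`.
#' @param hardcore_radius_um minimum centre-to-centre cone spacing, um.
#' @param cone_radius_range_um length-2: cone radius bounds, um (spot
#'   diameters ~3-8 um).
#' @param intensity_meanlog,intensity_sdlog log-normal peak-intensity model
#'   for cones (16-bit scale).
#' @param bg_mean background mean intensity.
#' @param bg_gradient_amp amplitude of the planar background gradient across
#'   the retina.
#' @param noise_scale photon-noise scale: pixel s.d. = sqrt(noise_scale *
#'   signal). 0 disables noise.
#' @param surface_amplitude_um amplitude of the smooth focal-depth
#'   undulation z(x, y) (makes per-field autofocus non-trivial).
#' @param seed integer seed; scenes are bit-reproducible given the seed.
#' @return An object of class `synthetic_params`.
#' @export
synthetic_params <- function(base_density = 5000,
                             radial_gradient = 1,
                             dorsoventral_gradient = 1,
                             retina_radius_mm = 1.9,
                             n_incisions = 4L,
                             incision_depth = 0.35,
                             dark_patch_fraction = 0.02,
                             cluster_fraction = 0.05,
                             hardcore_radius_um = 6,
                             cone_radius_range_um = c(1.5, 2.5),
                             intensity_meanlog = log(9000),
                             intensity_sdlog = 0.25,
                             bg_mean = 500,
                             bg_gradient_amp = 120,
                             noise_scale = 1,
                             surface_amplitude_um = 20,
                             seed = 1L) {
  stopifnot(base_density >= 0, retina_radius_mm > 0,
            radial_gradient > 0, dorsoventral_gradient > 0,
            dark_patch_fraction >= 0, dark_patch_fraction <= 1,
            cluster_fraction >= 0, cluster_fraction <= 1,
            hardcore_radius_um >= 0, n_incisions >= 0,
            incision_depth >= 0, incision_depth < 1,
            length(cone_radius_range_um) == 2L,
            all(cone_radius_range_um > 0),
            diff(cone_radius_range_um) >= 0,
            bg_mean >= 0, noise_scale >= 0, surface_amplitude_um >= 0)
  structure(list(base_density = base_density,
                 radial_gradient = radial_gradient,
                 dorsoventral_gradient = dorsoventral_gradient,
                 retina_radius_mm = retina_radius_mm,
                 n_incisions = as.integer(n_incisions),
                 incision_depth = incision_depth,
                 dark_patch_fraction = dark_patch_fraction,
                 cluster_fraction = cluster_fraction,
                 hardcore_radius_um = hardcore_radius_um,
                 cone_radius_range_um = as.numeric(cone_radius_range_um),
                 intensity_meanlog = intensity_meanlog,
                 intensity_sdlog = intensity_sdlog,
                 bg_mean = bg_mean,
                 bg_gradient_amp = bg_gradient_amp,
                 noise_scale = noise_scale,
                 surface_amplitude_um = surface_amplitude_um,
                 seed = as.integer(seed)),
            class = "synthetic_params")
}
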