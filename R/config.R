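# Structured-text (YAML) run configuration mirroring the module names.

#' Default run configuration
#'
#' Nested list with one section per pipeline stage; every variable is
#' present with its default. Files written/read by [write_run_config()] /
#' [read_run_config()]; unknown keys are rejected.
#'
#' @return Named nested list.
#' @export
default_config <- function() {
  det <- detection_params()
  syn <- synthetic_params()
  af <- autofocus_config()
  list(
    seed = 1L,
    camera = "coolsnap_fx",
    verbosity = 1L,
    acquisition = list(
      n_planes = 9L, plane_spacing_um = 0.7, width = 650L, height = 515L,
      autofocus = list(coarse_n = af$coarse_n,
                       coarse_step_um = af$coarse_step_um,
                       fine_n = af$fine_n, fine_step_um = af$fine_step_um,
                       focus_metric = af$focus_metric),
      grid_mode = "full"),
    detection = unclass(det),
    counting = list(mode = "global",
                    frame_width_um = 30, frame_height_um = 30,
                    sample = list(n_fields_target = 65, field_side_um = 35,
                                  radius_um = 2000)),
    fundus = list(n_rows = 9L, bin_step = 45, n_bins = 9L,
                  dorsal = "up", nasal = "left", eye = "left"),
    simulate = unclass(syn),
    stats = list(per_day_normalization = FALSE)
  )
}

check_keys <- function(cfg, ref, path = "") {
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra) > 0)
    stop(sprintf("unknown configuration key%s: %s",
                 if (length(extra) > 1) "s" else "",
                 paste0(path, extra, collapse = ", ")))
  for (nm in names(cfg))
    if (is.list(ref[[nm]]) && is.list(cfg[[nm]]))
      check_keys(cfg[[nm]], ref[[nm]], paste0(path, nm, "."))
  invisible(TRUE)
}

#' Read a run configuration file
#'
#' Reads a YAML configuration, validates it against [default_config()]
#' (unknown keys are an error) and fills missing values with the defaults.
#'
#' @param path YAML file path.
#' @return Nested configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ref <- default_config()
  check_keys(cfg, ref)
  modifyList(ref, cfg)
}

#' Write a run configuration file
#' @param config nested configuration list.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# Section -> parameter-object converters.
config_acquisition <- function(config) {
  a <- config$acquisition
  acquisition_config(camera = config$camera, n_planes = a$n_planes,
                     plane_spacing_um = a$plane_spacing_um,
                     width = a$width, height = a$height)
}
config_autofocus <- function(config) {
  f <- config$acquisition$autofocus
  autofocus_config(f$coarse_n, f$coarse_step_um, f$fine_n, f$fine_step_um,
                   f$focus_metric)
}
config_detection <- function(config) {
  do.call(detection_params, config$detection)
}
config_synthetic <- function(config) {
  s <- config$simulate
  s$seed <- config$seed
  do.call(synthetic_params, s)
}
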