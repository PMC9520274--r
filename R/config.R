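#' Path to the frozen default parameter config
#'
#' The package ships a versioned YAML file holding every physical,
#' acoustic and numerical default of the bubble-dynamics module (units
#' annotated in the key names). Shell parameters in it were frozen by
#' [calibrate_shell()].
#'
#' @return Path to the installed YAML file.
#' @export
default_bubble_config <- function() {
  system.file("extdata", "marmottant_defaults.yaml", package = "sonopore",
              mustWork = TRUE)
}

#' Load a bubble-simulation config
#'
#' Reads a YAML config with blocks `bubble`, `gas`, `medium`, `shell`,
#' `drive`, `thresholds`, `solver` (units annotated in key names, e.g.
#' `resting_radius_um`) and converts it to the package's strict-SI
#' domain objects.
#'
#' @param path Path to a YAML file; defaults to the frozen package
#'   config.
#' @return List with `system` ([bubble_system()]), `drive_template`
#'   (an [acoustic_drive()] at PNP 0; set `peak_negative_pressure` per
#'   run), `thresholds` ([regime_thresholds()]) and `solver` (list of
#'   `rtol`, `atol_radius`, `collapse_floor`).
#' @export
load_bubble_config <- function(path = default_bubble_config()) {
  cfg <- yaml::read_yaml(path)
  need <- c("bubble", "gas", "medium", "shell", "drive", "thresholds",
            "solver")
  missing <- setdiff(need, names(cfg))
  if (length(missing) > 0)
    stop("config is missing blocks: ", paste(missing, collapse = ", "))
  system <- bubble_system(
    resting_radius = cfg$bubble$resting_radius_um * 1e-6,
    gas = gas_properties(
      polytropic_exponent = cfg$gas$polytropic_exponent,
      vapor_pressure = cfg$gas$vapor_pressure_kpa * 1e3),
    medium = medium_properties(
      density = cfg$medium$density_kg_m3,
      dynamic_viscosity = cfg$medium$dynamic_viscosity_pa_s,
      sound_speed = cfg$medium$sound_speed_m_s,
      ambient_pressure = cfg$medium$ambient_pressure_kpa * 1e3,
      water_surface_tension = cfg$medium$water_surface_tension_n_m),
    shell = shell_properties(
      elastic_modulus = cfg$shell$elastic_modulus_n_m,
      surface_viscosity = cfg$shell$surface_viscosity_kg_s,
      initial_surface_tension = cfg$shell$initial_surface_tension_n_m))
  drive_template <- acoustic_drive(
    center_frequency = cfg$drive$center_frequency_khz * 1e3,
    peak_negative_pressure = 0,
    n_cycles = cfg$drive$n_cycles,
    envelope = cfg$drive$envelope)
  thresholds <- regime_thresholds(
    stable_lower = cfg$thresholds$stable_lower,
    inertial_onset = cfg$thresholds$inertial_onset)
  solver <- list(rtol = cfg$solver$rtol,
                 atol_radius = cfg$solver$atol_radius_rel,
                 collapse_floor = cfg$solver$collapse_floor_rel)
  list(system = system, drive_template = drive_template,
       thresholds = thresholds, solver = solver)
}

#' Default calibrated bubble system
#'
#' Convenience wrapper returning the [bubble_system()] described by the
#' frozen package config.
#'
#' @return A [bubble_system()].
#' @export
default_bubble_system <- function() {
  load_bubble_config()$system
}
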