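#' Gas core properties
#'
#' Physical properties of the microbubble gas core. The default polytropic
#' exponent corresponds to quasi-adiabatic compression of perfluorobutane
#' (C4F10); low-solubility perfluorocarbon cores have negligible vapor
#' pressure, so the default vapor pressure is zero.
#'
#' @param polytropic_exponent Dimensionless polytropic exponent (>= 1).
#' @param vapor_pressure Vapor pressure inside the bubble, Pa (>= 0).
#' @return An object of class `gas_properties`.
#' @export
gas_properties <- function(polytropic_exponent = 1.07, vapor_pressure = 0) {
  stopifnot(is.numeric(polytropic_exponent), length(polytropic_exponent) == 1,
            polytropic_exponent >= 1,
            is.numeric(vapor_pressure), length(vapor_pressure) == 1,
            vapor_pressure >= 0)
  structure(list(polytropic_exponent = polytropic_exponent,
                 vapor_pressure = vapor_pressure),
            class = "gas_properties")
}

#' Surrounding-medium properties
#'
#' Properties of the liquid surrounding the bubble. Defaults approximate
#' water at body temperature at atmospheric pressure.
#'
#' @param density Liquid density, kg/m^3.
#' @param dynamic_viscosity Dynamic viscosity, Pa s.
#' @param sound_speed Speed of sound in the liquid, m/s.
#' @param ambient_pressure Static ambient pressure, Pa.
#' @param water_surface_tension Surface tension of the clean gas-liquid
#'   interface, N/m; this is the ruptured-shell limit of the shell model.
#' @return An object of class `medium_properties`.
#' @export
medium_properties <- function(density = 1000,
                              dynamic_viscosity = 0.002,
                              sound_speed = 1500,
                              ambient_pressure = 101325,
                              water_surface_tension = 0.073) {
  vals <- c(density, dynamic_viscosity, sound_speed, ambient_pressure,
            water_surface_tension)
  stopifnot(is.numeric(vals), length(vals) == 5, all(vals > 0))
  structure(list(density = density,
                 dynamic_viscosity = dynamic_viscosity,
                 sound_speed = sound_speed,
                 ambient_pressure = ambient_pressure,
                 water_surface_tension = water_surface_tension),
            class = "medium_properties")
}

#' Lipid-shell properties
#'
#' Elastic and viscous parameters of the lipid monolayer shell. The
#' piecewise surface tension of the shell is zero below the buckling
#' radius, elastic (`chi * (R^2/R_buckling^2 - 1)`) between buckling and
#' rupture, and equal to the clean-interface surface tension above rupture.
#' The buckling and rupture radii are derived from the resting radius when
#' the shell is attached to a [bubble_system()]; they are chosen so that
#' the surface tension at the resting radius equals
#' `initial_surface_tension`.
#'
#' The default values are the package's frozen calibration: a single
#' parameter set fitted jointly (via [calibrate_shell()]) to the
#' expansion-ratio anchors 15/33/50 at 300/500/800 kPa and the
#' stable-cavitation boundaries 85/205 kPa for a 1.5 um bubble driven at
#' 250 kHz. They are also recorded in the versioned default config (see
#' [default_bubble_config()]).
#'
#' @param elastic_modulus Shell elastic modulus chi, N/m (> 0).
#' @param surface_viscosity Shell surface (dilatational) viscosity
#'   kappa_s, kg/s (>= 0).
#' @param initial_surface_tension Surface tension at the resting radius,
#'   N/m; must lie in `[0, water_surface_tension]`.
#' @return An object of class `shell_properties`. The fields
#'   `buckling_radius` and `rupture_radius` are `NA` until the shell is
#'   bound to a bubble system.
#' @export
shell_properties <- function(elastic_modulus = 0.020,
                             surface_viscosity = 5.8e-9,
                             initial_surface_tension = 0.050) {
  stopifnot(is.numeric(elastic_modulus), elastic_modulus > 0,
            is.numeric(surface_viscosity), surface_viscosity >= 0,
            is.numeric(initial_surface_tension), initial_surface_tension >= 0)
  structure(list(elastic_modulus = elastic_modulus,
                 surface_viscosity = surface_viscosity,
                 initial_surface_tension = initial_surface_tension,
                 buckling_radius = NA_real_,
                 rupture_radius = NA_real_),
            class = "shell_properties")
}

#' Acoustic drive
#'
#' Sinusoidal insonation pulse, rarefaction-first (the first half-cycle is
#' the negative one, so a bubble at rest is pulled outward first).
#'
#' @param center_frequency Center frequency, Hz.
#' @param peak_negative_pressure Peak negative pressure (PNP), Pa (>= 0).
#' @param n_cycles Number of drive cycles (>= 1).
#' @param envelope `"rectangular"` (default) or `"ramped"` (linear
#'   amplitude ramp over `ramp_cycles` cycles).
#' @param ramp_cycles Ramp length in cycles, used when
#'   `envelope = "ramped"`.
#' @return An object of class `acoustic_drive`.
#' @export
acoustic_drive <- function(center_frequency = 250e3,
                           peak_negative_pressure = 0,
                           n_cycles = 50,
                           envelope = c("rectangular", "ramped"),
                           ramp_cycles = 5) {
  envelope <- match.arg(envelope)
  stopifnot(center_frequency > 0, peak_negative_pressure >= 0,
            n_cycles >= 1, ramp_cycles > 0)
  structure(list(center_frequency = center_frequency,
                 peak_negative_pressure = peak_negative_pressure,
                 n_cycles = n_cycles,
                 envelope = envelope,
                 ramp_cycles = if (envelope == "ramped") ramp_cycles else 0),
            class = "acoustic_drive")
}

#' Assemble a bubble system
#'
#' Binds bubble, gas, medium and shell parameters into a single validated
#' system. The buckling and rupture radii of the shell are derived here:
#' `R_buckling = R0 / sqrt(1 + sigma_0/chi)` makes the elastic branch of
#' the surface tension pass through `sigma_0` at the resting radius, and
#' `R_rupture = R_buckling * sqrt(1 + sigma_water/chi)` makes it continuous
#' with the clean-interface value at rupture. The equilibrium gas pressure
#' follows from mechanical balance at rest:
#' `P_gas0 = P0 + 2 sigma(R0)/R0`.
#'
#' @param resting_radius Resting radius R0, m. The default 0.75 um
#'   corresponds to a 1.5 um diameter bubble.
#' @param gas A [gas_properties()] object.
#' @param medium A [medium_properties()] object.
#' @param shell A [shell_properties()] object.
#' @return An object of class `bubble_system`.
#' @export
bubble_system <- function(resting_radius = 0.75e-6,
                          gas = gas_properties(),
                          medium = medium_properties(),
                          shell = shell_properties()) {
  stopifnot(inherits(gas, "gas_properties"),
            inherits(medium, "medium_properties"),
            inherits(shell, "shell_properties"),
            is.numeric(resting_radius), resting_radius > 0)
  if (shell$initial_surface_tension > medium$water_surface_tension)
    stop("initial_surface_tension must not exceed water_surface_tension")
  chi <- shell$elastic_modulus
  sig0 <- shell$initial_surface_tension
  shell$buckling_radius <- resting_radius / sqrt(1 + sig0 / chi)
  shell$rupture_radius <- shell$buckling_radius *
    sqrt(1 + medium$water_surface_tension / chi)
  stopifnot(shell$buckling_radius <= resting_radius,
            resting_radius <= shell$rupture_radius)
  eq_gas <- medium$ambient_pressure + 2 * sig0 / resting_radius
  structure(list(resting_radius = resting_radius,
                 gas = gas, medium = medium, shell = shell,
                 equilibrium_gas_pressure = eq_gas),
            class = "bubble_system")
}

#' Piecewise shell surface tension
#'
#' Effective surface tension of a lipid-shelled bubble as a function of
#' radius: 0 in the buckled state, elastic in between, clean-interface
#' value once ruptured. Continuous at both regime boundaries.
#'
#' @param radius Bubble radius, m (vectorized, all > 0).
#' @param shell A `shell_properties` object with derived buckling and
#'   rupture radii (i.e. taken from a [bubble_system()]).
#' @param medium A `medium_properties` object.
#' @return Surface tension in N/m, same length as `radius`.
#' @export
surface_tension <- function(radius, shell, medium) {
  if (inherits(shell, "bubble_system")) {
    medium <- shell$medium
    shell <- shell$shell
  }
  stopifnot(is.numeric(radius), all(radius > 0))
  rb <- shell$buckling_radius
  rr <- shell$rupture_radius
  if (is.na(rb) || is.na(rr))
    stop("shell has no derived buckling/rupture radii; build it via bubble_system()")
  sig <- ifelse(radius <= rb, 0,
         ifelse(radius < rr,
                shell$elastic_modulus * ((radius / rb)^2 - 1),
                medium$water_surface_tension))
  pmin(pmax(sig, 0), medium$water_surface_tension)
}

#' Instantaneous drive pressure
#'
#' Acoustic pressure perturbation at time `t`: a rarefaction-first sine of
#' amplitude PNP during the pulse, zero afterwards.
#'
#' @param t Time, s (vectorized, >= 0).
#' @param drive An [acoustic_drive()] object.
#' @return Pressure perturbation in Pa (negative during rarefaction).
#' @export
drive_pressure <- function(t, drive) {
  stopifnot(inherits(drive, "acoustic_drive"))
  f <- drive$center_frequency
  on <- t >= 0 & t < drive$n_cycles / f
  amp <- rep(drive$peak_negative_pressure, length(t))
  if (drive$ramp_cycles > 0) {
    tc <- t * f
    amp <- amp * pmin(tc / drive$ramp_cycles, 1)
  }
  ifelse(on, -amp * sin(2 * pi * f * t), 0)
}

#' Regime classification thresholds
#'
#' Expansion-ratio thresholds separating negligible, stable and inertial
#' cavitation. Defaults follow the convention that expansion ratios from
#' 1.1 to 3.5 reflect stable cavitation and ratios above 3.5 mark the
#' onset of inertial cavitation.
#'
#' @param stable_lower Lower expansion-ratio bound of stable cavitation.
#' @param inertial_onset Expansion ratio at which inertial cavitation
#'   begins.
#' @return An object of class `regime_thresholds`.
#' @export
regime_thresholds <- function(stable_lower = 1.1, inertial_onset = 3.5) {
  stopifnot(stable_lower > 1, inertial_onset > stable_lower)
  structure(list(stable_lower = stable_lower,
                 inertial_onset = inertial_onset),
            class = "regime_thresholds")
}

#' @export
print.bubble_system <- function(x, ...) {
  cat("Lipid-shelled microbubble system\n")
  cat(sprintf("  resting radius: %.3g um (diameter %.3g um)\n",
              x$resting_radius * 1e6, 2 * x$resting_radius * 1e6))
  cat(sprintf("  shell: chi = %.3g N/m, kappa_s = %.3g kg/s, sigma(R0) = %.3g N/m\n",
              x$shell$elastic_modulus, x$shell$surface_viscosity,
              x$shell$initial_surface_tension))
  cat(sprintf("  buckling/rupture radii: %.4g / %.4g um\n",
              x$shell$buckling_radius * 1e6, x$shell$rupture_radius * 1e6))
  cat(sprintf("  gas: polytropic exponent %.3g, vapor pressure %.3g Pa\n",
              x$gas$polytropic_exponent, x$gas$vapor_pressure))
  cat(sprintf("  medium: rho = %g kg/m^3, mu = %g Pa s, c = %g m/s, P0 = %g kPa\n",
              x$medium$density, x$medium$dynamic_viscosity,
              x$medium$sound_speed, x$medium$ambient_pressure / 1e3))
  cat(sprintf("  equilibrium gas pressure: %.4g kPa\n",
              x$equilibrium_gas_pressure / 1e3))
  invisible(x)
}
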