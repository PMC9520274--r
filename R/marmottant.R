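#' Marmottant model right-hand side
#'
#' Time derivative of the bubble state `(R, Rdot)` under the Marmottant
#' modified Rayleigh-Plesset equation: polytropic gas core, piecewise
#' shell surface tension, liquid and shell viscous damping, and a
#' first-order acoustic radiation (compressibility) correction:
#'
#' \deqn{\rho (R \ddot R + \tfrac{3}{2} \dot R^2) =
#'   P_{g0} (R_0/R)^{3\kappa} (1 - 3\kappa \dot R / c) + P_v
#'   - 2\sigma(R)/R - 4\mu \dot R / R - 4\kappa_s \dot R / R^2
#'   - P_0 - p_{ac}(t)}
#'
#' @param state Numeric vector `c(R, Rdot)` with `R > 0` in m and `Rdot`
#'   in m/s.
#' @param t Time, s.
#' @param system A [bubble_system()].
#' @param drive An [acoustic_drive()].
#' @return Numeric vector `c(Rdot, Rddot)`.
#' @export
marmottant_rhs <- function(state, t, system, drive) {
  R <- state[[1]]
  Rd <- state[[2]]
  if (!is.finite(R) || R <= 0) stop("radius must be positive")
  med <- system$medium
  gas <- system$gas
  R0 <- system$resting_radius
  pg0 <- system$equilibrium_gas_pressure - gas$vapor_pressure
  k3 <- 3 * gas$polytropic_exponent
  pg <- pg0 * (R0 / R)^k3
  sig <- surface_tension(R, system$shell, med)
  pbal <- pg * (1 - k3 * Rd / med$sound_speed) + gas$vapor_pressure -
    2 * sig / R -
    4 * med$dynamic_viscosity * Rd / R -
    4 * system$shell$surface_viscosity * Rd / R^2 -
    med$ambient_pressure - drive_pressure(t, drive)
  c(Rd, (pbal / med$density - 1.5 * Rd^2) / R)
}

marm_parms <- function(system, drive, collapse_floor) {
  c(system$resting_radius,
    system$gas$polytropic_exponent,
    system$gas$vapor_pressure,
    system$medium$density,
    system$medium$dynamic_viscosity,
    system$medium$sound_speed,
    system$medium$ambient_pressure,
    system$medium$water_surface_tension,
    system$shell$elastic_modulus,
    system$shell$surface_viscosity,
    system$shell$buckling_radius,
    system$shell$rupture_radius,
    drive$peak_negative_pressure,
    drive$center_frequency,
    drive$n_cycles,
    drive$ramp_cycles,
    collapse_floor)
}

#' Simulate bubble radial dynamics
#'
#' Integrates the Marmottant equation from rest over the drive window with
#' a stiff-capable adaptive solver (`deSolve::lsodar`). A terminal event
#' truncates the trace when the radius falls below `collapse_floor * R0`
#' (inertial collapse); the trace is then flagged and the pre-collapse
#' history retained, which preserves the maximum-expansion statistic while
#' avoiding the stiffness blow-up of the collapse itself.
#'
#' @param system A [bubble_system()].
#' @param drive An [acoustic_drive()].
#' @param points_per_cycle Output samples per drive cycle (the solver's
#'   internal steps are adaptive and independent of this grid).
#' @param rtol,atol_radius Relative tolerance and absolute radius
#'   tolerance (as a fraction of R0) of the solver.
#' @param collapse_floor Collapse event threshold as a fraction of R0.
#' @param engine `"compiled"` (C right-hand side, default) or `"R"`
#'   (the exported [marmottant_rhs()], provided for cross-checking).
#' @return An object of class `radius_trace`: list with `times`, `radii`,
#'   `radial_velocities`, `truncated_at_collapse`, `resting_radius`.
#' @export
simulate_radius <- function(system, drive,
                            points_per_cycle = 200,
                            rtol = 1e-8,
                            atol_radius = 1e-12,
                            collapse_floor = 0.05,
                            engine = c("compiled", "R")) {
  engine <- match.arg(engine)
  stopifnot(inherits(system, "bubble_system"), inherits(drive, "acoustic_drive"))
  R0 <- system$resting_radius
  f <- drive$center_frequency
  times <- seq(0, drive$n_cycles / f,
               length.out = ceiling(drive$n_cycles * points_per_cycle) + 1)
  y0 <- c(R = R0, Rdot = 0)
  atol <- c(atol_radius * R0, 1e-8)
  hmax <- 1 / (20 * f)
  if (engine == "compiled") {
    out <- deSolve::lsodar(y = y0, times = times,
                           func = "marm_derivs", dllname = "sonopore",
                           initfunc = "marm_init",
                           rootfunc = "marm_root", nroot = 1L,
                           parms = marm_parms(system, drive, collapse_floor),
                           rtol = rtol, atol = atol, hmax = hmax,
                           maxsteps = 500000)
  } else {
    rhs <- function(t, y, p) list(marmottant_rhs(y, t, system, drive))
    rootf <- function(t, y, p) y[1] - collapse_floor * R0
    out <- deSolve::lsodar(y = y0, times = times, func = rhs, parms = NULL,
                           rootfunc = rootf,
                           rtol = rtol, atol = atol, hmax = hmax,
                           maxsteps = 500000)
  }
  diagn <- attr(out, "istate")
  if (!is.null(diagn) && diagn[1] < 0)
    stop(sprintf("integration failed (istate = %d) at PNP = %g Pa",
                 diagn[1], drive$peak_negative_pressure))
  truncated <- !is.null(attr(out, "troot")) && length(attr(out, "troot")) > 0
  structure(list(times = out[, 1],
                 radii = out[, 2],
                 radial_velocities = out[, 3],
                 truncated_at_collapse = truncated,
                 resting_radius = R0),
            class = "radius_trace")
}

#' Expansion ratio of a radius trace
#'
#' Maximal diameter over resting diameter (equivalently, maximal radius
#' over resting radius) attained during the simulated window.
#'
#' @param trace A `radius_trace` from [simulate_radius()].
#' @return Dimensionless expansion ratio (>= 1 up to solver tolerance).
#' @export
expansion_ratio <- function(trace) {
  stopifnot(inherits(trace, "radius_trace"))
  if (length(trace$radii) == 0) stop("empty radius trace")
  max(trace$radii) / trace$resting_radius
}

#' Classify the cavitation regime of an expansion ratio
#'
#' @param er Expansion ratio(s), dimensionless.
#' @param thresholds A [regime_thresholds()].
#' @return Factor with levels `negligible`, `stable`, `inertial`:
#'   `er < stable_lower` is negligible, values in
#'   `[stable_lower, inertial_onset]` are stable, larger values inertial.
#' @export
classify_cavitation <- function(er, thresholds = regime_thresholds()) {
  stopifnot(inherits(thresholds, "regime_thresholds"))
  lv <- c("negligible", "stable", "inertial")
  out <- ifelse(er < thresholds$stable_lower, "negligible",
         ifelse(er <= thresholds$inertial_onset, "stable", "inertial"))
  factor(out, levels = lv)
}

#' Expansion-ratio sweep over peak negative pressure
#'
#' Runs [simulate_radius()] on an ascending PNP grid and records the
#' expansion ratio and cavitation regime at each point.
#'
#' @param system A [bubble_system()].
#' @param frequency Drive center frequency, Hz.
#' @param pnp_min,pnp_max,step PNP grid in Pa (`pnp_min >= 0`,
#'   `step > 0`).
#' @param n_cycles Drive cycles per simulation.
#' @param thresholds A [regime_thresholds()].
#' @param ... Further arguments to [simulate_radius()].
#' @return An object of class `sweep_result`: data frame with columns
#'   `pnp` (Pa), `expansion_ratio`, `regime`.
#' @export
pressure_sweep <- function(system, frequency = 250e3,
                           pnp_min = 0, pnp_max = 800e3, step = 5e3,
                           n_cycles = 50,
                           thresholds = regime_thresholds(), ...) {
  stopifnot(pnp_min >= 0, step > 0, pnp_max >= pnp_min)
  grid <- seq(pnp_min, pnp_max, by = step)
  er <- vapply(grid, function(p) {
    drv <- acoustic_drive(center_frequency = frequency,
                          peak_negative_pressure = p, n_cycles = n_cycles)
    expansion_ratio(simulate_radius(system, drv, ...))
  }, numeric(1))
  out <- data.frame(pnp = grid, expansion_ratio = er,
                    regime = classify_cavitation(er, thresholds))
  class(out) <- c("sweep_result", "data.frame")
  attr(out, "thresholds") <- thresholds
  attr(out, "frequency") <- frequency
  out
}

#' Locate stable/inertial regime boundaries on a sweep
#'
#' Finds the PNPs at which the expansion-ratio curve first crosses the
#' stable-cavitation floor and the inertial-cavitation onset, by linear
#' interpolation at the first upward crossing of each threshold. A
#' threshold that is never crossed yields `NA` with `reached = FALSE`
#' rather than an error.
#'
#' @param sweep A `sweep_result` from [pressure_sweep()].
#' @param thresholds A [regime_thresholds()].
#' @return List with `stable_low` and `inertial_onset` (Pa, `NA` when not
#'   reached) and logical flags `stable_low_reached`,
#'   `inertial_onset_reached`.
#' @export
find_regime_boundaries <- function(sweep, thresholds = regime_thresholds()) {
  stopifnot(inherits(sweep, "sweep_result"))
  cross <- function(thr) {
    pnp <- sweep$pnp
    er <- sweep$expansion_ratio
    if (er[1] >= thr) return(pnp[1])
    i <- which(er[-length(er)] < thr & er[-1] >= thr)
    if (length(i) == 0) return(NA_real_)
    i <- i[1]
    pnp[i] + (thr - er[i]) * (pnp[i + 1] - pnp[i]) / (er[i + 1] - er[i])
  }
  lo <- cross(thresholds$stable_lower)
  hi <- cross(thresholds$inertial_onset)
  list(stable_low = lo, inertial_onset = hi,
       stable_low_reached = !is.na(lo), inertial_onset_reached = !is.na(hi))
}

#' Mechanical index
#'
#' Standard diagnostic-ultrasound mechanical index: PNP in MPa divided by
#' the square root of the frequency in MHz. The FDA diagnostic limit is
#' 1.9.
#'
#' @param pnp Peak negative pressure, Pa (>= 0).
#' @param frequency Center frequency, Hz (> 0).
#' @return Dimensionless mechanical index.
#' @export
mechanical_index <- function(pnp, frequency) {
  stopifnot(all(pnp >= 0))
  if (any(frequency <= 0)) stop("frequency must be positive")
  (pnp / 1e6) / sqrt(frequency / 1e6)
}

#' Quasi-static Blake threshold estimate
#'
#' Classical closed-form Blake threshold for a clean bubble with constant
#' surface tension, evaluated at the system's effective (resting) surface
#' tension: the ambient pressure plus the tension-driven instability term
#' \deqn{P_B = P_0 + \frac{4\sigma}{3}\sqrt{\frac{2\sigma}{3 P_{g0} R_0^3}}}
#' with \eqn{P_{g0} = P_0 + 2\sigma/R_0} (isothermal gas). This is a
#' diagnostic reference for the explosive-growth pressure scale of a
#' bubble driven far below resonance; it is an approximation and is not
#' used in regime classification.
#'
#' @param system A [bubble_system()].
#' @param sigma Surface tension to use, N/m; defaults to the shell's
#'   surface tension at the resting radius.
#' @return Threshold pressure in Pa.
#' @export
blake_threshold_estimate <- function(system,
                                     sigma = system$shell$initial_surface_tension) {
  stopifnot(inherits(system, "bubble_system"), sigma >= 0)
  R0 <- system$resting_radius
  P0 <- system$medium$ambient_pressure
  if (sigma == 0) return(P0)
  pg0 <- P0 + 2 * sigma / R0
  P0 + (4 * sigma / 3) * sqrt(2 * sigma / (3 * pg0 * R0^3))
}

#' @export
print.radius_trace <- function(x, ...) {
  cat(sprintf("radius_trace: %d samples over %.3g us%s\n",
              length(x$times), diff(range(x$times)) * 1e6,
              if (x$truncated_at_collapse) " (truncated at collapse)" else ""))
  cat(sprintf("  R0 = %.3g um, max R = %.3g um (expansion ratio %.3g)\n",
              x$resting_radius * 1e6, max(x$radii) * 1e6,
              max(x$radii) / x$resting_radius))
  invisible(x)
}

#' @export
plot.radius_trace <- function(x, ...) {
  plot(x$times * 1e6, x$radii * 1e6, type = "l",
       xlab = "time (us)", ylab = "radius (um)", ...)
  abline(h = x$resting_radius * 1e6, lty = 3)
  invisible(x)
}

#' @export
plot.sweep_result <- function(x, ...) {
  plot(x$pnp / 1e3, x$expansion_ratio, type = "l",
       xlab = "peak negative pressure (kPa)", ylab = "expansion ratio", ...)
  thr <- attr(x, "thresholds")
  if (!is.null(thr)) abline(h = c(thr$stable_lower, thr$inertial_onset), lty = 3)
  invisible(x)
}
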