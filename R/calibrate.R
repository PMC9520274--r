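er_at_pnp <- function(system, frequency, pnp, n_cycles, ...) {
  drv <- acoustic_drive(center_frequency = frequency,
                        peak_negative_pressure = pnp, n_cycles = n_cycles)
  expansion_ratio(simulate_radius(system, drv, ...))
}

# First upward crossing of `target_er` on [lo, hi] by bisection on the
# simulated expansion-ratio curve (assumed non-decreasing at this scale).
er_crossing <- function(system, frequency, target_er, lo = 0, hi = 300e3,
                        n_cycles = 50, iter = 16, ...) {
  f_lo <- er_at_pnp(system, frequency, lo, n_cycles, ...)
  f_hi <- er_at_pnp(system, frequency, hi, n_cycles, ...)
  if (f_lo >= target_er) return(lo)
  if (f_hi < target_er) return(NA_real_)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (er_at_pnp(system, frequency, mid, n_cycles, ...) >= target_er)
      hi <- mid
    else
      lo <- mid
  }
  (lo + hi) / 2
}

#' Calibrate shell parameters against expansion-ratio anchors
#'
#' The elastic modulus, surface viscosity and resting surface tension of
#' the lipid shell are not directly measurable here; this routine freezes
#' them by fitting the simulated expansion-ratio curve to a set of anchor
#' points (PNP, target expansion ratio) and, optionally, to target regime
#' boundaries (the PNPs at which the curve crosses the stable and
#' inertial thresholds). A single parameter set is chosen that minimizes
#' the mean squared relative error over all targets jointly; there is no
#' per-anchor tuning.
#'
#' Optimization is Nelder-Mead on log-transformed parameters, restricted
#' to the supplied search box (candidates outside the box are penalized).
#' Boundary predictions during the search use a bisection crossing
#' finder, which agrees with the sweep-plus-interpolation estimator of
#' [find_regime_boundaries()] to well below a grid step.
#'
#' @param anchors Data frame with columns `pnp` (Pa) and
#'   `expansion_ratio` (target, dimensionless); at least 2 rows required
#'   when no boundaries are given, at least 1 otherwise.
#' @param search_box Named list of `c(lower, upper)` ranges for any of
#'   `elastic_modulus` (N/m), `surface_viscosity` (kg/s),
#'   `initial_surface_tension` (N/m). Parameters not listed are held at
#'   the value in `system`.
#' @param boundaries Optional list with targets `stable_low` and/or
#'   `inertial_onset` in Pa.
#' @param system Template [bubble_system()] supplying all non-fitted
#'   parameters.
#' @param frequency,n_cycles Drive used for every prediction.
#' @param thresholds [regime_thresholds()] defining the boundary
#'   expansion ratios.
#' @param maxit Maximum Nelder-Mead iterations.
#' @param tol_rms Root-mean-square relative residual above which the
#'   result is flagged as a calibration failure (the best candidate is
#'   still returned).
#' @param ... Further arguments to [simulate_radius()].
#' @return An object of class `shell_calibration`: list with `shell`
#'   (the fitted [shell_properties()]), `system` (template rebuilt with
#'   the fitted shell), `residuals` (per-target relative errors),
#'   `rms_relative_error`, and `converged`.
#' @export
calibrate_shell <- function(anchors,
                            search_box,
                            boundaries = NULL,
                            system = bubble_system(),
                            frequency = 250e3,
                            n_cycles = 50,
                            thresholds = regime_thresholds(),
                            maxit = 150,
                            tol_rms = 0.2,
                            ...) {
  stopifnot(is.data.frame(anchors),
            all(c("pnp", "expansion_ratio") %in% names(anchors)))
  n_targets <- nrow(anchors) + length(boundaries)
  if (n_targets < 2) stop("need at least 2 calibration targets")
  if (!is.list(search_box) || length(search_box) == 0)
    stop("empty search box")
  allowed <- c("elastic_modulus", "surface_viscosity",
               "initial_surface_tension")
  if (!all(names(search_box) %in% allowed))
    stop("search_box names must be among: ", paste(allowed, collapse = ", "))
  for (b in search_box)
    if (length(b) != 2 || any(b <= 0) || b[2] < b[1])
      stop("each search_box entry must be positive c(lower, upper)")

  base <- system$shell[allowed]
  par_names <- names(search_box)
  lower <- log(vapply(search_box, `[`, numeric(1), 1))
  upper <- log(vapply(search_box, `[`, numeric(1), 2))

  build <- function(logp) {
    vals <- base
    vals[par_names] <- as.list(exp(logp))
    bubble_system(resting_radius = system$resting_radius,
                  gas = system$gas, medium = system$medium,
                  shell = shell_properties(
                    elastic_modulus = vals$elastic_modulus,
                    surface_viscosity = vals$surface_viscosity,
                    initial_surface_tension = vals$initial_surface_tension))
  }

  residuals_for <- function(sys) {
    res <- (vapply(anchors$pnp, function(p)
      er_at_pnp(sys, frequency, p, n_cycles, ...), numeric(1)) -
        anchors$expansion_ratio) / anchors$expansion_ratio
    names(res) <- sprintf("er_at_%g_kPa", anchors$pnp / 1e3)
    if (!is.null(boundaries$stable_low)) {
      pred <- er_crossing(sys, frequency, thresholds$stable_lower,
                          hi = 2 * boundaries$stable_low + 100e3,
                          n_cycles = n_cycles, ...)
      res <- c(res, stable_low = if (is.na(pred)) 2 else
        (pred - boundaries$stable_low) / boundaries$stable_low)
    }
    if (!is.null(boundaries$inertial_onset)) {
      pred <- er_crossing(sys, frequency, thresholds$inertial_onset,
                          hi = 2 * boundaries$inertial_onset + 100e3,
                          n_cycles = n_cycles, ...)
      res <- c(res, inertial_onset = if (is.na(pred)) 2 else
        (pred - boundaries$inertial_onset) / boundaries$inertial_onset)
    }
    res
  }

  objective <- function(logp) {
    pen <- sum(pmax(logp - upper, 0)^2) + sum(pmax(lower - logp, 0)^2)
    logp <- pmin(pmax(logp, lower), upper)
    sys <- build(logp)
    mean(residuals_for(sys)^2) + 100 * pen
  }

  start <- (lower + upper) / 2
  opt <- stats::optim(start, objective, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-4))
  best <- pmin(pmax(opt$par, lower), upper)
  fitted_sys <- build(best)
  res <- residuals_for(fitted_sys)
  rms <- sqrt(mean(res^2))
  out <- structure(list(shell = fitted_sys$shell,
                        system = fitted_sys,
                        residuals = res,
                        rms_relative_error = rms,
                        converged = rms <= tol_rms,
                        optim = opt),
                   class = "shell_calibration")
  if (!out$converged)
    warning(sprintf(
      "calibration residual %.3g exceeds tolerance %.3g; best candidate returned",
      rms, tol_rms))
  out
}

#' @export
print.shell_calibration <- function(x, ...) {
  cat("Shell calibration\n")
  cat(sprintf("  chi = %.4g N/m, kappa_s = %.4g kg/s, sigma(R0) = %.4g N/m\n",
              x$shell$elastic_modulus, x$shell$surface_viscosity,
              x$shell$initial_surface_tension))
  cat(sprintf("  rms relative residual: %.3g (%s)\n", x$rms_relative_error,
              if (x$converged) "converged" else "NOT converged"))
  cat("  per-target relative errors:\n")
  for (nm in names(x$residuals))
    cat(sprintf("    %-18s %+.3g\n", nm, x$residuals[nm]))
  invisible(x)
}
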