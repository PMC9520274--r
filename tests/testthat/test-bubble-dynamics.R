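sys <- default_bubble_system()
R0 <- sys$resting_radius

test_that("shell surface tension is piecewise, continuous and pinned at rest", {
  shell <- sys$shell
  med <- sys$medium
  rb <- shell$buckling_radius
  rr <- shell$rupture_radius
  eps <- 1e-9 * R0

  # buckled regime and the clean-interface plateau
  expect_equal(surface_tension(c(0.5 * rb, rb), shell, med), c(0, 0))
  expect_equal(surface_tension(rr, shell, med), med$water_surface_tension)
  expect_equal(surface_tension(2 * rr, shell, med), med$water_surface_tension)

  # continuity at both regime boundaries
  expect_lt(abs(surface_tension(rb + eps, shell, med) -
                surface_tension(rb - eps, shell, med)), 1e-6)
  expect_lt(abs(surface_tension(rr + eps, shell, med) -
                surface_tension(rr - eps, shell, med)), 1e-6)

  # buckling radius is constructed so sigma(R0) is the configured value
  expect_equal(surface_tension(R0, shell, med),
               shell$initial_surface_tension, tolerance = 1e-10)

  # bounded on a radius grid spanning all three regimes
  grid <- seq(0.2 * rb, 3 * rr, length.out = 200)
  sig <- surface_tension(grid, shell, med)
  expect_true(all(sig >= 0 & sig <= med$water_surface_tension))

  expect_error(surface_tension(-1e-6, shell, med))
})

test_that("drive pressure is a rarefaction-first pulse with PNP amplitude", {
  drv <- acoustic_drive(peak_negative_pressure = 500e3, n_cycles = 10)
  f <- drv$center_frequency
  expect_equal(drive_pressure(0, drv), 0)
  expect_equal(drive_pressure(1 / (4 * f), drv), -500e3)
  expect_equal(drive_pressure(3 / (4 * f), drv), 500e3)
  expect_equal(drive_pressure(10 / f + 1e-9, drv), 0)
  expect_equal(drive_pressure(0.3 / f, acoustic_drive(peak_negative_pressure = 0)), 0)
  tt <- seq(0, 10 / f, length.out = 5000)
  expect_equal(min(drive_pressure(tt, drv)), -500e3, tolerance = 1e-5)

  ramped <- acoustic_drive(peak_negative_pressure = 500e3, n_cycles = 10,
                           envelope = "ramped", ramp_cycles = 5)
  expect_equal(drive_pressure(1 / (4 * f), ramped), -500e3 * 0.25 / 5)
  expect_equal(drive_pressure(9.25 / f, ramped), -500e3)
})

test_that("rest is a fixed point of the dynamics and of the integrator", {
  drv0 <- acoustic_drive(peak_negative_pressure = 0)
  expect_equal(marmottant_rhs(c(R0, 0), 0, sys, drv0), c(0, 0))
  expect_error(marmottant_rhs(c(-R0, 0), 0, sys, drv0), "positive")

  tr <- simulate_radius(sys, drv0)
  expect_false(tr$truncated_at_collapse)
  expect_equal(tr$radii[1], R0)
  expect_lt(max(abs(tr$radii / R0 - 1)), 1e-6)
})

test_that("compiled and R right-hand sides integrate to the same trajectory", {
  drv <- acoustic_drive(peak_negative_pressure = 100e3, n_cycles = 5)
  trc <- simulate_radius(sys, drv, points_per_cycle = 100)
  trr <- simulate_radius(sys, drv, points_per_cycle = 100, engine = "R")
  expect_lt(max(abs(trc$radii - trr$radii)) / R0, 1e-6)

  # the reported velocity is the time derivative of the reported radius
  # (central differences on a fine output grid)
  trf <- simulate_radius(sys, drv, points_per_cycle = 1000)
  slope <- diff(trf$radii) / diff(trf$times)
  mid_v <- (trf$radial_velocities[-1] +
              trf$radial_velocities[-length(trf$times)]) / 2
  expect_lt(max(abs(slope - mid_v)) / max(abs(trf$radial_velocities)), 5e-3)
})

test_that("small-amplitude dynamics match the linearization of the RHS", {
  lin <- linearize_at_rest(sys)
  drv0 <- acoustic_drive(peak_negative_pressure = 0)

  # free relaxation of a small radial perturbation vs the 2x2 linear
  # solution (matrix exponential via eigendecomposition)
  x0 <- c(1e-4 * R0, 0)
  tt <- seq(0, 2e-7, length.out = 41)
  out <- deSolve::ode(y = c(R = R0 + x0[1], Rdot = 0), times = tt,
                      func = function(t, y, p)
                        list(marmottant_rhs(y, t, sys, drv0)),
                      rtol = 1e-10, atol = c(1e-14 * R0, 1e-10))
  ev <- eigen(lin$A)
  c0 <- solve(ev$vectors, x0)
  pred <- vapply(tt, function(t)
    Re(ev$vectors %*% (c0 * exp(ev$values * t)))[1], numeric(1))
  expect_lt(max(abs(out[, 2] - R0 - pred)) / abs(x0[1]), 0.02)

  # driven steady state at PNP = 1 kPa matches the linear-oscillator
  # response amplitude within 2%
  w <- 2 * pi * 250e3
  A_pred <- (1e3 / (sys$medium$density * R0)) /
    sqrt((lin$omega0_sq - w^2)^2 + (lin$two_beta * w)^2)
  tr <- simulate_radius(sys, acoustic_drive(peak_negative_pressure = 1e3),
                        points_per_cycle = 400)
  late <- tr$times > 40 / 250e3
  A_sim <- (max(tr$radii[late]) - min(tr$radii[late])) / 2
  expect_lt(abs(A_sim - A_pred) / A_pred, 0.02)
})

test_that("expansion ratio and regime classification follow their definitions", {
  flat <- structure(list(times = c(0, 1e-6), radii = c(R0, R0),
                         radial_velocities = c(0, 0),
                         truncated_at_collapse = FALSE, resting_radius = R0),
                    class = "radius_trace")
  expect_equal(expansion_ratio(flat), 1)
  flat$radii <- c(R0, 3 * R0)
  expect_equal(expansion_ratio(flat), 3)
  flat$radii <- numeric(0)
  expect_error(expansion_ratio(flat), "empty")

  expect_equal(as.character(classify_cavitation(c(1.05, 2, 4))),
               c("negligible", "stable", "inertial"))
  # boundary values are inclusive for the stable band
  expect_equal(as.character(classify_cavitation(c(1.1, 3.5))),
               c("stable", "stable"))
})

test_that("sweep is compositional and boundary interpolation is exact on synthetic curves", {
  sw <- pressure_sweep(sys, pnp_min = 0, pnp_max = 200e3, step = 100e3)
  expect_equal(sw$pnp, c(0, 100e3, 200e3))
  single <- vapply(sw$pnp, function(p)
    expansion_ratio(simulate_radius(sys,
      acoustic_drive(peak_negative_pressure = p))), numeric(1))
  expect_equal(sw$expansion_ratio, single)
  expect_equal(sw$expansion_ratio[1], 1, tolerance = 1e-6)
  expect_equal(as.character(sw$regime[1]), "negligible")

  # synthetic piecewise-linear curve: crossings recovered exactly
  make_sweep <- function(pnp, er) {
    out <- data.frame(pnp = pnp, expansion_ratio = er,
                      regime = classify_cavitation(er))
    class(out) <- c("sweep_result", "data.frame")
    out
  }
  pnp <- seq(0, 300e3, by = 5e3)
  syn <- make_sweep(pnp, 1 + pnp / 100e3)
  b <- find_regime_boundaries(syn)
  expect_equal(b$stable_low, 10e3, tolerance = 1e-10)
  expect_equal(b$inertial_onset, 250e3, tolerance = 1e-10)

  # never crossed: explicit not-reached result, not an error
  low <- make_sweep(pnp, rep(1.0, length(pnp)))
  b2 <- find_regime_boundaries(low)
  expect_false(b2$stable_low_reached)
  expect_false(b2$inertial_onset_reached)
  expect_true(is.na(b2$stable_low))

  # curve already above the threshold at the grid start
  hi <- make_sweep(pnp, 2 + pnp / 100e3)
  expect_equal(find_regime_boundaries(hi)$stable_low, 0)
})

test_that("regime boundaries satisfy ER(boundary) = threshold by construction", {
  sw <- pressure_sweep(sys, pnp_min = 60e3, pnp_max = 250e3, step = 5e3)
  b <- find_regime_boundaries(sw)
  expect_true(b$stable_low_reached && b$inertial_onset_reached)
  expect_lt(b$stable_low, b$inertial_onset)
  er_lo <- expansion_ratio(simulate_radius(sys,
    acoustic_drive(peak_negative_pressure = b$stable_low)))
  expect_equal(er_lo, 1.1, tolerance = 0.02)
})

test_that("mechanical index and Blake threshold follow their closed forms", {
  expect_equal(mechanical_index(0, 1e6), 0)
  expect_equal(mechanical_index(800e3, 250e3), 1.6)
  expect_lt(mechanical_index(800e3, 250e3), 1.9)
  expect_equal(mechanical_index(1.9e6, 1e6), 1.9)
  expect_error(mechanical_index(1e5, 0))

  P0 <- sys$medium$ambient_pressure
  expect_equal(blake_threshold_estimate(sys, sigma = 0), P0)
  # independent evaluation of the documented closed form
  sigw <- sys$medium$water_surface_tension
  pg0 <- P0 + 2 * sigw / R0
  expect_equal(blake_threshold_estimate(sys, sigma = sigw),
               P0 + (4 * sigw / 3) * sqrt(2 * sigw / (3 * pg0 * R0^3)))
  # smaller bubbles have larger thresholds
  radii <- c(2, 1.5, 1, 0.75, 0.5) * 1e-6
  thr <- vapply(radii, function(r)
    blake_threshold_estimate(bubble_system(resting_radius = r)), numeric(1))
  expect_true(all(diff(thr) > 0))
})

test_that("inertial collapse truncates the trace and keeps the pre-collapse maximum", {
  tr <- simulate_radius(sys, acoustic_drive(peak_negative_pressure = 500e3))
  expect_true(tr$truncated_at_collapse)
  expect_gte(min(tr$radii), 0.05 * R0 * 0.99)
  expect_gt(expansion_ratio(tr), 3.5)
  expect_lt(max(tr$times), 50 / 250e3)
})

test_that("the frozen YAML config round-trips into the default system", {
  cfg <- load_bubble_config()
  expect_equal(cfg$system$resting_radius, 0.75e-6)
  expect_equal(cfg$drive_template$center_frequency, 250e3)
  expect_equal(cfg$thresholds$stable_lower, 1.1)
  expect_equal(cfg$thresholds$inertial_onset, 3.5)
  # mechanical equilibrium invariant of the assembled system
  expect_equal(cfg$system$equilibrium_gas_pressure,
               cfg$system$medium$ambient_pressure +
                 2 * cfg$system$shell$initial_surface_tension /
                   cfg$system$resting_radius)
})
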