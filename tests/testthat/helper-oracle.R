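# Independent fixed-step 4th-order Runge-Kutta oracle for the shelled
# bubble dynamics. The model formula is written out again here, from
# scratch, so the oracle shares neither the compiled right-hand side nor
# the adaptive integrator with the implementation it checks.
rk4_oracle <- function(system, drive, n_cycles = drive$n_cycles,
                       steps_per_cycle = 1e4, keep_every = 100) {
  R0 <- system$resting_radius
  chi <- system$shell$elastic_modulus
  ks <- system$shell$surface_viscosity
  rb <- system$shell$buckling_radius
  rr <- system$shell$rupture_radius
  sigw <- system$medium$water_surface_tension
  rho <- system$medium$density
  mu <- system$medium$dynamic_viscosity
  cs <- system$medium$sound_speed
  P0 <- system$medium$ambient_pressure
  pv <- system$gas$vapor_pressure
  k3 <- 3 * system$gas$polytropic_exponent
  pnp <- drive$peak_negative_pressure
  f <- drive$center_frequency
  t_on <- drive$n_cycles / f

  sig <- function(R) {
    if (R <= rb) return(0)
    if (R < rr) return(chi * ((R / rb)^2 - 1))
    sigw
  }
  pg0 <- P0 + 2 * sig(R0) / R0 - pv

  acc <- function(t, R, Rd) {
    pac <- if (t >= 0 && t < t_on) -pnp * sin(2 * pi * f * t) else 0
    pb <- pg0 * (R0 / R)^k3 * (1 - k3 * Rd / cs) + pv -
      2 * sig(R) / R - 4 * mu * Rd / R - 4 * ks * Rd / R^2 - P0 - pac
    (pb / rho - 1.5 * Rd^2) / R
  }

  dt <- 1 / (f * steps_per_cycle)
  n_steps <- n_cycles * steps_per_cycle
  n_keep <- n_steps / keep_every
  stopifnot(n_keep == round(n_keep))
  times <- numeric(n_keep + 1)
  radii <- numeric(n_keep + 1)
  R <- R0
  Rd <- 0
  times[1] <- 0
  radii[1] <- R
  j <- 1
  t <- 0
  for (i in seq_len(n_steps)) {
    k1r <- Rd
    k1v <- acc(t, R, Rd)
    k2r <- Rd + dt / 2 * k1v
    k2v <- acc(t + dt / 2, R + dt / 2 * k1r, Rd + dt / 2 * k1v)
    k3r <- Rd + dt / 2 * k2v
    k3v <- acc(t + dt / 2, R + dt / 2 * k2r, Rd + dt / 2 * k2v)
    k4r <- Rd + dt * k3v
    k4v <- acc(t + dt, R + dt * k3r, Rd + dt * k3v)
    R <- R + dt / 6 * (k1r + 2 * k2r + 2 * k3r + k4r)
    Rd <- Rd + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
    t <- i * dt
    if (i %% keep_every == 0) {
      j <- j + 1
      times[j] <- t
      radii[j] <- R
    }
  }
  list(times = times, radii = radii)
}

# 2x2 linearization of the radial dynamics around rest, by central
# finite differences of the package's R-level right-hand side.
linearize_at_rest <- function(system, h_rel = 1e-7) {
  R0 <- system$resting_radius
  drv <- acoustic_drive(peak_negative_pressure = 0)
  h <- h_rel * R0
  dfdR <- (marmottant_rhs(c(R0 + h, 0), 0, system, drv)[2] -
           marmottant_rhs(c(R0 - h, 0), 0, system, drv)[2]) / (2 * h)
  hv <- 1e-3
  dfdV <- (marmottant_rhs(c(R0, hv), 0, system, drv)[2] -
           marmottant_rhs(c(R0, -hv), 0, system, drv)[2]) / (2 * hv)
  list(omega0_sq = -dfdR, two_beta = -dfdV,
       A = matrix(c(0, dfdR, 1, dfdV), 2, 2))
}
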