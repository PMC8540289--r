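# Independent oracles used to validate the model implementation.

# Fixed-step explicit Euler integration of the shrinkage model; deliberately
# naive and independent of the package's adaptive solver.
euler_volume <- function(radius0, p, dpi, k_mech, t0, times, dt = 1e-5,
                         area_mode = "sphere") {
  v0 <- 4 / 3 * pi * radius0^3
  a0 <- 4 * pi * radius0^2
  vw <- 1.8e-5
  ts <- seq(t0, max(times) + dt, by = dt)
  vs <- numeric(length(ts))
  v <- v0
  vs[1] <- v
  for (i in seq_along(ts)[-1]) {
    a <- if (area_mode == "sphere") a0 * (v / v0)^(2 / 3) else a0
    v <- v - dt * a * vw * p * (dpi - k_mech * (v0 - v) / v0)
    vs[i] <- v
  }
  vapply(times, function(tt) {
    if (tt < t0) v0 else approx(ts, vs, xout = tt)$y
  }, numeric(1))
}

# Closed-form trajectory for the frozen-area variant (linear ODE):
# exponential saturation to relative volume loss dpi/k_mech.
frozen_area_volume <- function(radius0, p, dpi, k_mech, t0, times) {
  v0 <- 4 / 3 * pi * radius0^3
  a0 <- 4 * pi * radius0^2
  vw <- 1.8e-5
  tau <- v0 / (a0 * vw * p * k_mech)
  eps <- dpi / k_mech
  ifelse(times < t0, v0, v0 * (1 - eps * (1 - exp(-(times - t0) / tau))))
}

# Default simulated trace used across trace-fit tests.
make_default_trace <- function(dpi, t0 = NULL, noise_sd = 0, seed = NULL,
                               p = 2e-5, gamma = 10, k_mech = 1500,
                               times = seq(0, 1, by = 1e-3), dead_time = 0.01) {
  if (is.null(t0)) t0 <- 2 / dpi
  simulate_shrinkage_trace(
    osmotic_condition(dpi),
    shrinkage_physics(permeability = p, t0 = t0, k_mech = k_mech),
    optics = optics_map(5, 4, gamma),
    times = times, dead_time = dead_time, noise_sd = noise_sd, seed = seed)
}

A0_55NM <- 4 * pi * (55e-9)^2
V0_55NM <- 4 / 3 * pi * (55e-9)^3
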