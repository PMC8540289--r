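## Two-phase fluorescence kinetics of a membrane-bound pH probe
## (fluorescein-PE): a fast exponential phase from (de)protonation of the
## outer-leaflet dye population, then a slow linear rise whose slope is
## proportional to the transmembrane proton flux through water-filled lipid
## pores. The slow slope is coupled linearly to the osmotic pressure
## difference: more osmotic drive means more open pores, hence more Grotthuss
## proton transfer.

#' Two-phase proton-flux kinetics parameters
#'
#' @param f0 Baseline fluorescence, a.u.
#' @param a_fast Outer-leaflet amplitude at the reference pH gradient, a.u.;
#'   its effective sign follows the sign of `delta_ph`.
#' @param tau_fast Fast-phase time constant, s; positive.
#' @param s_ref Slow-slope scale, a.u./s per pH unit at unit coupling.
#' @param dph_ref Reference pH gradient used to scale `a_fast`, default 1.4.
#' @return Object of class `"proton_kinetics"`.
#' @export
proton_kinetics <- function(f0 = 100, a_fast = 8, tau_fast = 5,
                            s_ref = 0.05, dph_ref = 1.4) {
  if (!is.finite(tau_fast) || tau_fast <= 0) {
    stop_invalid("tau_fast must be > 0")
  }
  structure(
    list(f0 = f0, a_fast = a_fast, tau_fast = tau_fast, s_ref = s_ref,
         dph_ref = dph_ref),
    class = "proton_kinetics"
  )
}

#' Slow proton-flux slope implied by the coupling model
#'
#' `m_slow = s_ref * delta_ph * (g0 + c_pi * delta_pi)`: linear in the pH
#' gradient over the small range used, with a positive baseline `g0`
#' (pores open occasionally even without osmotic drive) and linear gain
#' `c_pi` in the osmotic pressure difference.
#'
#' @param kin A [proton_kinetics()].
#' @param cond An [osmotic_condition()].
#' @param coupling Named list or vector with `g0` and `c_pi` (per mOsm).
#' @return Slope, a.u./s.
#' @export
proton_slow_slope <- function(kin, cond, coupling = default_proton_coupling()) {
  stopifnot(inherits(kin, "proton_kinetics"),
            inherits(cond, "osmotic_condition"))
  kin$s_ref * cond$delta_ph * (coupling$g0 + coupling$c_pi * cond$delta_pi)
}

#' Default proton-flux coupling to the osmotic pressure difference
#'
#' @return List with baseline `g0 = 1` (dimensionless) and gain
#'   `c_pi = 0.02` per mOsm, so the slow slope at 150 mOsm is 4x the
#'   zero-osmotic-drive slope.
#' @export
default_proton_coupling <- function() list(g0 = 1, c_pi = 0.02)

#' Simulate a fluorescence trace of transmembrane proton flux
#'
#' \deqn{F(t) = f_0 + a_{fast} \frac{\Delta pH}{\Delta pH_{ref}}
#'       (1 - e^{-t/\tau_{fast}}) + m_{slow}\, t}
#' with `m_slow` from [proton_slow_slope()]. When the pH gradient is zero but
#' an osmotic difference is present, a small osmotic artifact is added
#' (default: a fast-saturating bump plus a linear term at 3% of the slope the
#' same osmotic condition would give at the reference pH gradient), mirroring
#' the control in which the osmotically induced interface change stays below
#' 5% of the pH-driven signal.
#'
#' @param kin A [proton_kinetics()].
#' @param cond An [osmotic_condition()] (signed `delta_ph`).
#' @param coupling See [proton_slow_slope()].
#' @param times Time grid, s; should span at least 150 s for the windowed
#'   slope estimator.
#' @param noise_sd Gaussian noise sd, a.u.
#' @param seed Optional integer seed.
#' @param osmotic_artifact Include the zero-`delta_ph` osmotic artifact term,
#'   default `TRUE`.
#' @param artifact_frac Linear artifact slope as a fraction of the
#'   reference-pH slope, default 0.03.
#' @return An `"of_trace"` with `meta$kind = "fluorescence"`.
#' @export
simulate_fluorescence <- function(kin, cond,
                                  coupling = default_proton_coupling(),
                                  times = seq(0, 160, by = 0.25),
                                  noise_sd = 0, seed = NULL,
                                  osmotic_artifact = TRUE,
                                  artifact_frac = 0.03) {
  stopifnot(inherits(kin, "proton_kinetics"),
            inherits(cond, "osmotic_condition"))
  if (any(diff(times) <= 0)) stop_invalid("times must be strictly increasing")
  fast <- kin$a_fast * (cond$delta_ph / kin$dph_ref) *
    (1 - exp(-times / kin$tau_fast))
  m_slow <- proton_slow_slope(kin, cond, coupling)
  f <- kin$f0 + fast + m_slow * times
  if (osmotic_artifact && cond$delta_ph == 0 && cond$delta_pi > 0) {
    ref_slope <- kin$s_ref * kin$dph_ref *
      (coupling$g0 + coupling$c_pi * cond$delta_pi)
    f <- f + 0.5 * (1 - exp(-times / 10)) + artifact_frac * ref_slope * times
  }
  if (noise_sd > 0) {
    f <- f + with_seed(seed, rnorm(length(f), sd = noise_sd))
  }
  meta <- list(kind = "fluorescence", delta_pi_mosm = cond$delta_pi,
               delta_ph = cond$delta_ph, solute = cond$solute,
               dead_time_s = 0, temperature_k = 298.15, composition = "PC",
               m_slow_true = m_slow)
  if (!is.null(seed)) meta$seed <- seed
  new_trace(times, f, meta)
}

#' Windowed slope of a fluorescence trace
#'
#' Ordinary least-squares slope of the fluorescence over a late time window
#' (default 80--150 s), after the fast outer-leaflet phase has decayed; the
#' slope is proportional to the transmembrane proton flux.
#'
#' @param trace An `"of_trace"` (fluorescence kinetics).
#' @param window Two times, s; must lie within the trace span and contain at
#'   least 10 samples.
#' @return Slope, a.u./s.
#' @export
window_slope <- function(trace, window = c(80, 150)) {
  stopifnot(inherits(trace, "of_trace"))
  t <- trace$times
  if (window[1] < t[1] || window[2] > t[length(t)] || window[1] >= window[2]) {
    stop_invalid("window outside the trace span")
  }
  inside <- t >= window[1] & t <= window[2]
  if (sum(inside) < 10L) {
    stop_insufficient("fewer than 10 samples inside the window")
  }
  unname(coef(lm(trace$intensities[inside] ~ t[inside]))[2])
}

#' Classify photobleaching from a long-time drift
#'
#' A drift is negligible when the total fluorescence change it would produce
#' over the stated duration stays below 3% of the baseline.
#'
#' @param slope Drift slope, a.u./s.
#' @param f0 Baseline fluorescence, a.u.
#' @param duration Observation span, s; default 3 hours.
#' @return `"negligible"` or `"significant"`.
#' @export
classify_photobleaching <- function(slope, f0, duration = 3 * 3600) {
  if (abs(slope) * duration < 0.03 * abs(f0)) "negligible" else "significant"
}

#' Proton flux response to the osmotic pressure difference
#'
#' Sorts windowed slopes by osmotic pressure difference and reports whether
#' the flux is non-decreasing in the osmotic drive (the coupling signature).
#' Duplicate `delta_pi` entries are averaged with a warning.
#'
#' @param delta_pi Osmotic pressure differences, mOsm (>= 2 conditions);
#'   alternatively a data frame with columns `delta_pi` and `slope`.
#' @param slope Windowed slopes, a.u./s.
#' @return Object of class `"flux_response"`: the sorted table, `verdict`
#'   (`"increasing"` or `"not increasing"`) and `flat` (all slopes equal).
#' @export
flux_response <- function(delta_pi, slope) {
  if (is.data.frame(delta_pi)) {
    slope <- delta_pi$slope
    delta_pi <- delta_pi$delta_pi
  }
  if (length(delta_pi) < 2L) stop_insufficient("need at least 2 conditions")
  if (anyDuplicated(delta_pi)) {
    warning("duplicate delta_pi entries averaged")
    slope <- tapply(slope, delta_pi, mean)
    delta_pi <- as.numeric(names(slope))
    slope <- as.numeric(slope)
  }
  ord <- order(delta_pi)
  tab <- data.frame(delta_pi = delta_pi[ord], slope = slope[ord])
  increasing <- all(diff(tab$slope) >= 0)
  structure(
    list(table = tab,
         verdict = if (increasing) "increasing" else "not increasing",
         flat = all(tab$slope == tab$slope[1])),
    class = "flux_response"
  )
}

#' @export
print.flux_response <- function(x, ...) {
  cat("Proton flux vs osmotic pressure difference\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("  verdict: %s%s\n", x$verdict,
              if (x$flat) " (flat)" else ""))
  invisible(x)
}
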