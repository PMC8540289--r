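## Parameterization of stopped-flow kinetic curves: the deflection time t0
## (end of stage I / pore opening), plateau intensities, the stage-II average
## slope and the derived osmotic water permeability; plus the two run-level
## regressions: t0 against 1/dpi and t0 against bending rigidity.

## OLS slope of (1 - exp(-t/tau)) over its first half-rise, i.e. the factor by
## which the average stage-II slope (window ending at 50% of the rise)
## underestimates the initial slope of a saturating-exponential recovery.
## Closed form: 12 * [(c/2)(1 - e^-c) - 1 + (1+c) e^-c] / c^3 with c = ln 2.
HALF_RISE_OLS_FACTOR <- local({
  cc <- log(2)
  12 * ((cc / 2) * (1 - exp(-cc)) - 1 + (1 + cc) * exp(-cc)) / cc^3
})

## Shape factor for the stage-II OLS slope under the full model, where the
## shrinking surface area makes the recovery slightly faster-saturating than
## exponential. x(s) solves dx/ds = (1 - eps*x)^(2/3) (1 - x) with x the
## fraction of the equilibrium volume loss, eps the relative equilibrium
## volume loss (delta_pi / k_mech) and s = t/tau; the factor is the OLS slope
## of x over [0, s_half] (x(s_half) = 1/2) relative to the initial slope 1.
## eps = 0 reduces to the closed-form exponential factor above.
ols_shape_factor <- function(rel_loss = 0) {
  if (!is.finite(rel_loss) || rel_loss <= 1e-6) return(HALF_RISE_OLS_FACTOR)
  rel_loss <- min(rel_loss, 0.9)
  s <- seq(0, 3, by = 0.002)
  sol <- deSolve::ode(c(x = 0), s, function(s, y, p) {
    list((1 - rel_loss * y[1])^(2 / 3) * (1 - y[1]))
  }, parms = NULL, rtol = 1e-8, atol = 1e-10)
  x <- sol[, "x"]
  s_half <- approx(x, s, xout = 0.5)$y
  win <- s <= s_half
  sw <- s[win]
  xw <- x[win]
  sum((sw - mean(sw)) * (xw - mean(xw))) / sum((sw - mean(sw))^2)
}

sg_smooth <- function(y, window) {
  if (window < 3 || window %% 2 == 0) {
    stop_invalid("smooth_window must be odd and >= 3")
  }
  if (length(y) < window) stop_invalid("trace shorter than smooth_window")
  as.numeric(signal::sgolayfilt(y, p = 2, n = window))
}

#' Detect the deflection point of a shrinkage trace
#'
#' The deflection time `t0` is the time needed to reach the minimum of the
#' scattered-light intensity (the end of stage I). The trace is smoothed with
#' a local quadratic (Savitzky--Golay) filter; the global minimum after the
#' dead time is refined by parabolic interpolation through the minimum and its
#' two neighbours.
#'
#' Outcomes other than a clean estimate are reported through `status`:
#' `"unresolvable"` when the minimum sits at the first retained sample (the
#' true delay lies below the instrument dead time) and `"no-deflection"` when
#' there is no recovery phase after the minimum (e.g. the flat isosmotic
#' control, or a monotonically decreasing trace).
#'
#' @param trace An `"of_trace"`.
#' @param smooth_window Odd window length (samples) of the smoother,
#'   default 11.
#' @return List with `t0_est` (s, `NA` for `"no-deflection"`), `resolvable`
#'   (logical) and `status` (`"ok"`, `"unresolvable"` or `"no-deflection"`).
#' @export
detect_deflection <- function(trace, smooth_window = 11) {
  stopifnot(inherits(trace, "of_trace"))
  y <- sg_smooth(trace$intensities, smooth_window)
  t <- trace$times
  n <- length(y)
  i_min <- which.min(y)

  ## recovery after the minimum must be distinguishable from noise
  noise <- mad(diff(trace$intensities)) / sqrt(2)
  rise_after <- if (i_min < n) max(y[i_min:n]) - y[i_min] else 0
  span <- diff(range(y))
  if (rise_after <= max(5 * noise, 1e-3 * span, 1e-12)) {
    return(list(t0_est = NA_real_, resolvable = NA, status = "no-deflection"))
  }
  if (i_min == 1L) {
    return(list(t0_est = t[1], resolvable = FALSE, status = "unresolvable"))
  }
  ## the smoothed minimum is biased toward the flatter (stage-I) side of the
  ## kink by up to half the filter window; re-locate on the raw trace nearby
  yr <- trace$intensities
  h2 <- (smooth_window - 1L) %/% 2L
  lo <- max(1L, i_min - h2)
  hi <- min(n, i_min + h2)
  i_min <- lo - 1L + which.min(yr[lo:hi])
  if (i_min == 1L) {
    return(list(t0_est = t[1], resolvable = FALSE, status = "unresolvable"))
  }
  t0 <- t[i_min]
  if (i_min > 1L && i_min < n) {
    h <- t[i_min + 1] - t[i_min]
    denom <- yr[i_min - 1] - 2 * yr[i_min] + yr[i_min + 1]
    if (denom > 0) {
      delta <- 0.5 * (yr[i_min - 1] - yr[i_min + 1]) / denom
      t0 <- t[i_min] + h * max(-0.5, min(0.5, delta))
    }
  }
  list(t0_est = t0, resolvable = TRUE, status = "ok")
}

#' Extract the plateau intensities of a trace
#'
#' Robust estimates of the three characteristic levels of the kinetic curve:
#' `i_00` (pre-mix level; median of the first `n_first` retained samples, or a
#' supplied pre-mix reference), `i_0fin` (intensity at the deflection point,
#' averaged over the three nearest raw samples -- the quadratic smoother is
#' biased upward at the stage-I/II kink) and `i_finfin` (median of the final
#' `tail_frac` fraction of
#' samples), together with the stage-I drop `i_00 - i_0fin` and the
#' stage-II/III rise `i_finfin - i_0fin`.
#'
#' @param trace An `"of_trace"`.
#' @param t0_est Deflection time estimate, s; must fall within the trace span.
#' @param i_00_ref Optional known pre-mix intensity; overrides the first-sample
#'   median (useful when stage I is mostly lost in the dead time).
#' @param n_first Number of initial samples for `i_00`, default 5.
#' @param tail_frac Final fraction of samples for `i_finfin`, default 0.05.
#' @param smooth_window Smoother window for `i_0fin`, default 11.
#' @return List with `i_00`, `i_0fin`, `i_finfin`, `drop_stage1`,
#'   `rise_stage23` and logical `plateau_warning` (set when the final window
#'   still drifts, i.e. the trace has not plateaued).
#' @export
extract_plateaus <- function(trace, t0_est, i_00_ref = NULL, n_first = 5,
                             tail_frac = 0.05, smooth_window = 11) {
  stopifnot(inherits(trace, "of_trace"))
  t <- trace$times
  if (!is.finite(t0_est) || t0_est < t[1] || t0_est > t[length(t)]) {
    stop_invalid("t0_est outside the trace span")
  }
  y <- trace$intensities
  i_00 <- if (!is.null(i_00_ref)) i_00_ref else median(head(y, n_first))
  i_idx <- which.min(abs(t - t0_est))
  i_0fin <- mean(y[max(1L, i_idx - 1L):min(length(y), i_idx + 1L)])

  n_tail <- max(5L, ceiling(tail_frac * length(y)))
  tail_idx <- seq.int(length(y) - n_tail + 1L, length(y))
  i_finfin <- median(y[tail_idx])
  ## drift check: final-window slope times window length vs noise level
  tail_fit <- lm(y[tail_idx] ~ t[tail_idx])
  drift <- abs(coef(tail_fit)[2]) * (t[tail_idx[n_tail]] - t[tail_idx[1]])
  noise <- mad(diff(y)) / sqrt(2)
  plateau_warning <- drift > max(3 * noise, 1e-3 * abs(i_finfin - i_0fin))

  list(i_00 = i_00, i_0fin = i_0fin, i_finfin = i_finfin,
       drop_stage1 = i_00 - i_0fin, rise_stage23 = i_finfin - i_0fin,
       plateau_warning = unname(plateau_warning))
}

#' Average stage-II slope of a shrinkage trace
#'
#' Ordinary least-squares slope of the intensity over the early, quasi-linear
#' part of the recovery: from the deflection point to the time the intensity
#' first exceeds half of the stage-II/III rise.
#'
#' @param trace An `"of_trace"`.
#' @param t0_est Deflection time estimate, s; at least 10 samples must follow
#'   it.
#' @param plateaus Optional result of [extract_plateaus()]; computed if
#'   missing.
#' @param smooth_window Smoother window used to locate the half-rise crossing.
#' @return List with `slope` (a.u./s), `window` (start/end times, s) and
#'   `n_samples`.
#' @export
stage2_slope <- function(trace, t0_est, plateaus = NULL, smooth_window = 11) {
  stopifnot(inherits(trace, "of_trace"))
  t <- trace$times
  y <- trace$intensities
  after <- which(t >= t0_est)
  if (length(after) < 10L) {
    stop_insufficient("need at least 10 samples after t0_est")
  }
  if (is.null(plateaus)) {
    plateaus <- extract_plateaus(trace, t0_est, smooth_window = smooth_window)
  }
  ys <- sg_smooth(y, smooth_window)
  thresh <- plateaus$i_0fin + 0.5 * plateaus$rise_stage23
  ## first *sustained* crossing (3 consecutive smoothed samples above the
  ## threshold), so an isolated noise spike cannot truncate the window
  above <- ys[after] > thresh
  r <- rle(above)
  ends <- cumsum(r$lengths)
  sust <- which(r$values & r$lengths >= 3L)
  i_end <- if (length(sust)) {
    after[ends[sust[1]] - r$lengths[sust[1]] + 1L]
  } else {
    after[length(after)]
  }
  win <- after[after <= i_end]
  if (length(win) < 5L) {
    stop_insufficient("stage-II window shorter than 5 samples")
  }
  fit <- lm(y[win] ~ t[win])
  list(slope = unname(coef(fit)[2]),
       window = c(start = t[win[1]], end = t[win[length(win)]]),
       n_samples = length(win))
}

#' Osmotic water permeability from the stage-II slope
#'
#' Inverts the osmotic flux law for the permeability:
#' \deqn{P = s\, V_0 / (c\, \gamma\, A_0\, V_w\, \Delta\pi)}
#' where `s` is the average stage-II slope in intensity units and `gamma` the
#' optical gain (a.u. per unit relative volume loss). The factor `c = 0.7156`
#' corrects for the fact that the OLS slope of a saturating-exponential
#' recovery taken over its first half-rise underestimates the initial slope;
#' set `shape_correction = FALSE` for the raw inversion. When `gamma` is
#' unknown it is taken as 1 and the result is flagged as relative units.
#'
#' @param slope Stage-II slope, a.u./s.
#' @param optics_gamma Optical gain, a.u.; `NULL` for unknown.
#' @param geometry A [vesicle_state()] giving `V0` and `A0`.
#' @param delta_pi Osmotic pressure difference, mOsm; must be positive.
#' @param shape_correction Apply the half-rise OLS factor (default `TRUE`).
#' @param rel_volume_loss Optional relative equilibrium volume loss
#'   \eqn{\Delta\pi/k_{mech}} (equivalently `rise_stage23 / gamma`); when
#'   given, the shape factor additionally accounts for the shrinking surface
#'   area along the trajectory.
#' @return List with `p_est` and `units` (`"m/s"` or `"relative"`).
#' @export
permeability_from_slope <- function(slope, optics_gamma, geometry, delta_pi,
                                    shape_correction = TRUE,
                                    rel_volume_loss = NULL) {
  stopifnot(inherits(geometry, "vesicle_state"))
  if (!is.finite(delta_pi) || delta_pi <= 0) {
    stop_invalid("delta_pi must be > 0 for a permeability estimate")
  }
  relative <- is.null(optics_gamma)
  gam <- if (relative) 1 else optics_gamma
  if (gam <= 0) stop_invalid("optics_gamma must be > 0")
  corr <- if (!shape_correction) {
    1
  } else if (is.null(rel_volume_loss)) {
    HALF_RISE_OLS_FACTOR
  } else {
    ols_shape_factor(rel_volume_loss)
  }
  p <- slope * geometry$volume / (corr * gam * geometry$area * V_W * delta_pi)
  list(p_est = p, units = if (relative) "relative" else "m/s")
}

#' Fit the full parameterization of a shrinkage trace
#'
#' One-call parameterization of a stopped-flow trace: deflection time
#' ([detect_deflection()]), plateau intensities ([extract_plateaus()]),
#' stage-II slope ([stage2_slope()]) and derived permeability
#' ([permeability_from_slope()]).
#'
#' @param trace An `"of_trace"`.
#' @param smooth_window Smoother window, odd, default 11.
#' @param optics_gamma Optical gain for the permeability estimate; `NULL`
#'   (default) flags the permeability as relative units.
#' @param geometry A [vesicle_state()]; default 55 nm radius.
#' @param i_00_ref Optional pre-mix intensity reference.
#' @return Object of class `"shrinkage_fit"`.
#' @examples
#' tr <- simulate_shrinkage_trace(osmotic_condition(50),
#'                                shrinkage_physics(t0 = 0.04))
#' fit <- fit_trace(tr, optics_gamma = 10)
#' coef(fit)
#' @export
fit_trace <- function(trace, smooth_window = 11, optics_gamma = NULL,
                      geometry = vesicle_state(radius = 55e-9),
                      i_00_ref = NULL) {
  stopifnot(inherits(trace, "of_trace"))
  det <- detect_deflection(trace, smooth_window)
  res <- list(trace_meta = trace$meta, t0_est = det$t0_est,
              resolvable = det$resolvable, status = det$status,
              smooth_window = smooth_window)
  if (det$status == "no-deflection") {
    res[c("i_00", "i_0fin", "i_finfin", "drop_stage1", "rise_stage23",
          "slope", "p_est")] <- NA_real_
    res$p_units <- NA_character_
    return(structure(res, class = "shrinkage_fit"))
  }
  pl <- extract_plateaus(trace, det$t0_est, i_00_ref = i_00_ref,
                         smooth_window = smooth_window)
  res[names(pl)] <- pl
  s2 <- stage2_slope(trace, det$t0_est, plateaus = pl,
                     smooth_window = smooth_window)
  res$slope <- s2$slope
  res$stage2_window <- s2$window
  dpi <- trace$meta$delta_pi_mosm
  if (!is.null(dpi) && is.finite(dpi) && dpi > 0) {
    rel_loss <- if (is.null(optics_gamma)) NULL else {
      max(0, pl$rise_stage23 / optics_gamma)
    }
    pe <- permeability_from_slope(s2$slope, optics_gamma, geometry, dpi,
                                  rel_volume_loss = rel_loss)
    res$p_est <- pe$p_est
    res$p_units <- pe$units
  } else {
    res$p_est <- NA_real_
    res$p_units <- NA_character_
  }
  structure(res, class = "shrinkage_fit")
}

#' @export
print.shrinkage_fit <- function(x, ...) {
  cat("Stopped-flow shrinkage trace fit\n")
  cat(sprintf("  status: %s\n", x$status))
  if (x$status != "no-deflection") {
    cat(sprintf("  t0 = %.4g s (%s)\n", x$t0_est,
                if (isTRUE(x$resolvable)) "resolvable" else "below dead time"))
    cat(sprintf("  stage-I drop = %.4g a.u., stage-II/III rise = %.4g a.u.\n",
                x$drop_stage1, x$rise_stage23))
    cat(sprintf("  stage-II slope = %.4g a.u./s\n", x$slope))
    if (is.finite(x$p_est)) {
      cat(sprintf("  permeability = %.4g (%s)\n", x$p_est, x$p_units))
    }
  }
  invisible(x)
}

#' @export
coef.shrinkage_fit <- function(object, ...) {
  c(t0 = object$t0_est, slope = object$slope, i_00 = object$i_00,
    i_0fin = object$i_0fin, i_finfin = object$i_finfin,
    drop_stage1 = object$drop_stage1, rise_stage23 = object$rise_stage23,
    p_est = object$p_est)
}

#' @export
summary.shrinkage_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$stage2_window)) {
    cat(sprintf("  stage-II window: [%.4g, %.4g] s\n",
                object$stage2_window[1], object$stage2_window[2]))
  }
  if (isTRUE(object$plateau_warning)) {
    cat("  warning: final plateau still drifting (trace not equilibrated)\n")
  }
  invisible(object)
}

#' Fit the delay law t0 ~ 1/delta_pi
#'
#' Ordinary least squares of the deflection time on the reciprocal osmotic
#' pressure difference. A straight line through the origin in these
#' coordinates is the signature of the pore-opening delay law; `slope_k` is
#' the delay scale in mOsm s.
#'
#' @param delta_pi Osmotic pressure differences, mOsm (at least two distinct
#'   positive values); alternatively a data frame with columns `delta_pi` and
#'   `t0`.
#' @param t0 Deflection times, s.
#' @return Object of class `"delay_law_fit"` with `slope_k` (mOsm s),
#'   `intercept` (s), `r_squared` and `n_points`.
#' @examples
#' f <- fit_delay_law(c(15, 25, 50, 100, 150), 2 / c(15, 25, 50, 100, 150))
#' coef(f)  # slope_k = 2, intercept = 0
#' @export
fit_delay_law <- function(delta_pi, t0) {
  if (is.data.frame(delta_pi)) {
    t0 <- delta_pi$t0
    delta_pi <- delta_pi$delta_pi
  }
  ok <- is.finite(delta_pi) & is.finite(t0) & delta_pi > 0
  delta_pi <- delta_pi[ok]
  t0 <- t0[ok]
  if (length(unique(delta_pi)) < 2L) {
    stop_insufficient("need at least 2 distinct positive delta_pi values")
  }
  inv <- 1 / delta_pi
  fit <- lm(t0 ~ inv)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((t0 - mean(t0))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(
    list(slope_k = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = r2, n_points = length(t0), lm_fit = fit,
         delta_pi = delta_pi, t0 = t0),
    class = "delay_law_fit"
  )
}

#' @export
print.delay_law_fit <- function(x, ...) {
  cat("Pore-opening delay law fit: t0 = slope_k / delta_pi + intercept\n")
  cat(sprintf("  slope_k = %.4g mOsm s, intercept = %.4g s, R^2 = %.4f (n = %d)\n",
              x$slope_k, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' @export
coef.delay_law_fit <- function(object, ...) {
  c(slope_k = object$slope_k, intercept = object$intercept)
}

#' @export
predict.delay_law_fit <- function(object, delta_pi, ...) {
  object$intercept + object$slope_k / delta_pi
}

#' @export
plot.delay_law_fit <- function(x, ...) {
  inv <- 1 / x$delta_pi
  plot(inv, x$t0, xlab = "1 / delta_pi (1/mOsm)", ylab = "t0 (s)",
       main = "Pore-opening delay law", ...)
  abline(x$intercept, x$slope_k, lty = 2)
  invisible(x)
}

#' Correlate the pore-opening delay with membrane bending rigidity
#'
#' Pearson correlation and least-squares line of the deflection time `t0`
#' against the bending rigidity `kappa_b`, across membrane compositions at a
#' single osmotic pressure difference. A positive correlation supports the
#' continuum-elastic reading of pore opening: stiffer membranes take longer
#' to open a pore.
#'
#' @param kappa_b Bending rigidities, kT (at least 3 pairs); alternatively a
#'   data frame with columns `kappa_b` and `t0`.
#' @param t0 Deflection times, s.
#' @return Object of class `"rigidity_correlation"` with `pearson_r`, `slope`,
#'   `intercept`, `n_pairs`.
#' @export
correlate_delay_rigidity <- function(kappa_b, t0) {
  if (is.data.frame(kappa_b)) {
    t0 <- kappa_b$t0
    kappa_b <- kappa_b$kappa_b
  }
  ok <- is.finite(kappa_b) & is.finite(t0)
  kappa_b <- kappa_b[ok]
  t0 <- t0[ok]
  if (length(t0) < 3L) stop_insufficient("need at least 3 (kappa_b, t0) pairs")
  fit <- lm(t0 ~ kappa_b)
  structure(
    list(pearson_r = cor(kappa_b, t0), slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]), n_pairs = length(t0),
         kappa_b = kappa_b, t0 = t0),
    class = "rigidity_correlation"
  )
}

#' @export
print.rigidity_correlation <- function(x, ...) {
  cat("Delay-rigidity correlation (t0 vs kappa_b)\n")
  cat(sprintf("  Pearson r = %.3f over %d pairs; t0 = %.4g + %.4g * kappa_b\n",
              x$pearson_r, x$n_pairs, x$intercept, x$slope))
  invisible(x)
}

#' @export
plot.rigidity_correlation <- function(x, ...) {
  plot(x$kappa_b, x$t0, xlab = "kappa_b (kT)", ylab = "t0 (s)",
       main = "Pore-opening delay vs bending rigidity", ...)
  abline(x$intercept, x$slope, lty = 2)
  invisible(x)
}
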