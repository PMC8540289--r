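test_that("deflection detection recovers t0 and flags the degenerate cases", {
  # noiseless, t0 = 0.5 s on a 1 ms grid: within one grid step
  tr <- make_default_trace(50, t0 = 0.5, times = seq(0, 1.5, by = 1e-3))
  det <- detect_deflection(tr)
  expect_identical(det$status, "ok")
  expect_lt(abs(det$t0_est - 0.5), 1e-3)
  # sweep of delay times: always within one grid step, noiseless
  for (dpi in c(15, 25, 50, 100, 150)) {
    tr <- make_default_trace(dpi)
    det <- detect_deflection(tr)
    expect_lt(abs(det$t0_est - 2 / dpi), 1e-3)
  }
  # isosmotic control: flat trace, no deflection
  tr0 <- make_default_trace(0, t0 = 0.1)
  expect_identical(detect_deflection(tr0)$status, "no-deflection")
  tr0n <- make_default_trace(0, t0 = 0.1, noise_sd = 0.02, seed = 4)
  expect_identical(detect_deflection(tr0n)$status, "no-deflection")
  # delay below the dead time cannot be resolved
  tr_fast <- make_default_trace(400, t0 = 0.005)
  det_fast <- detect_deflection(tr_fast)
  expect_identical(det_fast$status, "unresolvable")
  expect_false(det_fast$resolvable)
})

test_that("deflection detection is invariant to intensity translation", {
  tr <- make_default_trace(50, noise_sd = 0.02, seed = 9)
  t0_a <- detect_deflection(tr)$t0_est
  tr$intensities <- tr$intensities + 123.4
  expect_equal(detect_deflection(tr)$t0_est, t0_a)
})

test_that("plateau extraction returns the generator's levels", {
  # dpi = 150: drop = 1, rise = gamma * dpi / k_mech = 1
  tr <- make_default_trace(150)
  det <- detect_deflection(tr)
  pl <- extract_plateaus(tr, det$t0_est, i_00_ref = 5)
  expect_equal(pl$drop_stage1, 1.0, tolerance = 0.02)
  expect_equal(pl$rise_stage23, 1.0, tolerance = 0.02)
  expect_false(pl$plateau_warning)
  # no osmotic drive: no stage-II/III rise
  tr0 <- make_default_trace(0, t0 = 0.1)
  pl0 <- extract_plateaus(tr0, 0.1)
  expect_equal(pl0$rise_stage23, 0, tolerance = 1e-3)
  # doubling gamma doubles the rise, leaves the stage-I drop unchanged
  tr_g <- make_default_trace(150, gamma = 20)
  pl_g <- extract_plateaus(tr_g, detect_deflection(tr_g)$t0_est, i_00_ref = 5)
  expect_equal(pl_g$rise_stage23 / pl$rise_stage23, 2, tolerance = 0.02)
  expect_equal(pl_g$drop_stage1, pl$drop_stage1, tolerance = 0.02)
  expect_error(extract_plateaus(tr, 99), class = "osmoflux_invalid_input")
})

test_that("stage-II slope scales with the osmotic drive", {
  slopes <- vapply(c(15, 25, 50, 100, 150), function(dpi) {
    tr <- make_default_trace(dpi)
    stage2_slope(tr, detect_deflection(tr)$t0_est)$slope
  }, numeric(1))
  expect_true(all(diff(slopes) > 0))
  # the OLS slope over the half-rise window is the initial slope
  # gamma*A0*Vw*P*dpi/V0 times the saturating-shape factor (~0.7)
  init_slope <- 10 * A0_55NM * 1.8e-5 * 2e-5 * 50 / V0_55NM
  tr <- make_default_trace(50)
  s <- stage2_slope(tr, detect_deflection(tr)$t0_est)
  expect_equal(s$slope / init_slope, osmoflux:::ols_shape_factor(50 / 1500),
               tolerance = 0.05)
  # flat trace: slope ~ 0
  tr0 <- make_default_trace(0, t0 = 0.1)
  expect_equal(stage2_slope(tr0, 0.1)$slope, 0, tolerance = 1e-6)
  short <- make_default_trace(50)
  expect_error(stage2_slope(short, max(short$times) - 0.002),
               class = "osmoflux_insufficient_data")
})

test_that("permeability inversion recovers the generator's P", {
  geom <- vesicle_state(radius = 55e-9)
  for (dpi in c(15, 50, 150)) {
    tr <- make_default_trace(dpi)
    fit <- fit_trace(tr, optics_gamma = 10)
    expect_equal(fit$p_est, 2e-5, tolerance = 0.05)
    expect_identical(fit$p_units, "m/s")
  }
  # halving delta_pi at fixed slope doubles P
  p1 <- permeability_from_slope(5, 10, geom, 100)$p_est
  p2 <- permeability_from_slope(5, 10, geom, 50)$p_est
  expect_equal(p2, 2 * p1)
  # unknown gamma: relative units, off by exactly the gamma factor
  pr <- permeability_from_slope(5, NULL, geom, 100)
  expect_identical(pr$units, "relative")
  expect_equal(pr$p_est, 10 * p1)
  expect_error(permeability_from_slope(5, 10, geom, 0),
               class = "osmoflux_invalid_input")
})

test_that("full pipeline recovers t0 and P under noise", {
  # noiseless: t0 within one grid step, P within 5% (checked above per-op);
  # at SNR 20 (noise sd = rise/20) the 50-seed recovery stays within 15%
  errs <- t(vapply(1:50, function(s) {
    dpi <- 50
    rise <- 10 * dpi / 1500
    tr <- make_default_trace(dpi, noise_sd = rise / 20, seed = s)
    fit <- fit_trace(tr, optics_gamma = 10)
    c(abs(fit$t0_est - 2 / dpi) / (2 / dpi), abs(fit$p_est - 2e-5) / 2e-5)
  }, numeric(2)))
  expect_lt(median(errs[, 1]), 0.15)
  expect_lt(median(errs[, 2]), 0.15)
  expect_lt(mean(errs[, 2]), 0.15)
})

test_that("delay-law regression recovers the generator scale", {
  dpis <- c(15, 25, 50, 100, 150)
  # exact synthetic law: slope_k = 2, zero intercept, R^2 = 1
  f <- fit_delay_law(dpis, 2 / dpis)
  expect_equal(f$slope_k, 2)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  expect_equal(predict(f, 40), 0.05)
  # constant t0: zero slope
  expect_equal(fit_delay_law(dpis, rep(0.1, 5))$slope_k, 0, tolerance = 1e-12)
  # 10% multiplicative noise on t0: R^2 stays above 0.9 (100 seeds)
  r2 <- vapply(1:100, function(s) {
    set.seed(s)
    fit_delay_law(dpis, (2 / dpis) * (1 + 0.1 * rnorm(5)))$r_squared
  }, numeric(1))
  expect_true(all(r2 >= 0.9))
  expect_error(fit_delay_law(c(50, 50), c(0.04, 0.04)),
               class = "osmoflux_insufficient_data")
})

test_that("fitted traces refit the delay law within 2% (noiseless sweep)", {
  dpis <- c(15, 25, 50, 100, 150)
  t0e <- vapply(dpis, function(dpi) {
    detect_deflection(make_default_trace(dpi))$t0_est
  }, numeric(1))
  f <- fit_delay_law(dpis, t0e)
  expect_equal(f$slope_k, 2, tolerance = 0.02)
  expect_gt(f$r_squared, 0.999)
})

test_that("delay-rigidity correlation behaves", {
  kb <- c(15, 25, 40, 50)
  expect_equal(correlate_delay_rigidity(kb, 0.01 + 0.002 * kb)$pearson_r, 1)
  expect_equal(correlate_delay_rigidity(kb, 0.5 - 0.002 * kb)$pearson_r, -1)
  expect_error(correlate_delay_rigidity(c(15, 25), c(0.1, 0.2)),
               class = "osmoflux_insufficient_data")
  # pairs from the default delay law at 20 mOsm with 5% noise: r >= 0.9
  cal <- delay_calibration()
  set.seed(21)
  pairs <- do.call(rbind, lapply(c(15, 25, 25, 50), function(k) {
    t0 <- pore_delay_time(osmotic_condition(20), membrane_mechanics(k), cal)$t0
    data.frame(kappa_b = k, t0 = t0 * (1 + 0.05 * rnorm(3)))
  }))
  rc <- correlate_delay_rigidity(pairs)
  expect_gte(rc$pearson_r, 0.9)
  expect_gt(rc$slope, 0)
})

test_that("fit_trace returns a classed object with methods", {
  tr <- make_default_trace(50)
  fit <- fit_trace(tr, optics_gamma = 10)
  expect_s3_class(fit, "shrinkage_fit")
  co <- coef(fit)
  expect_named(co, c("t0", "slope", "i_00", "i_0fin", "i_finfin",
                     "drop_stage1", "rise_stage23", "p_est"))
  expect_output(print(fit), "t0 = ")
  fit0 <- fit_trace(make_default_trace(0, t0 = 0.1))
  expect_identical(fit0$status, "no-deflection")
  expect_true(is.na(fit0$p_est))
})
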