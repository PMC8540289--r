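test_that("mode variance matches the hand-evaluated equipartition term", {
  m <- membrane_mechanics(25)
  # single-term sum at l_max = 2: (5/4pi)(1/24) * 3^2 / (25 * 1 * 4 * 6)
  b2 <- (5 / (4 * pi)) * (1 / 24) * 9 / (25 * 1 * 4 * 6)
  expect_equal(mode_variance(2, m, sigma_bar = 0, l_max = 2), b2)
  expect_equal(b2, 2.487e-4, tolerance = 1e-3)
  # stiffness kills the fluctuations
  expect_lt(mode_variance(2, membrane_mechanics(1e9), 0, 30), 1e-11)
  # spectrum decreases with mode order (exhaustive, both tensions)
  for (sig in c(0, 5)) {
    bn <- mode_variance(2:29, m, sig, l_max = 30)
    expect_true(all(diff(bn) < 0))
  }
  # dilation and translation modes are excluded
  expect_error(mode_variance(1, m, 0, 30), class = "osmoflux_invalid_input")
  expect_error(mode_variance(31, m, 0, 30), class = "osmoflux_invalid_input")
})

test_that("contour generator reproduces the model spectrum", {
  m <- membrane_mechanics(25)
  # near-rigid membrane: tiny excursions
  stiff <- generate_contours(10, membrane_mechanics(1e6), 0, n_frames = 100,
                             seed = 2)
  expect_lt(max(abs(stiff$radii / 10 - 1)), 1e-2)
  # seeded reproducibility, bit identical
  c1 <- generate_contours(10, m, 5, n_frames = 20, seed = 3)
  c2 <- generate_contours(10, m, 5, n_frames = 20, seed = 3)
  expect_identical(c1$radii, c2$radii)
  # sampled mean square amplitude at n = 2 within 5% of B_2 (7500 frames)
  big <- generate_contours(10, m, 5, n_frames = 7500, seed = 4)
  p <- osmoflux:::contour_mode_power(big, 2:5)
  b <- mode_variance(2:5, m, 5, 30)
  expect_equal(mean(p[, 1]), b[1], tolerance = 0.05)
  expect_error(generate_contours(10, m, 5, n_frames = 10, n_angles = 64),
               class = "osmoflux_invalid_input")
})

test_that("rendering and extraction are mutually consistent", {
  m <- membrane_mechanics(25)
  ctr <- generate_contours(5, m, 5, n_frames = 2, seed = 6)
  st <- render_frames(ctr, noise_model = NULL)
  e <- extract_contour(st$frames[[1]], st$center)
  expect_true(e$ok)
  err_px <- abs(e$radii_px - ctr$radii[1, ] / st$pixel_size)
  expect_lt(max(err_px), 0.1)
  # mean radius error well under 0.2 px
  expect_lt(abs(mean(e$radii_px) - mean(ctr$radii[1, ]) / st$pixel_size), 0.2)
  # injected pure n = 2 deformation of relative amplitude 0.02
  ang <- seq(0, 2 * pi, length.out = 129)[1:128]
  r2 <- matrix(5 * (1 + 0.02 * cos(2 * ang)), nrow = 1)
  ctr2 <- osmoflux:::new_contour_series(r2, ang, 5, 0.102)
  st2 <- render_frames(ctr2, noise_model = NULL)
  e2 <- extract_contour(st2$frames[[1]], st2$center)
  u <- e2$radii_px / mean(e2$radii_px) - 1
  expect_equal(2 * mean(u * cos(2 * ang)), 0.02, tolerance = 0.05)
  # blank frame is rejected, not an error
  blank <- extract_contour(matrix(0, st$size, st$size), st$center)
  expect_false(blank$ok)
  # zero peak intensity renders blank frames
  dark <- render_frames(ctr, peak_intensity = 0, noise_model = NULL)
  expect_equal(max(dark$frames[[1]]), 0)
  # seeded noise reproducibility
  s1 <- render_frames(ctr, seed = 11)
  s2 <- render_frames(ctr, seed = 11)
  expect_identical(s1$frames, s2$frames)
})

test_that("rigidity fit recovers the generator parameters", {
  m <- membrane_mechanics(25)
  big <- generate_contours(10, m, 5, n_frames = 7500, seed = 8)
  fit <- fit_bending_rigidity(big, n_boot = 0)
  expect_equal(fit$kappa_b, 25, tolerance = 0.10)
  expect_s3_class(fit, "rigidity_fit")
  # doubling the fluctuation variance halves the fitted rigidity
  half <- big
  half$radii <- big$mean_radius + sqrt(2) * (big$radii - big$mean_radius)
  fit_half <- fit_bending_rigidity(half, n_boot = 0)
  expect_equal(fit_half$kappa_b, fit$kappa_b / 2, tolerance = 1e-6)
  expect_equal(fit_half$sigma_bar, fit$sigma_bar, tolerance = 1e-3)
  # guard rails
  expect_error(fit_bending_rigidity(big, n_range = 1:20),
               class = "osmoflux_invalid_input")
  small <- generate_contours(10, m, 5, n_frames = 10, seed = 9)
  expect_error(fit_bending_rigidity(small),
               class = "osmoflux_insufficient_data")
})

test_that("stiff and soft membranes give separated confidence intervals", {
  soft <- generate_contours(10, membrane_mechanics(15), 5, n_frames = 7500,
                            seed = 12)
  stiff <- generate_contours(10, membrane_mechanics(50), 5, n_frames = 7500,
                             seed = 13)
  f_soft <- fit_bending_rigidity(soft, n_boot = 1000, seed = 1)
  f_stiff <- fit_bending_rigidity(stiff, n_boot = 1000, seed = 1)
  expect_lt(f_soft$ci["upper"], f_stiff$ci["lower"])
  # CI contains the point estimate and is seeded-reproducible
  expect_true(f_soft$ci["lower"] <= f_soft$kappa_b &&
                f_soft$kappa_b <= f_soft$ci["upper"])
  f_soft2 <- fit_bending_rigidity(soft, n_boot = 1000, seed = 1)
  expect_identical(f_soft$ci, f_soft2$ci)
})

test_that("rigidity error shrinks with the number of frames", {
  m <- membrane_mechanics(25)
  med_err <- vapply(c(500, 2000, 7500), function(nf) {
    errs <- vapply(1:20, function(s) {
      ctr <- generate_contours(10, m, 5, n_frames = nf, seed = 1000 + s)
      abs(fit_bending_rigidity(ctr, n_boot = 0)$kappa_b - 25) / 25
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
})

test_that("image pipeline end to end: render, extract, fit", {
  m <- membrane_mechanics(25)
  ctr <- generate_contours(10, m, 5, n_frames = 2000, seed = 15)
  st <- render_frames(ctr, seed = 16)
  ex <- extract_contours(st)
  # dropout artifact rejects about a quarter of the frames
  expect_gte(mean(ex$flags), 0.70)
  expect_lte(mean(ex$flags), 0.80)
  fit <- fit_bending_rigidity(ex, n_boot = 0)
  expect_equal(fit$kappa_b, 25, tolerance = 0.15)
})
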