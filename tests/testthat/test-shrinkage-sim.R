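test_that("sphere geometry is exact and self-consistent", {
  # 110 nm mean diameter vesicle: R = 55 nm, A = 3.8013e4 nm^2
  g <- sphere_geometry(6.9691e5)  # nm^3
  expect_equal(g$radius, 55.0, tolerance = 1e-4)
  expect_equal(g$area, 3.8013e4, tolerance = 1e-4)
  # similarity: 8x volume doubles the radius and quadruples the area
  g8 <- sphere_geometry(8 * 6.9691e5)
  expect_equal(g8$radius, 2 * g$radius)
  expect_equal(g8$area, 4 * g$area)
  # round trip volume -> (R, A) -> volume
  v <- 3.1e-22
  g2 <- sphere_geometry(v)
  expect_equal(4 / 3 * pi * g2$radius^3, v, tolerance = 1e-12)
  expect_equal(g2$area, (36 * pi)^(1 / 3) * v^(2 / 3), tolerance = 1e-12)
  expect_error(sphere_geometry(0), class = "osmoflux_invalid_input")
})

test_that("the molar volume of water is 0.018 L/mol", {
  expect_equal(signif(water_molar_volume("l_per_mol"), 2), 0.018)
  expect_identical(shrinkage_physics()$v_w, 1.8e-5)
})

test_that("no volume change before the pore opens or without osmotic drive", {
  vs <- vesicle_state(radius = 55e-9)
  phys <- shrinkage_physics(t0 = 0.5)
  tt <- seq(0, 0.4, by = 0.01)  # grid entirely before t0
  v <- simulate_volume(vs, phys, osmotic_condition(150), tt)
  expect_equal(as.numeric(v), rep(vs$volume, length(tt)))
  v0 <- simulate_volume(vs, shrinkage_physics(t0 = 0), osmotic_condition(0),
                        seq(0, 1, by = 0.01))
  expect_equal(as.numeric(v0), rep(vs$volume, 101))
})

test_that("volume trajectory matches the Euler oracle and the closed form", {
  vs <- vesicle_state(radius = 55e-9)
  tt <- seq(0, 1, by = 0.01)
  # adaptive solver vs fixed-step Euler (dt = 1e-5), sphere area update
  v <- simulate_volume(vs, shrinkage_physics(permeability = 2e-5, t0 = 0),
                       osmotic_condition(150), tt)
  v_or <- euler_volume(55e-9, 2e-5, 150, 1500, 0, tt)
  expect_lt(max(abs(v / v_or - 1)), 1e-3)
  # initial slope = -A0 * Vw * P * dpi = -2.053e-21 m^3/s
  tfine <- c(0, 1e-6)
  vf <- simulate_volume(vs, shrinkage_physics(permeability = 2e-5, t0 = 0),
                        osmotic_condition(150), tfine)
  expect_equal((vf[2] - vf[1]) / 1e-6, -2.053e-21, tolerance = 1e-3)
  # frozen-area variant equals the exponential closed form
  vfz <- simulate_volume(vs, shrinkage_physics(permeability = 2e-5, t0 = 0.1),
                         osmotic_condition(100), tt, area_mode = "frozen")
  expect_equal(as.numeric(vfz),
               frozen_area_volume(55e-9, 2e-5, 100, 1500, 0.1, tt),
               tolerance = 1e-6)
})

test_that("delayed trajectory is the time-translated zero-delay trajectory", {
  vs <- vesicle_state(radius = 55e-9)
  t0 <- 0.04
  tt <- seq(0, 0.5, by = 0.005)
  v_delay <- simulate_volume(vs, shrinkage_physics(t0 = t0),
                             osmotic_condition(50), tt)
  v_plain <- simulate_volume(vs, shrinkage_physics(t0 = 0),
                             osmotic_condition(50), tt - min(tt))
  after <- tt >= t0
  v_shifted <- simulate_volume(vs, shrinkage_physics(t0 = 0),
                               osmotic_condition(50), tt[after] - t0)
  expect_equal(as.numeric(v_delay[after]), as.numeric(v_shifted),
               tolerance = 1e-7)
  # with t0 = 0 the piecewise model is the plain flux law on the whole grid
  expect_equal(as.numeric(v_plain),
               euler_volume(55e-9, 2e-5, 50, 1500, 0, tt), tolerance = 1e-3)
})

test_that("trajectory is monotone and saturates at the elastic equilibrium", {
  vs <- vesicle_state(radius = 55e-9)
  tt <- seq(0, 2, by = 0.01)
  for (dpi in c(15, 50, 150)) {
    v <- simulate_volume(vs, shrinkage_physics(t0 = 0),
                         osmotic_condition(dpi), tt)
    expect_true(all(diff(v) <= 1e-30))
    expect_equal((vs$volume - v[length(v)]) / vs$volume, dpi / 1500,
                 tolerance = 1e-5)
    expect_false(attr(v, "full_collapse"))
  }
  v_fc <- simulate_volume(vs, shrinkage_physics(t0 = 0, k_mech = 100),
                          osmotic_condition(150), seq(0, 0.05, by = 0.01))
  expect_true(attr(v_fc, "full_collapse"))
})

test_that("a rigid vesicle reduces to the constant-drive linear flux law", {
  vs <- vesicle_state(radius = 55e-9)
  phys <- shrinkage_physics(permeability = 2e-5, t0 = 0, k_mech = 1e9)
  tt <- c(0, 1e-4, 2e-4)
  v <- simulate_volume(vs, phys, osmotic_condition(150), tt)
  slope <- (v[2] - v[1]) / 1e-4
  expect_equal(slope, -A0_55NM * 1.8e-5 * 2e-5 * 150, tolerance = 0.01)
})

test_that("intensity map builds the three-stage trace anatomy", {
  vs <- vesicle_state(radius = 55e-9)
  tt <- seq(0, 1, by = 1e-3)
  t0 <- 0.04
  v <- simulate_volume(vs, shrinkage_physics(t0 = t0), osmotic_condition(150),
                       tt)
  opt <- optics_map(5, 4, 10)
  tr <- intensity_from_volume(v, opt, t0, tt)
  i_t0 <- tr$intensities[which.min(abs(tt - t0))]
  expect_equal(i_t0, 4, tolerance = 1e-6)
  expect_equal(min(tr$intensities), 4, tolerance = 1e-6)
  expect_equal(tt[which.min(tr$intensities)], t0, tolerance = 1e-3)
  # final plateau: i_0fin + gamma * dpi / k_mech = 4 + 10 * 0.1 = 5
  expect_equal(tr$intensities[length(tt)], 4 + 10 * 150 / 1500,
               tolerance = 1e-3)
  expect_equal(tr$intensities[1], 5)  # pre-mix level
  # isosmotic control: flat line at i_0fin after stage I
  v_iso <- simulate_volume(vs, shrinkage_physics(t0 = t0),
                           osmotic_condition(0), tt)
  tr_iso <- intensity_from_volume(v_iso, opt, t0, tt)
  post <- tt >= t0
  expect_equal(as.numeric(tr_iso$intensities[post]), rep(4, sum(post)))
  expect_error(intensity_from_volume(v[-1], opt, t0, tt),
               class = "osmoflux_invalid_input")
})

test_that("instrument model removes the dead time and seeds its noise", {
  tr <- make_default_trace(50, dead_time = 0)
  # identity when nothing is applied
  tr_id <- apply_instrument(tr, dead_time = 0, noise_sd = 0)
  expect_equal(tr_id$intensities, tr$intensities)
  # a 10 ms dead time removes exactly 10 samples of a 1 ms grid starting at 0
  tr_dt <- apply_instrument(tr, dead_time = 0.01)
  expect_identical(length(tr$times) - length(tr_dt$times), 10L)
  expect_gte(min(tr_dt$times), 0.01)
  # seeded reproducibility; different seeds differ
  n1 <- apply_instrument(tr, noise_sd = 0.05, seed = 7)
  n2 <- apply_instrument(tr, noise_sd = 0.05, seed = 7)
  n3 <- apply_instrument(tr, noise_sd = 0.05, seed = 8)
  expect_identical(n1$intensities, n2$intensities)
  expect_gt(max(abs(n1$intensities - n3$intensities)), 1e-12)
  expect_error(apply_instrument(tr, dead_time = 10),
               class = "osmoflux_invalid_input")
})
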