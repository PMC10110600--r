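test_that("sphere magnification follows the multiple-reflection form", {
  cfg <- sphere_config(rho_S = 0.97)
  expect_equal(magnification(cfg, 550), 0.97 / 0.03, tolerance = 1e-10)
  expect_equal(round(magnification(cfg, 550), 2), 32.33)
  cfg0 <- sphere_config(rho_S = 0.97, rho_0 = 0)
  expect_equal(magnification(cfg0, 550), 0)
  cfg_port <- sphere_config(rho_S = 0.97,
                            ports = list(list(f = 0.05, rho = 0)))
  expect_equal(magnification(cfg_port, 550), 0.97 / (1 - 0.9215),
               tolerance = 1e-10)
  expect_equal(round(magnification(cfg_port, 550), 2), 12.36)
  expect_error(magnification(sphere_config(rho_S = 1.0), 550),
               "non-physical")
})

make_qy_scan <- function(em_level, abs_level, s_gain = 1,
                         gain = 1) {
  wl <- seq(400, 760, 1)
  # photon-flux-flat construction: I proportional to 1/lambda makes the
  # lambda-weighted integrals proportional to the window widths
  I_b <- gain * 1e5 / wl
  I_x <- I_b
  ex <- wl >= 490 & wl <= 510
  em <- wl >= 600 & wl <= 700
  I_x[ex] <- I_x[ex] * (1 - abs_level)
  I_x[em] <- I_x[em] + gain * em_level * 1e5 / wl[em]
  qy_scan(spectrum(wl, I_x), spectrum(wl, I_b),
          spectrum(wl, rep(s_gain, length(wl))),
          lambda_ex = 500, delta_lambda = 10,
          emission_window = c(600, 700))
}

test_that("quantum yield reduces to the photon-flux ratio", {
  # absorbed flux: 0.6 over 20 nm; emitted: 0.06 over 100 nm -> 0.5
  out <- quantum_yield(make_qy_scan(em_level = 0.06, abs_level = 0.6))
  expect_equal(out$phi_pl, 0.5, tolerance = 1e-9)
  expect_length(out$flags, 0)
})

test_that("quantum yield is invariant under responsivity and gain scaling", {
  base <- quantum_yield(make_qy_scan(0.06, 0.6))$phi_pl
  expect_equal(quantum_yield(make_qy_scan(0.06, 0.6, s_gain = 7))$phi_pl,
               base, tolerance = 1e-12)
  expect_equal(quantum_yield(make_qy_scan(0.06, 0.6, gain = 3.7))$phi_pl,
               base, tolerance = 1e-12)
})

test_that("no absorption raises an error", {
  expect_error(quantum_yield(make_qy_scan(0.01, 0)), "no absorption")
})

test_that("quantum yields above one are flagged, not errored", {
  out <- quantum_yield(make_qy_scan(em_level = 0.30, abs_level = 0.6))
  expect_gt(out$phi_pl, 1)
  expect_true("phi_above_one" %in% out$flags)
})

test_that("overlapping excitation and emission windows are rejected", {
  wl <- seq(400, 760, 1)
  s <- spectrum(wl, rep(1, length(wl)))
  expect_error(
    qy_scan(s, s, s, lambda_ex = 590, delta_lambda = 20,
            emission_window = c(600, 700)),
    "overlap")
})

test_that("diffuse reflectance reduces certified-standard ratios", {
  std <- list(E_e = 1050, E_Ref = 550, E_D = 50)
  expect_equal(diffuse_reflectance(std, std, 0.99), 0.99)
  black <- list(E_e = 50, E_Ref = 550, E_D = 50)
  expect_equal(diffuse_reflectance(black, std, 0.99), 0)
  half <- list(E_e = 550, E_Ref = 550, E_D = 50)   # direct ratio halved
  expect_equal(diffuse_reflectance(half, std, 0.98), 0.49)
  bad <- list(E_e = 100, E_Ref = 40, E_D = 50)
  expect_error(diffuse_reflectance(bad, std, 0.99), "reference")
})

test_that("transmittance reduces empty-sphere ratios", {
  empty <- list(E_e = 2050, E_Ref = 1050, E_D = 50)
  expect_equal(transmittance(empty, empty), 1)
  opaque <- list(E_e = 50, E_Ref = 1050, E_D = 50)
  expect_equal(transmittance(opaque, empty), 0)
  quarter <- list(E_e = 550, E_Ref = 1050, E_D = 50)
  expect_equal(transmittance(quarter, empty), 0.25)
})

test_that("trap-detector collimated transmittance is a dark-corrected ratio", {
  expect_equal(collimated_transmittance(1050, 1050, 50), 1)
  expect_equal(collimated_transmittance(50, 1050, 50), 0)
  expect_equal(collimated_transmittance(550, 1050, 50), 0.5)
  expect_error(collimated_transmittance(100, 40, 50), "above dark")
})

test_that("all reductions are gain invariant", {
  k <- 13.7
  std <- list(E_e = 900, E_Ref = 500, E_D = 50)
  smp <- list(E_e = 420, E_Ref = 480, E_D = 50)
  scale <- function(l) lapply(l, `*`, k)
  expect_equal(diffuse_reflectance(scale(smp), scale(std), 0.98),
               diffuse_reflectance(smp, std, 0.98), tolerance = 1e-12)
  expect_equal(transmittance(scale(smp), scale(std)),
               transmittance(smp, std), tolerance = 1e-12)
  expect_equal(collimated_transmittance(k * 550, k * 1050, k * 50),
               collimated_transmittance(550, 1050, 50),
               tolerance = 1e-12)
})

test_that("T_t - T_d equals T_c when reduced from one synthetic scene", {
  sc <- synthetic_scene(wavelength_nm = seq(500, 600, 20))
  b <- synthesize_measurements(sc, seed = 3)
  red <- reduce_bundle(b)
  m <- red$measurement
  expect_true(all(abs(m$T_t$value - m$T_d$value - m$T_c$value) < 1e-6))
})
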