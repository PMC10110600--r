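test_that("cross sections from bulk coefficients are unit consistent", {
  expect_equal(sigma_from_mu(0, 1e10), 0)
  expect_equal(sigma_from_mu(0.1, 1e10), 1e-10)   # 1/cm over 1/cm^3
  expect_equal(sigma_from_mu(1, 2e10), sigma_from_mu(1, 1e10) / 2)
  expect_error(sigma_from_mu(1, 0), "> 0")
})

test_that("efficiency is the cross section over the geometric one", {
  expect_equal(absorption_efficiency(0, 500), 0)
  geo <- pi * (500 * 1e-7)^2
  expect_equal(absorption_efficiency(geo, 500), 1)
  expect_equal(absorption_efficiency(7.854e-9, 500), 1, tolerance = 1e-4)
  expect_error(absorption_efficiency(1e-10, -1), "> 0")
})

test_that("brightness and luminescence efficiency are exact products", {
  expect_equal(brightness(1e-10, 0.5), 5e-11)
  expect_equal(brightness(1e-10, 0), 0)
  expect_lte(brightness(1e-10, 0.99), 1e-10)
  expect_equal(luminescence_efficiency(0.02, 0.76), 0.0152)
  expect_equal(luminescence_efficiency(0.02, 0), 0)
  expect_lte(luminescence_efficiency(0.3, 0.9), 0.3)
  expect_warning(luminescence_efficiency(1.6, 0.9), "LE > 1")
  expect_error(luminescence_efficiency(-0.1, 0.5), ">= 0")
  expect_error(brightness(1e-10, 1.2), "\\[0, 1\\]")
})

test_that("molecular brightness is linear in each factor", {
  expect_equal(molecular_brightness(0, 1e5, 0.5), 0)
  expect_equal(molecular_brightness(1e3, 1e5, 0.5), 5e7)
  expect_equal(molecular_brightness(2e3, 1e5, 0.5),
               2 * molecular_brightness(1e3, 1e5, 0.5))
})

test_that("dye loading follows Beer-Lambert and the particle mass", {
  z <- dye_loading(0, 1e5, 1e-3, 3, 50)
  expect_equal(z$N_dye, 0)
  dl <- dye_loading(0.5, 1e5, 1e-3, 1, 50)
  expect_equal(dl$moles_dye, 5e-6 * 1e-3, tolerance = 1e-12)
  # 50 nm radius, 1050 kg/m^3: 1.82e12 particles per mg
  expect_equal(dl$n_particles, 1.82e12, tolerance = 0.005)
  expect_error(dye_loading(-0.1, 1e5, 1e-3, 1, 50), ">= 0")
})

test_that("the Mie fit recovers a monodisperse dispersion", {
  wl <- seq(420, 780, 10)
  truth <- particle_model(625, 1.5e9, width = 0)
  bo <- bulk_optics_from_particles(truth, wl)
  fit <- fit_particles(bo, n_nodes = 32L, max_rounds = 1L)
  expect_lt(abs(fit$particle$r_p_nm / 625 - 1), 0.01)
  expect_lt(abs(fit$particle$N_p_per_ml / 1.5e9 - 1), 0.03)
  expect_true(fit$diagnostics$resonances_detectable)
})

test_that("absorption-free truth yields negligible fitted n2", {
  wl <- seq(450, 750, 15)
  truth <- particle_model(600, 2e9, width = 0.02)
  bo <- bulk_optics_from_particles(truth, wl)
  fit <- fit_particles(bo, n_nodes = 32L, max_rounds = 1L)
  expect_lte(max(fit$n2$n2), 1e-5)
})

test_that("featureless scattering without a radius seed is rejected", {
  wl <- seq(450, 750, 15)
  truth <- particle_model(50, 5e11, width = 0.02)   # Rayleigh-smooth
  bo <- bulk_optics_from_particles(truth, wl)
  expect_error(fit_particles(bo), "underdetermined")
})

test_that("radiation-transport and Mie cross-section paths agree", {
  wl <- seq(450, 750, 15)
  lamg <- seq(350, 800, 1)
  hw <- 30
  eps <- spectrum(lamg, 5e4 * hw^2 / ((lamg - 530)^2 + hw^2))
  gam <- gamma_increment(eps)
  c_dye <- 0.02
  truth <- particle_model(500, 2.5e9, width = 0.02,
                          n2 = spectrum(gam$wavelength_nm,
                                        c_dye * gam$value))
  bo <- bulk_optics_from_particles(truth, wl)
  fit <- fit_particles(bo, dye_gamma = gam, n_nodes = 32L,
                       max_rounds = 1L)
  # Mie path at the band center
  cs <- spectral_cross_sections(fit$particle, c(529, 531))
  sigma_mie <- cs$sigma_a_nm2[1] * 1e-14
  # radiation-transport path: mu_a / N_p
  i0 <- which.min(abs(wl - 530))
  sigma_rt <- sigma_from_mu(bo$mu_a_per_mm[i0], fit$particle$N_p_per_ml)
  expect_lt(abs(sigma_mie / sigma_rt - 1), 0.05)
})

test_that("brightness report keeps the defining identities exact", {
  p <- particle_model(500, 2.5e9, n2 = 1e-3)
  rep1 <- brightness_report(p, phi_pl = 0.76, lambda_ex = 530)
  expect_identical(rep1$B_cm2, rep1$sigma_a_cm2 * rep1$phi_pl)
  expect_identical(rep1$LE, rep1$Q_abs * rep1$phi_pl)
  expect_true(rep1$LE >= 0)
  # the mu_a / N_p route must agree with the direct Mie route
  cs <- spectral_cross_sections(p, c(529.5, 530.5))
  mu_a <- p$N_p_per_ml * cs$sigma_a_nm2[1] * 1e-15
  rep2 <- brightness_report(p, 0.76, 530, mu_a_ex = mu_a)
  expect_equal(rep2$sigma_a_cm2, rep1$sigma_a_cm2, tolerance = 1e-3)
})
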