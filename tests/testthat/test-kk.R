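test_that("gamma increment follows the extinction spectrum", {
  wl <- c(500, 550, 600)
  expect_equal(gamma_increment(spectrum(wl, c(0, 0, 0)))$value,
               rep(0, 3))
  g <- gamma_increment(spectrum(wl, rep(1e5, 3)))
  expect_equal(g$value[2], log(10) / (4 * pi) * 1e5 * 550e-7,
               tolerance = 1e-12)
  expect_equal(round(g$value[2], 3), 1.008)
  g3 <- gamma_increment(spectrum(wl, rep(3e5, 3)))
  expect_equal(g3$value, 3 * g$value, tolerance = 1e-12)
  expect_error(gamma_increment(spectrum(wl, c(-1, 0, 0))), "negative")
})

test_that("zero imaginary increment transforms to zero real increment", {
  g <- spectrum(seq(300, 700, 0.5), rep(0, 801))
  a <- alpha_increment(g, c(300, 700))
  expect_true(all(a$value == 0))
})

test_that("the transform reproduces Lorentz-oscillator dispersion", {
  osc <- lorentz_pair(530, 0.08)
  lam <- seq(300, 700, 0.5)
  g <- spectrum(lam, osc$gamma(lam))
  a <- alpha_increment(g, c(300, 700), step_out = 5)
  truth <- osc$alpha(a$wavelength_nm)
  peak <- max(abs(truth))
  inner <- a$wavelength_nm >= 380 & a$wavelength_nm <= 660
  expect_lt(max(abs(a$value - truth)[inner]) / peak, 0.01)
})

test_that("anomalous dispersion changes sign across the band maximum", {
  osc <- lorentz_pair(530, 0.08)
  lam <- seq(300, 700, 0.5)
  a <- alpha_increment(spectrum(lam, osc$gamma(lam)), c(300, 700),
                       step_out = 1)
  below <- a$value[a$wavelength_nm == 515]
  above <- a$value[a$wavelength_nm == 545]
  expect_lt(below, 0)
  expect_gt(above, 0)
  # cross-check the sign structure against the brute-force PV reference
  expect_equal(sign(below),
               sign(pv_alpha_reference(515, osc$gamma, 300, 700)))
})

test_that("grid halving changes the interior transform by < 0.2% of peak", {
  osc <- lorentz_pair(530, 0.2)       # ~60 nm FWHM band
  lam <- seq(300, 700, 0.5)
  g <- spectrum(lam, osc$gamma(lam))
  a1 <- alpha_increment(g, c(300, 700), step_out = 5)
  a2 <- alpha_increment(g, c(300, 700), step_out = 5, step_work = 0.25)
  peak <- max(abs(a1$value))
  inner <- a1$wavelength_nm >= 320 & a1$wavelength_nm <= 680
  expect_lt(max(abs(a2$value - a1$value)[inner]) / peak, 0.002)
})

test_that("the numeric transform matches the brute-force PV reference", {
  osc <- lorentz_pair(530, 0.2)
  lam <- seq(300, 700, 0.5)
  a <- alpha_increment(spectrum(lam, osc$gamma(lam)), c(300, 700),
                       step_out = 5)
  peak <- max(abs(a$value))
  for (l in c(420, 530, 610)) {
    ref <- pv_alpha_reference(l, osc$gamma, 300, 700)
    expect_lt(abs(a$value[a$wavelength_nm == l] - ref) / peak, 1e-4)
  }
})

test_that("inverse transform recovers the imaginary increment", {
  # isolated narrow band tabulated over a wide range; the additive
  # far-wing baseline of alpha carries no band absorption and is
  # removed before inversion (subtractive Kramers-Kronig analysis)
  osc <- lorentz_pair(530, 0.08)
  lam <- seq(250, 950, 0.5)
  a <- alpha_increment(spectrum(lam, osc$gamma(lam)), c(250, 950),
                       step_out = 1)
  base <- (a$value[1] + a$value[length(a$value)]) / 2
  peak <- max(abs(osc$gamma(lam)))
  for (l in c(450, 500, 530, 570, 650)) {
    rec <- pv_gamma_reference(l, a$wavelength_nm, a$value - base)
    expect_lt(abs(rec - osc$gamma(l)) / peak, 0.02)
  }
})

test_that("out-of-band evaluation requires the extrapolation flag", {
  g <- spectrum(seq(400, 600, 0.5), rep(1, 401))
  expect_error(alpha_increment(g, c(400, 600), lambda_out = c(350, 500)),
               "outside the band")
  a <- alpha_increment(g, c(400, 600), lambda_out = c(350, 700),
                       extrapolate = TRUE)
  expect_true(all(is.finite(a$value)))
})

test_that("index assembly is linear in the dye concentration", {
  lam <- seq(300, 700, 0.5)
  hw <- 30
  eps <- spectrum(lam, 5e4 * hw^2 / ((lam - 530)^2 + hw^2))
  gam <- gamma_increment(eps)
  alp <- alpha_increment(gam, c(300, 700), step_out = 5)
  inc <- list(gamma = gam, alpha = alp)
  n0 <- assemble_index(n_polystyrene, 0, inc,
                       wavelength_nm = alp$wavelength_nm)
  expect_equal(n0$n1, n_polystyrene(alp$wavelength_nm))
  expect_true(all(n0$n2 == 0))
  n1x <- assemble_index(n_polystyrene, 0.01, inc,
                        wavelength_nm = alp$wavelength_nm)
  n2x <- assemble_index(n_polystyrene, 0.02, inc,
                        wavelength_nm = alp$wavelength_nm)
  expect_equal(n2x$n2, 2 * n1x$n2, tolerance = 1e-12)
  expect_equal(n2x$n1 - n0$n1, 2 * (n1x$n1 - n0$n1), tolerance = 1e-12)
  # n2 peak equals c_dye * gamma peak on the gamma grid
  nfull <- assemble_index(n_polystyrene, 0.02, inc)
  expect_equal(max(nfull$n2), 0.02 * max(gam$value), tolerance = 1e-12)
  # omitting the real part reproduces the unstained real index
  nom <- assemble_index(n_polystyrene, 0.02, inc,
                        wavelength_nm = alp$wavelength_nm,
                        include_real = FALSE)
  expect_equal(nom$n1, n_polystyrene(alp$wavelength_nm))
})
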