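geom_glass <- slab_geometry(1, n_slab = 1.33, n_wall = 1.52,
                            n_outside = 1)
geom_matched <- slab_geometry(1, n_slab = 1, n_wall = 1, n_outside = 1)

test_that("Henyey-Greenstein is isotropic at g = 0 and normalized", {
  expect_equal(hg_phase(0, c(-1, 0, 1)), rep(1 / (4 * pi), 3))
  for (g in c(-0.5, 0, 0.5, 0.99)) {
    nrm <- 2 * pi * stats::integrate(function(u) hg_phase(g, u), -1, 1,
                                     rel.tol = 1e-12)$value
    expect_lt(abs(nrm - 1), 1e-8)
  }
  expect_error(hg_phase(1, 0), "\\|g\\| < 1")
})

test_that("Henyey-Greenstein mean cosine equals g", {
  # composite Simpson over 1e4 intervals as the quadrature oracle
  u <- seq(-1, 1, length.out = 10001)
  h <- u[2] - u[1]
  w <- rep(c(2, 4), length.out = length(u))
  w[c(1, length(u))] <- 1
  mean_cos <- 2 * pi * h / 3 * sum(w * u * hg_phase(0.9, u))
  expect_lt(abs(mean_cos - 0.9), 1e-6)
})

test_that("lossless slabs conserve energy", {
  r <- forward_slab(0, 5, 0.9, geom_matched)
  expect_lt(abs(r$R_d + r$T_t - 1), 1e-4)
  r2 <- forward_slab(0, 10, 0, geom_glass)
  expect_lt(abs(r2$A), 1e-4)
})

test_that("scattering-free slabs follow Beer-Lambert", {
  r <- forward_slab(1, 0, 0, geom_matched)
  expect_equal(r$T_t, exp(-1), tolerance = 1e-6)
  expect_equal(r$T_c, exp(-1), tolerance = 1e-10)
})

test_that("excessive optical thickness raises the solver guard", {
  expect_error(forward_slab(2000, 0, 0, geom_matched), "infeasible")
})

test_that("adding-doubling matches Monte Carlo on mixed cases", {
  set.seed(7)
  cases <- data.frame(mu_a = c(0, 0.1, 1, 0.1),
                      mu_s = c(10, 5, 1, 0.5),
                      g = c(0.95, 0.9, 0, 0.7))
  for (i in seq_len(nrow(cases))) {
    ad <- forward_slab(cases$mu_a[i], cases$mu_s[i], cases$g[i],
                       geom_glass)
    mc <- mc_slab(cases$mu_a[i], cases$mu_s[i], cases$g[i], geom_glass,
                  n_photons = 2e5)
    expect_lt(abs(ad$R_d - mc$R_d), 0.005)
    expect_lt(abs(ad$T_t - mc$T_t), 0.005)
  }
})

test_that("transmission and reflection decrease with absorption", {
  mu_as <- c(0.05, 0.2, 0.8)
  out <- vapply(mu_as, function(mu_a) {
    r <- forward_slab(mu_a, 5, 0.8, geom_glass)
    c(r$R_d, r$T_t)
  }, numeric(2))
  expect_true(all(diff(out[1, ]) < 0))
  expect_true(all(diff(out[2, ]) < 0))
})

test_that("forward-invert round trip recovers the coefficients", {
  for (case in list(c(0.1, 5, 0.9), c(0.5, 2, 0.5), c(0.02, 8, 0.95))) {
    f <- forward_slab(case[1], case[2], case[3], geom_glass)
    inv <- invert_slab(f$R_d, f$T_t, f$T_c, geom_glass)
    expect_lt(abs(inv$mu_a_per_mm / case[1] - 1), 0.01)
    expect_lt(abs(inv$mu_s_per_mm / case[2] - 1), 0.01)
    expect_lt(abs(inv$g / case[3] - 1), 0.01)
  }
})

test_that("a scattering-free measurement recovers mu_s = 0", {
  f <- forward_slab(0.8, 0, 0, geom_glass)
  inv <- invert_slab(f$R_d, f$T_t, f$T_c, geom_glass)
  expect_lt(abs(inv$mu_s_per_mm), 1e-3)
  expect_lt(abs(inv$mu_a_per_mm - 0.8), 1e-3)
})

test_that("energy-violating measurements are rejected", {
  expect_error(invert_slab(0.6, 0.6, 0.01, geom_glass), "inconsistent")
})

test_that("spectrum inversion reproduces Mie-generated truth", {
  wl <- seq(500, 640, 20)
  truth <- particle_model(625, 1.5e9, width = 0.02)
  bo <- bulk_optics_from_particles(truth, wl)
  slab <- vapply(seq_along(wl), function(i) {
    r <- forward_slab(bo$mu_a_per_mm[i], bo$mu_s_per_mm[i], bo$g[i],
                      geom_glass)
    c(r$R_d, r$T_t, r$T_c)
  }, numeric(3))
  meas <- slab_measurement(spectrum(wl, slab[1, ]),
                           spectrum(wl, slab[2, ]),
                           spectrum(wl, slab[3, ]), geom_glass)
  out <- invert_spectrum(meas)
  expect_true(all(abs(out$mu_s_per_mm / bo$mu_s_per_mm - 1) < 0.02))
  expect_true(all(out$mu_a_per_mm <= 1e-3))   # absorption-free truth
  expect_true(all(abs(out$g - bo$g) < 0.01))
})

test_that("mismatched measurement grids are rejected", {
  wl <- seq(500, 600, 20)
  s1 <- spectrum(wl, rep(0.3, length(wl)))
  s2 <- spectrum(wl + 5, rep(0.5, length(wl)))
  expect_error(slab_measurement(s1, s2, s1, geom_glass), "common")
})

test_that("the lost-fraction option rescales before inversion", {
  f <- forward_slab(0.1, 5, 0.9, geom_glass)
  lost <- 0.05
  inv <- invert_slab(f$R_d * (1 - lost), f$T_t * (1 - lost), f$T_c,
                     geom_glass, lost_fraction = lost)
  expect_lt(abs(inv$mu_a_per_mm / 0.1 - 1), 0.01)
  expect_lt(abs(inv$mu_s_per_mm / 5 - 1), 0.01)
})
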