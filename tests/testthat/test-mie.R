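test_that("an optically matched sphere scatters nothing", {
  ab <- mie_coefficients(1 + 0i, 5)
  expect_true(all(Mod(ab$a) == 0))
  expect_true(all(Mod(ab$b) == 0))
  e <- mie_efficiencies(1 + 0i, 5)
  expect_equal(e$Q_ext, 0)
})

test_that("invalid m or x is rejected", {
  expect_error(mie_coefficients(NaN + 0i, 1), "finite")
  expect_error(mie_coefficients(1.5 + 0i, -1), "> 0")
  expect_error(mie_efficiencies(1.5 - 0.1i, 1), ">= 0")
})

test_that("Rayleigh-limit closed forms hold below x = 0.03", {
  m <- 1.59 / 1.33 + 0i
  for (x in c(0.005, 0.01, 0.03)) {
    e <- mie_efficiencies(m, x)
    ray <- 8 / 3 * x^4 * Mod((m^2 - 1) / (m^2 + 2))^2
    expect_lt(abs(e$Q_sca / ray - 1), 0.005)
  }
  ma <- complex(real = 1.1955, imaginary = 0.001 / 1.33)
  for (x in c(0.005, 0.01, 0.03)) {
    e <- mie_efficiencies(ma, x)
    ray_abs <- 4 * x * Im((ma^2 - 1) / (ma^2 + 2))
    expect_lt(abs(e$Q_abs / ray_abs - 1), 0.005)
  }
})

test_that("extinction approaches the large-sphere limit of 2", {
  e <- mie_efficiencies(1.59 / 1.33 + 0i, 1000)
  expect_lt(abs(e$Q_ext - 2), 0.1)
})

test_that("efficiencies agree with an independently coded series", {
  grid <- expand.grid(
    n1 = c(1.05, 1.2, 1.4, 1.59),
    n2 = c(0, 0.01, 0.1),
    x = c(0.5, 2, 7)
  )
  grid <- grid[seq_len(nrow(grid)) %% 2 == 1 | grid$x < 5, ][1:20, ]
  for (i in seq_len(nrow(grid))) {
    m <- complex(real = grid$n1[i], imaginary = grid$n2[i])
    mine <- mie_efficiencies(m, grid$x[i])
    ref <- mie_reference(m, grid$x[i])
    expect_lt(abs(mine$Q_ext / ref$Q_ext - 1), 1e-6)
    expect_lt(abs(mine$Q_sca / ref$Q_sca - 1), 1e-6)
  }
})

test_that("energy conservation holds over random draws", {
  set.seed(42)
  for (i in 1:1000) {
    m <- complex(real = runif(1, 1.01, 2), imaginary = runif(1, 0, 0.5))
    x <- 10^runif(1, -2, 2)
    e <- mie_efficiencies(m, x)
    expect_lt(abs(e$Q_ext - e$Q_sca - e$Q_abs) / max(e$Q_ext, 1e-12),
              1e-8)
    expect_true(e$Q_ext >= 0 && e$Q_sca >= 0 && e$Q_abs >= -1e-15)
    expect_true(abs(e$g) <= 1)
  }
})

test_that("a non-absorbing sphere has exactly zero absorption", {
  e <- mie_efficiencies(1.2 + 0i, 3)
  expect_identical(e$Q_abs, 0)
})

test_that("asymmetry factor vanishes at small x and grows toward 1", {
  m <- 1.2 + 0.001i
  xs <- c(0.05, 0.5, 2, 10)
  gs <- mie_efficiencies(m, xs)$g
  expect_lt(abs(gs[1]), 0.01)
  expect_true(all(diff(gs) > 0))
  expect_gt(gs[length(gs)], 0.8)
})

test_that("degenerate size distribution equals the single sphere", {
  dist <- size_distribution("monodisperse", 500)
  m <- 1.59 / 1.33 + 0.001i
  pd <- polydisperse_average(dist, m, 550, 1.33)
  e <- mie_efficiencies(m, 2 * pi * 500 * 1.33 / 550)
  expect_equal(pd$Q_ext, e$Q_ext, tolerance = 1e-12)
  expect_equal(pd$g, e$g, tolerance = 1e-12)
})

test_that("polydisperse averaging smooths Mie resonances", {
  # find a resonant radius: local max of Q_sca vs r near 600 nm
  m <- 1.59 / 1.33 + 0i
  rr <- seq(550, 700, 2)
  q <- vapply(rr, function(r) {
    mie_efficiencies(m, 2 * pi * r * 1.33 / 550)$Q_sca
  }, numeric(1))
  r_res <- rr[which.max(q)]
  mono <- polydisperse_average(size_distribution("monodisperse", r_res),
                               m, 550, 1.33)
  poly <- polydisperse_average(size_distribution("lognormal", r_res,
                                                 0.05), m, 550, 1.33)
  expect_lt(poly$Q_sca, mono$Q_sca)
})

test_that("64-node quadrature matches a 1e4-point brute-force average", {
  dist <- size_distribution("lognormal", 600, 0.08)
  m <- 1.59 / 1.33 + 0.002i
  pd <- polydisperse_average(dist, m, 550, 1.33)
  # brute force: trapezoid over the same +/- 4 width support
  s2 <- log(1 + dist$width^2)
  mu <- log(dist$mean_radius) - s2 / 2
  r <- seq(exp(mu - 4 * sqrt(s2)), exp(mu + 4 * sqrt(s2)),
           length.out = 1e4)
  dens <- stats::dlnorm(r, mu, sqrt(s2))
  w <- dens / sum(dens)
  eff <- mie_efficiencies(m, 2 * pi * r * 1.33 / 550)
  sig_ext <- sum(w * eff$Q_ext * pi * r^2)
  expect_lt(abs(pd$sigma_ext / sig_ext - 1), 1e-3)
})

test_that("normal-shape distributions reaching r <= 0 are rejected", {
  expect_error(
    polydisperse_average(size_distribution("normal", 100, 0.3),
                         1.2 + 0i, 550, 1.33),
    "r <= 0")
})

test_that("spectral cross sections: flat n2 = 0 gives zero absorption", {
  p <- particle_model(500, 1e9)
  cs <- spectral_cross_sections(p, seq(450, 650, 50))
  expect_true(all(cs$sigma_a_nm2 == 0))
  expect_true(all(cs$sigma_s_nm2 > 0))
})

test_that("weak absorption scales linearly with n2", {
  p1 <- particle_model(500, 1e9, n2 = 1e-5)
  p2 <- particle_model(500, 1e9, n2 = 2e-5)
  wl <- seq(450, 650, 50)
  s1 <- spectral_cross_sections(p1, wl)$sigma_a_nm2
  s2 <- spectral_cross_sections(p2, wl)$sigma_a_nm2
  expect_true(all(abs(s2 / s1 - 2) < 0.02))
})

test_that("non-ascending wavelength grids are rejected", {
  p <- particle_model(500, 1e9)
  expect_error(spectral_cross_sections(p, c(500, 450, 550)), "ascending")
})

test_that("micron beads absorb orders of magnitude more than 100 nm", {
  n2 <- 1e-3
  sig <- function(d) {
    m <- complex(real = 1.59, imaginary = n2) / 1.33
    x <- pi * d * 1.33 / 550
    mie_efficiencies(m, x)$Q_abs * pi * (d / 2)^2
  }
  expect_gte(sig(1000) / sig(100), 100)
})
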