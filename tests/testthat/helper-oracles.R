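# Independent oracles used across the test suite. These deliberately do
# not share algorithms with the package: the Mie reference evaluates the
# Bohren-Huffman coefficient formulas directly from power-series
# Riccati-Bessel functions (complex argument) and base-R half-integer
# Bessel functions (real argument) instead of the package's
# logarithmic-derivative recurrences; the principal-value reference uses
# adaptive quadrature with analytic singularity subtraction.

# Riccati-Bessel psi_n(z) = z j_n(z) by power series (complex z,
# moderate |z|; accuracy degrades ~e^|z| from cancellation)
psi_series <- function(n, z) {
  term <- z^(n + 1) / prod(seq(1, 2 * n + 1, by = 2))
  total <- term
  k <- 1
  repeat {
    term <- term * (-z^2 / 2) / (k * (2 * n + 2 * k + 1))
    total <- total + term
    if (Mod(term) < 1e-18 * Mod(total) || k > 300) break
    k <- k + 1
  }
  total
}

# reference Mie efficiencies via direct Bohren-Huffman formulas
mie_reference <- function(m, x) {
  N <- ceiling(x + 4.05 * x^(1 / 3) + 2)
  y <- m * x
  psi_x <- vapply(0:N, function(n) {
    sqrt(pi * x / 2) * besselJ(x, n + 0.5)
  }, numeric(1))
  chi_x <- vapply(0:N, function(n) {
    -sqrt(pi * x / 2) * besselY(x, n + 0.5)
  }, numeric(1))
  zeta_x <- complex(real = psi_x, imaginary = -chi_x)
  psi_y <- vapply(0:N, function(n) psi_series(n, y), complex(1))
  a <- b <- complex(N)
  Qe <- Qs <- 0
  for (n in 1:N) {
    dpsi_x <- psi_x[n] - n / x * psi_x[n + 1]
    dzeta_x <- zeta_x[n] - n / x * zeta_x[n + 1]
    dpsi_y <- psi_y[n] - n / y * psi_y[n + 1]
    a[n] <- (m * psi_y[n + 1] * dpsi_x - psi_x[n + 1] * dpsi_y) /
      (m * psi_y[n + 1] * dzeta_x - zeta_x[n + 1] * dpsi_y)
    b[n] <- (psi_y[n + 1] * dpsi_x - m * psi_x[n + 1] * dpsi_y) /
      (psi_y[n + 1] * dzeta_x - m * zeta_x[n + 1] * dpsi_y)
    Qe <- Qe + (2 * n + 1) * Re(a[n] + b[n])
    Qs <- Qs + (2 * n + 1) * (Mod(a[n])^2 + Mod(b[n])^2)
  }
  list(Q_ext = 2 / x^2 * Qe, Q_sca = 2 / x^2 * Qs, a = a, b = b)
}

# band-limited principal-value Kramers-Kronig reference by adaptive
# quadrature with singularity subtraction (gamma_fun: function of nm)
pv_alpha_reference <- function(lambda, gamma_fun, a, b) {
  f <- function(L) {
    lambda^2 / (L * (L^2 - lambda^2)) * (gamma_fun(L) - gamma_fun(lambda))
  }
  I1 <- stats::integrate(f, a, lambda, rel.tol = 1e-10,
                         subdivisions = 2000)$value +
    stats::integrate(f, lambda, b, rel.tol = 1e-10,
                     subdivisions = 2000)$value
  Fpv <- 0.5 * (log(abs(b^2 - lambda^2)) - log(abs(a^2 - lambda^2))) -
    log(b) + log(a)
  -(2 / pi) * (I1 + gamma_fun(lambda) * Fpv)
}

# inverse Kramers-Kronig (real -> imaginary increment) on a tabulated
# uniform grid (lambda0 must be a grid node):
# gamma(l0) = (2 l0 / pi) PV Int alpha(L) / (L^2 - l0^2) dL
pv_gamma_reference <- function(lambda0, grid, alpha) {
  h <- grid[2] - grid[1]
  i0 <- which.min(abs(grid - lambda0))
  stopifnot(abs(grid[i0] - lambda0) < 1e-9)
  a0 <- alpha[i0]
  f <- (alpha - a0) / (grid^2 - lambda0^2)
  dal <- (alpha[min(i0 + 1, length(grid))] -
            alpha[max(i0 - 1, 1)]) /
    (grid[min(i0 + 1, length(grid))] - grid[max(i0 - 1, 1)])
  f[i0] <- dal / (2 * lambda0)
  wt <- rep(h, length(grid))
  wt[c(1, length(grid))] <- h / 2
  a <- grid[1]
  b <- grid[length(grid)]
  Fpv <- (log(abs((b - lambda0) / (b + lambda0))) -
            log(abs((a - lambda0) / (a + lambda0)))) / (2 * lambda0)
  (2 * lambda0 / pi) * (sum(wt * f) + a0 * Fpv)
}

# Lorentz oscillator pair (exact Kramers-Kronig partners over (0, Inf)):
# chi(omega) = 1 / (omega0^2 - omega^2 - i Gamma omega), omega = 1000/lambda
lorentz_pair <- function(center_nm, Gamma) {
  om <- function(l) 1000 / l
  om0 <- om(center_nm)
  chi <- function(l) 1 / (om0^2 - om(l)^2 - 1i * Gamma * om(l))
  list(gamma = function(l) Im(chi(l)) / 2,
       alpha = function(l) Re(chi(l)) / 2)
}
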