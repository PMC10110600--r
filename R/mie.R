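# Lorenz-Mie scattering for a homogeneous sphere with complex refractive
# index. Conventions follow Bohren & Huffman: size parameter x = pi*d /
# lambda_med (lambda_med = lambda/n_med the wavelength in the medium),
# internal parameter y = m*x with m = n_particle / n_medium the complex
# relative index. The logarithmic derivative D_n is evaluated by downward
# recurrence, the Riccati-Bessel functions psi_n and the Hankel-type
# zeta_n = psi_n - i*chi_n by upward recurrence, which is stable for
# absorbing spheres up to x of several thousand.

mie_nstop <- function(x) ceiling(x + 4.05 * x^(1 / 3) + 2)

check_mx <- function(m, x) {
  if (length(m) != 1L || !is.finite(Re(m)) || !is.finite(Im(m))) {
    stop_invalid("mie: relative index m must be a finite scalar")
  }
  if (Re(m) <= 0 || Im(m) < 0) {
    stop_invalid("mie: require Re(m) > 0 and Im(m) >= 0")
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop_invalid("mie: size parameter x must be finite and > 0")
  }
}

#' Lorenz-Mie partial-wave coefficients
#'
#' Computes the scattering coefficients \eqn{a_n, b_n} for a homogeneous
#' sphere of complex relative refractive index `m` and size parameter `x`.
#' The series is truncated at the Wiscombe order
#' \eqn{N = \lceil x + 4.05 x^{1/3} + 2\rceil}.
#'
#' @param m complex relative refractive index (particle over medium).
#' @param x size parameter \eqn{\pi d / \lambda_{med}}, scalar.
#' @return data.frame with columns `n`, `a`, `b` (complex).
#' @examples
#' mie_coefficients(1.1955 + 0i, 5)[1:3, ]
#' @export
mie_coefficients <- function(m, x) {
  check_mx(m, x)
  stopifnot(length(x) == 1L)
  ab <- mie_ab(m, x)
  data.frame(n = seq_len(nrow(ab$a)), a = ab$a[, 1], b = ab$b[, 1])
}

# a_n, b_n for scalar m and a VECTOR of x (shared truncation order);
# returns complex matrices [n, length(x)], entries beyond the per-x
# Wiscombe order zeroed.
mie_ab <- function(m, x) {
  nstop_each <- mie_nstop(x)
  N <- max(nstop_each)
  nx <- length(x)
  if (Mod(m - 1) < 1e-13) {
    z <- matrix(0 + 0i, N, nx)
    return(list(a = z, b = z, nstop = nstop_each))
  }
  y <- m * x
  nmx <- max(N, ceiling(max(Mod(y)))) + 16L
  # downward recurrence for D_n(y) = psi_n'(y)/psi_n(y)
  D <- matrix(0 + 0i, N, nx)
  Dn <- rep(0 + 0i, nx)                 # D_nmx
  for (n in nmx:2) {                    # D_{n-1} from D_n
    Dn <- n / y - 1 / (Dn + n / y)
    if (n - 1 <= N) D[n - 1, ] <- Dn
  }
  # upward recurrence for psi, chi at real argument x
  psi_m1 <- cos(x)          # psi_{-1}
  psi_0 <- sin(x)
  chi_m1 <- -sin(x)
  chi_0 <- cos(x)
  a <- matrix(0 + 0i, N, nx)
  b <- matrix(0 + 0i, N, nx)
  psi_nm1 <- psi_0          # psi_{n-1}, starts at n = 1
  psi_nm2 <- psi_m1
  chi_nm1 <- chi_0
  chi_nm2 <- chi_m1
  for (n in seq_len(N)) {
    psi_n <- (2 * n - 1) / x * psi_nm1 - psi_nm2
    chi_n <- (2 * n - 1) / x * chi_nm1 - chi_nm2
    zeta_n <- complex(real = psi_n, imaginary = -chi_n)
    zeta_nm1 <- complex(real = psi_nm1, imaginary = -chi_nm1)
    fa <- D[n, ] / m + n / x
    fb <- D[n, ] * m + n / x
    a[n, ] <- (fa * psi_n - psi_nm1) / (fa * zeta_n - zeta_nm1)
    b[n, ] <- (fb * psi_n - psi_nm1) / (fb * zeta_n - zeta_nm1)
    psi_nm2 <- psi_nm1
    psi_nm1 <- psi_n
    chi_nm2 <- chi_nm1
    chi_nm1 <- chi_n
  }
  # zero the tail beyond each x's own truncation order
  if (nx > 1L || N > nstop_each[1]) {
    mask <- outer(seq_len(N), nstop_each, ">")
    a[mask] <- 0 + 0i
    b[mask] <- 0 + 0i
    a[!is.finite(a)] <- 0 + 0i
    b[!is.finite(b)] <- 0 + 0i
  }
  list(a = a, b = b, nstop = nstop_each)
}

#' Mie efficiencies and asymmetry factor
#'
#' Extinction, scattering and absorption efficiencies and the asymmetry
#' factor g of a homogeneous sphere. `Q_abs` is returned as
#' `Q_ext - Q_sca` and is exactly zero for a real index.
#'
#' @inheritParams mie_coefficients
#' @param x size parameter(s); vectorised.
#' @return data.frame with columns `x`, `Q_ext`, `Q_sca`, `Q_abs`, `g`.
#' @examples
#' mie_efficiencies(1.59 / 1.33 + 0i, c(0.1, 1, 10))
#' @export
mie_efficiencies <- function(m, x) {
  check_mx(m, x)
  ab <- mie_ab(m, x)
  a <- ab$a
  b <- ab$b
  N <- nrow(a)
  n <- seq_len(N)
  w <- 2 * n + 1
  Qext <- 2 / x^2 * colSums(w * Re(a + b))
  Qsca <- 2 / x^2 * colSums(w * (Mod(a)^2 + Mod(b)^2))
  # asymmetry series
  cross <- (2 * n + 1) / (n * (n + 1)) * Re(a * Conj(b))
  if (N >= 2) {
    n1 <- seq_len(N - 1)
    fwd <- n1 * (n1 + 2) / (n1 + 1) *
      Re(a[n1, , drop = FALSE] * Conj(a[n1 + 1, , drop = FALSE]) +
         b[n1, , drop = FALSE] * Conj(b[n1 + 1, , drop = FALSE]))
    gsum <- colSums(fwd) + colSums(cross)
  } else {
    gsum <- colSums(matrix(cross, nrow = N))
  }
  gfac <- ifelse(Qsca > 0, 4 / (x^2 * Qsca) * gsum, 0)
  if (Im(m) == 0) {
    Qabs <- rep(0, length(x))
    Qext <- Qsca
  } else {
    Qabs <- Qext - Qsca
  }
  data.frame(x = x, Q_ext = Qext, Q_sca = Qsca, Q_abs = Qabs, g = gfac)
}

#' Size distribution of a particle population
#'
#' @param shape `"monodisperse"`, `"lognormal"` or `"normal"`.
#' @param mean_radius mean radius in nm (> 0).
#' @param width coefficient of variation (sd/mean), dimensionless;
#'   `width = 0` is equivalent to `"monodisperse"`.
#' @return a `size_distribution` list.
#' @export
size_distribution <- function(shape = c("lognormal", "normal",
                                        "monodisperse"),
                              mean_radius, width = 0) {
  shape <- match.arg(shape)
  if (!is.finite(mean_radius) || mean_radius <= 0) {
    stop_invalid("size_distribution: mean_radius must be > 0")
  }
  if (!is.finite(width) || width < 0) {
    stop_invalid("size_distribution: width must be >= 0")
  }
  if (width == 0) shape <- "monodisperse"
  if (shape == "monodisperse") width <- 0
  structure(list(shape = shape, mean_radius = mean_radius, width = width),
            class = "size_distribution")
}

# Quadrature over a size distribution: radii (nm) and normalized number
# weights. 64-point Gauss-Legendre over +/- 4 widths.
size_quadrature <- function(dist, n_nodes = 64L) {
  if (dist$width == 0) {
    return(list(r = dist$mean_radius, w = 1))
  }
  if (dist$shape == "normal") {
    sd <- dist$width * dist$mean_radius
    lo <- dist$mean_radius - 4 * sd
    hi <- dist$mean_radius + 4 * sd
    if (lo <= 0) {
      stop_invalid("size_quadrature: normal distribution reaches r <= 0; ",
                   "use lognormal or a smaller width")
    }
    gl <- gauss_legendre(n_nodes, lo, hi)
    dens <- stats::dnorm(gl$nodes, dist$mean_radius, sd)
  } else {
    s2 <- log(1 + dist$width^2)
    mu <- log(dist$mean_radius) - s2 / 2
    s <- sqrt(s2)
    gl <- gauss_legendre(n_nodes, exp(mu - 4 * s), exp(mu + 4 * s))
    dens <- stats::dlnorm(gl$nodes, mu, s)
  }
  w <- gl$weights * dens
  list(r = gl$nodes, w = w / sum(w))
}

#' Polydisperse average of Mie cross sections
#'
#' Number-weighted averages of the extinction, scattering and absorption
#' cross sections over a size distribution; the asymmetry factor is
#' weighted by the scattering cross section. Efficiencies are the averaged
#' cross sections normalized by the geometric cross section of the mean
#' radius.
#'
#' @param dist a [size_distribution()].
#' @param m complex relative refractive index at this wavelength.
#' @param wavelength_nm vacuum wavelength (nm).
#' @param n_medium real refractive index of the dispersion medium.
#' @param n_nodes quadrature nodes (default 64).
#' @return one-row data.frame: `sigma_ext`, `sigma_sca`, `sigma_abs`
#'   (nm^2), `Q_ext`, `Q_sca`, `Q_abs`, `g`.
#' @export
polydisperse_average <- function(dist, m, wavelength_nm, n_medium,
                                 n_nodes = 64L) {
  stopifnot(inherits(dist, "size_distribution"))
  q <- size_quadrature(dist, n_nodes)
  x <- 2 * pi * q$r * n_medium / wavelength_nm
  eff <- mie_efficiencies(m, x)
  geo <- pi * q$r^2
  s_ext <- sum(q$w * eff$Q_ext * geo)
  s_sca <- sum(q$w * eff$Q_sca * geo)
  s_abs <- sum(q$w * eff$Q_abs * geo)
  g <- if (s_sca > 0) sum(q$w * eff$Q_sca * geo * eff$g) / s_sca else 0
  geo_mean <- pi * dist$mean_radius^2
  data.frame(sigma_ext = s_ext, sigma_sca = s_sca, sigma_abs = s_abs,
             Q_ext = s_ext / geo_mean, Q_sca = s_sca / geo_mean,
             Q_abs = s_abs / geo_mean, g = g)
}

#' Wavelength-resolved cross sections of a particle model
#'
#' Evaluates the polydisperse Mie absorption and scattering cross sections
#' and the asymmetry factor of a [particle_model()] on a wavelength grid.
#'
#' @param particle a [particle_model()].
#' @param wavelength_nm ascending wavelength grid (nm).
#' @param n_nodes size-quadrature nodes.
#' @return data.frame with `wavelength_nm`, `sigma_a_nm2`, `sigma_s_nm2`,
#'   `g`.
#' @export
spectral_cross_sections <- function(particle, wavelength_nm,
                                    n_nodes = 64L) {
  stopifnot(inherits(particle, "particle_model"))
  if (is.unsorted(wavelength_nm, strictly = TRUE)) {
    stop_invalid("spectral_cross_sections: wavelength grid must be ",
                 "strictly ascending")
  }
  dist <- size_distribution(particle$shape, particle$r_p_nm,
                            particle$width)
  n_med <- particle$n_medium(wavelength_nm)
  n_par <- particle$n_particle(wavelength_nm)
  out <- vapply(seq_along(wavelength_nm), function(i) {
    m <- n_par[i] / n_med[i]
    r <- polydisperse_average(dist, m, wavelength_nm[i], n_med[i],
                              n_nodes)
    c(r$sigma_abs, r$sigma_sca, r$g)
  }, numeric(3))
  data.frame(wavelength_nm = wavelength_nm,
             sigma_a_nm2 = out[1, ], sigma_s_nm2 = out[2, ],
             g = out[3, ])
}
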