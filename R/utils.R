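# Small numerical building blocks shared across modules.

#' Gauss-Legendre quadrature nodes and weights
#'
#' Golub-Welsch nodes/weights for \eqn{\int_a^b f(x) dx}.
#'
#' @param n number of nodes.
#' @param a,b interval endpoints.
#' @return list with numeric `nodes` and `weights` (ascending nodes).
#' @export
gauss_legendre <- function(n, a = -1, b = 1) {
  stopifnot(n >= 1, b > a)
  if (n == 1L) {
    x <- 0
    w <- 2
  } else {
    k <- seq_len(n - 1)
    off <- k / sqrt(4 * k^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(k, k + 1)] <- off
    J[cbind(k + 1, k)] <- off
    e <- eigen(J, symmetric = TRUE)
    x <- rev(e$values)
    w <- rev(2 * e$vectors[1, ]^2)
    ord <- order(x)
    x <- x[ord]
    w <- w[ord]
  }
  list(nodes = (b - a) / 2 * x + (a + b) / 2, weights = (b - a) / 2 * w)
}

# Gauss-Radau rule on [a, b] with a fixed node at the RIGHT endpoint b.
# Gautschi's modified-Jacobi-matrix construction for Legendre weight.
radau_right <- function(n, a = -1, b = 1) {
  stopifnot(n >= 2, b > a)
  # monic Legendre recurrence coefficients; fixed endpoint +1 on [-1, 1]
  bet <- function(k) k^2 / (4 * k^2 - 1)
  p_prev <- 0
  p_cur <- 1
  for (k in seq_len(n - 1)) {           # evaluate monic pi_k at x = 1
    p_new <- 1 * p_cur - (if (k >= 2) bet(k - 1) else 0) * p_prev
    # note: alpha_k = 0 for Legendre, recurrence pi_k = x pi_{k-1} - beta pi_{k-2}
    p_prev <- p_cur
    p_cur <- p_new
  }
  alpha_star <- 1 - bet(n - 1) * p_prev / p_cur
  k <- seq_len(n - 1)
  off <- sqrt(bet(k))
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- off
  J[cbind(k + 1, k)] <- off
  J[n, n] <- alpha_star
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  x[n] <- 1                              # pin the endpoint exactly
  list(nodes = (b - a) / 2 * x + (a + b) / 2, weights = (b - a) / 2 * w)
}

# Legendre polynomials P_0..P_{K-1} evaluated at x: K x length(x) matrix.
legendre_matrix <- function(K, x) {
  P <- matrix(0, K, length(x))
  P[1, ] <- 1
  if (K >= 2) P[2, ] <- x
  if (K >= 3) {
    for (k in 2:(K - 1)) {
      P[k + 1, ] <- ((2 * k - 1) * x * P[k, ] - (k - 1) * P[k - 1, ]) / k
    }
  }
  P
}

#' Unpolarized Fresnel reflectance of a single interface
#'
#' @param n_i,n_t refractive indices of the incidence and transmission media.
#' @param mu cosine of the angle of incidence (vectorised).
#' @return reflectance in `[0, 1]`; 1 beyond the critical angle.
#' @export
fresnel_reflectance <- function(n_i, n_t, mu) {
  mu <- pmin(pmax(mu, 0), 1)
  sin_t2 <- (n_i / n_t)^2 * (1 - mu^2)
  r <- rep(1, length(mu))
  ok <- sin_t2 < 1
  if (any(ok)) {
    mu_t <- sqrt(1 - sin_t2[ok])
    mi <- mu[ok]
    rs <- ((n_i * mi - n_t * mu_t) / (n_i * mi + n_t * mu_t))^2
    rp <- ((n_i * mu_t - n_t * mi) / (n_i * mu_t + n_t * mi))^2
    r[ok] <- (rs + rp) / 2
  }
  r
}

#' Reflectance of a cuvette-wall boundary seen from inside the slab
#'
#' The cuvette window is treated as a single effective boundary pair
#' (dispersion medium | wall glass | outside), summing multiple internal
#' reflections in the non-absorbing wall incoherently.
#'
#' @param mu cosine of the internal angle of incidence (vectorised).
#' @param n_slab,n_wall,n_outside refractive indices. Setting
#'   `n_wall = n_slab` degenerates to a bare medium/outside interface.
#' @return reflectance in `[0, 1]`.
#' @export
boundary_reflectance <- function(mu, n_slab, n_wall, n_outside) {
  if (abs(n_wall - n_slab) < 1e-12) {
    return(fresnel_reflectance(n_slab, n_outside, mu))
  }
  r1 <- fresnel_reflectance(n_slab, n_wall, mu)
  sin_w2 <- (n_slab / n_wall)^2 * (1 - mu^2)
  out <- rep(1, length(mu))
  ok <- sin_w2 < 1
  if (any(ok)) {
    mu_w <- sqrt(1 - sin_w2[ok])
    r2 <- fresnel_reflectance(n_wall, n_outside, mu_w)
    r1k <- r1[ok]
    out[ok] <- r1k + (1 - r1k)^2 * r2 / (1 - r1k * r2)
  }
  out
}

stop_invalid <- function(...) stop(..., call. = FALSE)
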