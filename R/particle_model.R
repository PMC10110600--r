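#' Particle model of a dispersion
#'
#' Bundles everything Mie theory needs about a particle population:
#' mean radius, size-distribution shape and width (coefficient of
#' variation), number concentration, and the complex refractive index of
#' particle and medium. Index arguments may be given as constants,
#' functions of wavelength (nm), or [spectrum()] objects.
#'
#' @param r_p_nm mean particle radius (nm, > 0).
#' @param N_p_per_ml number concentration (1/mL, > 0).
#' @param width size-distribution coefficient of variation (>= 0).
#' @param shape `"lognormal"`, `"normal"` or `"monodisperse"`.
#' @param n_matrix real refractive index of the particle matrix
#'   (default polystyrene).
#' @param n_medium real refractive index of the dispersion medium
#'   (default water).
#' @param n2 imaginary refractive index of the particle (>= 0), e.g. from
#'   [assemble_index()]; default 0 (unstained).
#' @param n1_increment additive real-index term of the particle, e.g. the
#'   Kramers-Kronig dye contribution `c_dye * alpha`; default 0.
#' @return a `particle_model` list with `n_particle(lambda)` (complex) and
#'   `n_medium(lambda)` accessor functions.
#' @export
particle_model <- function(r_p_nm, N_p_per_ml, width = 0,
                           shape = "lognormal",
                           n_matrix = n_polystyrene,
                           n_medium = n_water,
                           n2 = 0, n1_increment = 0) {
  if (!is.finite(r_p_nm) || r_p_nm <= 0) {
    stop_invalid("particle_model: r_p_nm must be > 0")
  }
  if (!is.finite(N_p_per_ml) || N_p_per_ml <= 0) {
    stop_invalid("particle_model: N_p_per_ml must be > 0")
  }
  if (width < 0) stop_invalid("particle_model: width must be >= 0")
  f_mat <- as_index_fun(n_matrix)
  f_med <- as_index_fun(n_medium)
  f_n2 <- as_index_fun(n2)
  f_n1i <- as_index_fun(n1_increment)
  n_particle <- function(l) {
    v2 <- f_n2(l)
    if (any(v2 < -1e-12)) stop_invalid("particle_model: n2 must be >= 0")
    complex(real = f_mat(l) + f_n1i(l), imaginary = pmax(v2, 0))
  }
  structure(list(
    r_p_nm = r_p_nm, N_p_per_ml = N_p_per_ml, width = width,
    shape = if (width == 0) "monodisperse" else shape,
    n_particle = n_particle, n_medium = f_med,
    n_matrix_fun = f_mat, n2_fun = f_n2, n1_increment_fun = f_n1i
  ), class = "particle_model")
}

# normalize scalar / function / spectrum to a function of wavelength (nm)
as_index_fun <- function(x) {
  if (is.function(x)) return(x)
  if (is_spectrum(x)) {
    force(x)
    return(function(l) interp_spectrum(x, l, rule = 2))
  }
  if (is.numeric(x) && length(x) == 1L) {
    force(x)
    return(function(l) rep(x, length(l)))
  }
  stop_invalid("index must be a scalar, a function, or a spectrum")
}

#' Bulk optical coefficients of a particle dispersion from Mie theory
#'
#' Converts the per-particle cross sections of a [particle_model()] into
#' the bulk absorption and scattering coefficients of the dispersion,
#' `mu = N_p * sigma`, on a wavelength grid.
#'
#' @inheritParams spectral_cross_sections
#' @return a `bulk_optics` data.frame with columns `wavelength_nm`,
#'   `mu_a_per_mm`, `mu_s_per_mm`, `g`.
#' @export
bulk_optics_from_particles <- function(particle, wavelength_nm,
                                       n_nodes = 64L) {
  cs <- spectral_cross_sections(particle, wavelength_nm, n_nodes)
  # 1/mm = (1/mL) * nm^2 * 1e-15
  out <- data.frame(
    wavelength_nm = wavelength_nm,
    mu_a_per_mm = particle$N_p_per_ml * cs$sigma_a_nm2 * 1e-15,
    mu_s_per_mm = particle$N_p_per_ml * cs$sigma_s_nm2 * 1e-15,
    g = cs$g
  )
  class(out) <- c("bulk_optics", "data.frame")
  out
}

#' Bulk optics container
#'
#' @param wavelength_nm wavelength grid (nm).
#' @param mu_a_per_mm absorption coefficient (1/mm, >= 0).
#' @param mu_s_per_mm scattering coefficient (1/mm, >= 0).
#' @param g scattering anisotropy factor (mean cosine, in (-1, 1)).
#' @return a `bulk_optics` data.frame.
#' @export
bulk_optics <- function(wavelength_nm, mu_a_per_mm, mu_s_per_mm, g) {
  n <- length(wavelength_nm)
  stopifnot(length(mu_a_per_mm) == n, length(mu_s_per_mm) == n,
            length(g) == n)
  if (any(mu_a_per_mm < 0) || any(mu_s_per_mm < 0)) {
    stop_invalid("bulk_optics: coefficients must be >= 0")
  }
  if (any(abs(g) >= 1)) stop_invalid("bulk_optics: require |g| < 1")
  out <- data.frame(wavelength_nm = wavelength_nm,
                    mu_a_per_mm = mu_a_per_mm,
                    mu_s_per_mm = mu_s_per_mm, g = g)
  class(out) <- c("bulk_optics", "data.frame")
  out
}
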