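# Kramers-Kronig modelling of the dye contribution to the complex
# refractive index of a dye-loaded particle. The imaginary increment
# gamma(lambda) follows directly from the molar extinction spectrum; the
# real increment alpha(lambda) is its principal-value Kramers-Kronig
# transform over a finite wavelength band, evaluated on a 0.5 nm working
# grid with a Maclaurin alternating-node scheme (the integrand is
# evaluated only at nodes an odd number of steps from the singular node,
# with doubled step weight), then downsampled for Mie work.

#' Dye extinction spectrum with its integration band
#'
#' @param epsilon a [spectrum()] of the molar decadic extinction
#'   coefficient (L mol^-1 cm^-1, >= 0).
#' @param band numeric `c(lambda_a, lambda_b)` nm: the Kramers-Kronig
#'   integration range; must lie inside the tabulated grid.
#' @return a `dye_spectrum` list.
#' @export
dye_spectrum <- function(epsilon, band) {
  stopifnot(is_spectrum(epsilon), length(band) == 2, band[1] < band[2])
  if (any(epsilon$value < 0)) {
    stop_invalid("dye_spectrum: negative extinction coefficient")
  }
  if (band[1] < min(epsilon$wavelength_nm) - 1e-9 ||
      band[2] > max(epsilon$wavelength_nm) + 1e-9) {
    stop_invalid("dye_spectrum: band outside the tabulated grid")
  }
  structure(list(epsilon = epsilon, band = band), class = "dye_spectrum")
}

#' Imaginary refractive-index increment of a dye
#'
#' `gamma(lambda) = (ln 10 / 4 pi) * epsilon(lambda) * lambda`, with
#' `lambda` in cm so that the increment carries units of an inverse
#' molar concentration (L/mol).
#'
#' @param dye a [dye_spectrum()] (or bare [spectrum()] of epsilon).
#' @return a [spectrum()] of gamma (L/mol) on the input grid.
#' @export
gamma_increment <- function(dye) {
  eps <- if (inherits(dye, "dye_spectrum")) dye$epsilon else dye
  stopifnot(is_spectrum(eps))
  if (any(eps$value < 0)) {
    stop_invalid("gamma_increment: negative extinction coefficient")
  }
  lambda_cm <- eps$wavelength_nm * 1e-7
  spectrum(eps$wavelength_nm, log(10) / (4 * pi) * eps$value * lambda_cm,
           quantity = "gamma_L_per_mol")
}

#' Real refractive-index increment by finite-band Kramers-Kronig
#'
#' Evaluates
#' `alpha(lambda) = -(2/pi) PV Int_a^b (lambda/L)(lambda/(L^2-lambda^2))
#' gamma(L) dL` on a uniform working grid (default 0.5 nm) and
#' downsamples the result to `step_out`. Only the band's own
#' contribution is reported; spectra differing outside the band would
#' add constant or normal-dispersion terms, which can be supplied via
#' `baseline`.
#'
#' @param gamma a [spectrum()] of the imaginary increment (L/mol), e.g.
#'   from [gamma_increment()].
#' @param band `c(lambda_a, lambda_b)` nm integration range.
#' @param step_out output grid step in nm (default 5).
#' @param step_work working grid step in nm (default 0.5).
#' @param lambda_out optional explicit output wavelengths; values outside
#'   the band require `extrapolate = TRUE` (the kernel is regular there).
#' @param extrapolate allow evaluation outside the band.
#' @param baseline optional function of wavelength added to alpha
#'   (user-supplied out-of-band dispersion term); default zero.
#' @return a [spectrum()] of alpha (L/mol).
#' @export
alpha_increment <- function(gamma, band, step_out = 5, step_work = 0.5,
                            lambda_out = NULL, extrapolate = FALSE,
                            baseline = NULL) {
  stopifnot(is_spectrum(gamma), length(band) == 2, band[1] < band[2])
  grid <- seq(band[1], band[2], by = step_work)
  if (grid[length(grid)] < band[2] - 1e-9) grid <- c(grid, band[2])
  gam <- interp_spectrum(gamma, grid, rule = 2)
  if (is.null(lambda_out)) {
    lambda_out <- seq(ceiling(band[1] / step_out) * step_out, band[2],
                      by = step_out)
  } else if (!extrapolate &&
             (min(lambda_out) < band[1] - 1e-9 ||
              max(lambda_out) > band[2] + 1e-9)) {
    stop_invalid("alpha_increment: output wavelength outside the band; ",
                 "set extrapolate = TRUE to evaluate the regular kernel")
  }
  alpha_work <- kk_pv_subtracted(grid, gam)
  a_out <- stats::approx(grid, alpha_work, xout = lambda_out,
                         rule = 2)$y
  outside <- lambda_out < band[1] | lambda_out > band[2]
  if (any(outside)) {
    # regular integrand outside the band: plain trapezoid
    for (i in which(outside)) {
      l <- lambda_out[i]
      a_out[i] <- -(2 / pi) *
        trapz_(grid, l^2 / (grid * (grid^2 - l^2)) * gam)
    }
  }
  if (!is.null(baseline)) a_out <- a_out + baseline(lambda_out)
  spectrum(lambda_out, a_out, quantity = "alpha_L_per_mol")
}

# Principal value on a uniform grid by singularity subtraction:
#   PV Int K(l,L) g(L) dL = Int K(l,L) (g(L) - g(l)) dL + g(l) PV Int K dL
# The first integrand is regular at L = l (limit g'(l)/2) and is
# integrated by the trapezoidal rule; the kernel's principal value has
# the closed form [ln(|L^2 - l^2|) / 2 - ln(L)] evaluated at the band
# ends. Second-order accurate independent of the band-edge values of g.
kk_pv_subtracted <- function(grid, gam) {
  h <- grid[2] - grid[1]
  J <- length(grid)
  wt <- rep(h, J)
  wt[c(1, J)] <- h / 2
  Kmat <- outer(grid, grid, function(l, L) l^2 / (L * (L^2 - l^2)))
  diag(Kmat) <- 0
  dgam <- numeric(J)                    # central-difference g'(l)
  dgam[2:(J - 1)] <- (gam[3:J] - gam[1:(J - 2)]) / (2 * h)
  dgam[1] <- (gam[2] - gam[1]) / h
  dgam[J] <- (gam[J] - gam[J - 1]) / h
  a <- grid[1]
  b <- grid[J]
  Fpv <- 0.5 * (log(abs(b^2 - grid^2)) - log(abs(a^2 - grid^2))) -
    log(b) + log(a)
  Fpv[1] <- 0.5 * (log(b^2 - a^2) - log(2 * a * h)) - log(b) + log(a)
  Fpv[J] <- 0.5 * (log(2 * b * h) - log(b^2 - a^2)) - log(b) + log(a)
  reg <- Kmat %*% (wt * gam) - (Kmat %*% wt) * gam + wt * dgam / 2
  as.numeric(-(2 / pi) * (reg + gam * Fpv))
}

#' Assemble the complex refractive index of a dye-loaded particle
#'
#' `n(lambda) = n_matrix(lambda) + c_dye [alpha(lambda) + i
#' gamma(lambda)]`, with the matrix assumed non-absorbing
#' (`n2_matrix = 0`). Setting `include_real = FALSE` omits the alpha
#' term, reproducing the first-pass model in which the real part of the
#' stained particle equals that of the unstained particle.
#'
#' @param n_matrix real matrix index: scalar, function of wavelength or
#'   [spectrum()].
#' @param c_dye intra-particle molar dye concentration (mol/L, >= 0).
#' @param increments list with `gamma` and (if `include_real`) `alpha`
#'   [spectrum()] objects on compatible grids, e.g. from
#'   [gamma_increment()] / [alpha_increment()].
#' @param wavelength_nm evaluation grid; defaults to the gamma grid.
#' @param include_real include the Kramers-Kronig real-part term.
#' @return data.frame with `wavelength_nm`, `n1`, `n2`.
#' @export
assemble_index <- function(n_matrix, c_dye, increments,
                           wavelength_nm = NULL, include_real = TRUE) {
  if (!is.finite(c_dye) || c_dye < 0) {
    stop_invalid("assemble_index: c_dye must be >= 0")
  }
  stopifnot(is_spectrum(increments$gamma))
  if (include_real && !is_spectrum(increments$alpha)) {
    stop_invalid("assemble_index: alpha increment missing")
  }
  if (is.null(wavelength_nm)) {
    wavelength_nm <- increments$gamma$wavelength_nm
  }
  f_mat <- as_index_fun(n_matrix)
  gam <- interp_spectrum(increments$gamma, wavelength_nm, rule = 2)
  alp <- if (include_real) {
    interp_spectrum(increments$alpha, wavelength_nm, rule = 2)
  } else {
    0
  }
  data.frame(wavelength_nm = wavelength_nm,
             n1 = f_mat(wavelength_nm) + c_dye * alp,
             n2 = c_dye * gam)
}
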