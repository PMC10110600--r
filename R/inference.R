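# Particle inference: the coupled Mie/radiation-transport least-squares
# fit that turns bulk optical coefficients into single-particle
# properties, and the derived brightness metrics.
#
# The fit exploits the structure of the problem rather than attacking a
# joint nonlinear problem: the number concentration enters mu = N_p *
# sigma linearly and is profiled out in closed form; radius and
# distribution width are the only genuinely nonlinear shape parameters
# (they set the Mie resonance positions and contrast in mu_s and g); the
# imaginary index only affects mu_a to first order at the loadings of
# interest and is recovered in a separate stage, either as a single
# scale on a fixed dye band shape or per-wavelength. Stages are iterated
# because n2 (and, with the Kramers-Kronig term, the accompanying real
# increment) feeds back weakly into mu_s.

#' Cross section from a bulk coefficient
#'
#' `sigma = mu / N_p` with unit conversion: `mu` in 1/mm, `N_p` in 1/mL,
#' `sigma` in cm^2.
#'
#' @param mu_per_mm bulk coefficient (1/mm); absorption or scattering.
#' @param N_p_per_ml number concentration (1/mL, > 0).
#' @return cross section(s) in cm^2.
#' @export
sigma_from_mu <- function(mu_per_mm, N_p_per_ml) {
  if (!all(is.finite(N_p_per_ml)) || any(N_p_per_ml <= 0)) {
    stop_invalid("sigma_from_mu: N_p must be > 0")
  }
  (mu_per_mm * 10) / N_p_per_ml        # (1/cm) / (1/cm^3) = cm^2
}

#' Absorption (or scattering) efficiency from a cross section
#'
#' `Q = sigma / (pi r_p^2)`, the cross section over the geometric cross
#' section of the particle.
#'
#' @param sigma_cm2 cross section (cm^2).
#' @param r_p_nm particle radius (nm, > 0).
#' @return dimensionless efficiency.
#' @export
absorption_efficiency <- function(sigma_cm2, r_p_nm) {
  if (!all(is.finite(r_p_nm)) || any(r_p_nm <= 0)) {
    stop_invalid("absorption_efficiency: r_p must be > 0")
  }
  sigma_cm2 / (pi * (r_p_nm * 1e-7)^2)
}

#' Particle brightness
#'
#' `B = sigma_a(lambda_ex) * Phi_pl`, in cm^2: the sample-side
#' determinant of the detected signal per particle.
#'
#' @param sigma_a_cm2 absorption cross section at the excitation
#'   wavelength (cm^2, >= 0).
#' @param phi_pl photoluminescence quantum yield in `[0, 1]`.
#' @return brightness in cm^2.
#' @export
brightness <- function(sigma_a_cm2, phi_pl) {
  if (any(phi_pl < 0 | phi_pl > 1)) {
    stop_invalid("brightness: phi_pl must be in `[0, 1]`")
  }
  if (any(sigma_a_cm2 < 0)) stop_invalid("brightness: sigma_a must be >= 0")
  sigma_a_cm2 * phi_pl
}

#' Luminescence efficiency
#'
#' `LE = Q_abs * Phi_pl`: the size-independent fraction of photons
#' incident on the particle's geometric cross section that are
#' re-emitted. Values above 1 (possible for resonant spheres with
#' `Q_abs > 1`) are flagged with a warning, not errored.
#'
#' @param Q_abs absorption efficiency (>= 0).
#' @param phi_pl quantum yield in `[0, 1]`.
#' @return luminescence efficiency.
#' @export
luminescence_efficiency <- function(Q_abs, phi_pl) {
  if (any(Q_abs < 0)) {
    stop_invalid("luminescence_efficiency: Q_abs must be >= 0")
  }
  if (any(phi_pl < 0 | phi_pl > 1)) {
    stop_invalid("luminescence_efficiency: phi_pl must be in `[0, 1]`")
  }
  le <- Q_abs * phi_pl
  if (any(le > 1)) {
    warning("luminescence_efficiency: LE > 1 (resonant Q_abs)")
  }
  le
}

#' Molecular-brightness approximation
#'
#' `B_mol = N_dye * epsilon(lambda_ex) * Phi_pl` in L mol^-1 cm^-1: the
#' small-particle / low-loading approximation of particle brightness via
#' the number of incorporated dye molecules and the dye's molar
#' extinction coefficient in a matrix-mimicking solvent.
#'
#' @param N_dye dye molecules per particle (>= 0).
#' @param epsilon_ex molar extinction at the excitation wavelength
#'   (L mol^-1 cm^-1, >= 0).
#' @param phi_pl quantum yield in `[0, 1]`.
#' @return molecular brightness (L mol^-1 cm^-1).
#' @export
molecular_brightness <- function(N_dye, epsilon_ex, phi_pl) {
  if (any(N_dye < 0) || any(epsilon_ex < 0)) {
    stop_invalid("molecular_brightness: inputs must be >= 0")
  }
  if (any(phi_pl < 0 | phi_pl > 1)) {
    stop_invalid("molecular_brightness: phi_pl must be in `[0, 1]`")
  }
  N_dye * epsilon_ex * phi_pl
}

#' Dye loading from dissolution photometry
#'
#' Average number of dye molecules per particle and the intra-particle
#' molar concentration, from the absorbance of the dye released by
#' dissolving a known particle mass: Beer-Lambert gives the dissolved
#' dye concentration, the particle count follows from the mass, the
#' particle volume and the polystyrene density (1050 kg/m^3).
#'
#' @param absorbance absorbance of the dissolved-dye solution at 1 cm
#'   path (>= 0).
#' @param epsilon molar extinction of the dye in the dissolution solvent
#'   (L mol^-1 cm^-1, > 0).
#' @param dissolved_volume_l volume of the dissolved-dye solution (L).
#' @param ps_mass_mg dissolved particle mass (mg, > 0).
#' @param r_p_nm particle radius (nm, > 0).
#' @param rho_ps_kg_m3 particle material density (default polystyrene,
#'   1050 kg/m^3).
#' @return list with `N_dye` (molecules per particle), `c_dye_mol_l`
#'   (intra-particle mol/L), `n_particles`, `moles_dye`.
#' @export
dye_loading <- function(absorbance, epsilon, dissolved_volume_l,
                        ps_mass_mg, r_p_nm, rho_ps_kg_m3 = 1050) {
  if (absorbance < 0) stop_invalid("dye_loading: absorbance must be >= 0")
  if (epsilon <= 0 || ps_mass_mg <= 0 || r_p_nm <= 0) {
    stop_invalid("dye_loading: epsilon, ps_mass and r_p must be > 0")
  }
  c_dissolved <- absorbance / epsilon            # mol/L at 1 cm path
  moles <- c_dissolved * dissolved_volume_l
  v_particle_m3 <- 4 / 3 * pi * (r_p_nm * 1e-9)^3
  mass_particle_kg <- rho_ps_kg_m3 * v_particle_m3
  n_particles <- ps_mass_mg * 1e-6 / mass_particle_kg
  v_total_l <- n_particles * v_particle_m3 * 1e3  # m^3 -> L
  list(
    N_dye = moles * 6.02214076e23 / n_particles,
    c_dye_mol_l = if (v_total_l > 0) moles / v_total_l else 0,
    n_particles = n_particles,
    moles_dye = moles
  )
}

# oscillation contrast of mu_s(lambda): sd of log(mu_s) around a
# quadratic trend; Mie resonances show up as contrast >> noise.
resonance_contrast <- function(wavelength_nm, mu_s) {
  ok <- mu_s > 0
  if (sum(ok) < 8) return(0)
  l <- wavelength_nm[ok]
  y <- log(mu_s[ok])
  fit <- stats::lm(y ~ poly(l, 2))
  stats::sd(stats::residuals(fit))
}

#' Fit particle properties to bulk optical coefficients
#'
#' Least-squares recovery of mean radius, size-distribution width,
#' number concentration, and the imaginary refractive index of the
#' particles from `(mu_s, g, mu_a)` spectra, using polydisperse Mie
#' theory. Residuals are relative on `mu_s` and `mu_a` and absolute on
#' `g`. `N_p` is profiled out analytically at each trial shape.
#'
#' When a dye band shape is supplied (`dye_gamma`), `n2(lambda)` is
#' fitted as a single scale on that shape and, with
#' `use_kk_real_part = TRUE`, the matching Kramers-Kronig real increment
#' is included in `n1`; otherwise `n2` is recovered per wavelength.
#'
#' @param optics a [bulk_optics()] data.frame (columns `wavelength_nm`,
#'   `mu_a_per_mm`, `mu_s_per_mm`, `g`).
#' @param n_matrix,n_medium real index of particle matrix and medium
#'   (constant, function or [spectrum()]); defaults polystyrene in
#'   water.
#' @param dye_gamma optional [spectrum()]: the imaginary-increment band
#'   shape of the dye (any overall scale), e.g. from
#'   [gamma_increment()].
#' @param use_kk_real_part include the Kramers-Kronig real-part
#'   increment consistent with the fitted `n2` (requires `dye_gamma`).
#' @param kk_band integration band for the Kramers-Kronig transform of
#'   `dye_gamma` (nm); defaults to its tabulated range.
#' @param shape size-distribution family (`"lognormal"` default).
#' @param r_init optional initial radius guess (nm); required when
#'   `mu_s` shows no Mie resonance structure.
#' @param width_max upper bound on the distribution width (default 0.2).
#' @param n_nodes size-quadrature nodes used during fitting.
#' @param max_rounds shape/absorption alternation rounds.
#' @return list with `particle` (fitted [particle_model()]), `n2`
#'   (data.frame `wavelength_nm`, `n2`), and `diagnostics` (residual
#'   norms, resonance contrast, convergence flags).
#' @export
fit_particles <- function(optics, n_matrix = n_polystyrene,
                          n_medium = n_water, dye_gamma = NULL,
                          use_kk_real_part = FALSE, kk_band = NULL,
                          shape = "lognormal", r_init = NULL,
                          width_max = 0.2, n_nodes = 48L,
                          max_rounds = 2L) {
  stopifnot(is.data.frame(optics))
  wl <- optics$wavelength_nm
  mu_s <- optics$mu_s_per_mm
  mu_a <- optics$mu_a_per_mm
  g_obs <- optics$g
  if (use_kk_real_part && is.null(dye_gamma)) {
    stop_invalid("fit_particles: use_kk_real_part requires dye_gamma")
  }
  contrast <- resonance_contrast(wl, mu_s)
  if (contrast < 0.01 && is.null(r_init)) {
    stop_invalid(
      "fit_particles: underdetermined fit, mu_s(lambda) shows no Mie ",
      "resonance structure (contrast ", signif(contrast, 2),
      "); supply a known radius via r_init")
  }
  f_mat <- as_index_fun(n_matrix)
  f_med <- as_index_fun(n_medium)

  # normalized dye band shape and (optionally) its KK real companion
  gshape <- NULL
  ashape_fun <- NULL
  if (!is.null(dye_gamma)) {
    stopifnot(is_spectrum(dye_gamma))
    pk <- max(dye_gamma$value)
    gshape <- spectrum(dye_gamma$wavelength_nm, dye_gamma$value / pk)
    if (use_kk_real_part) {
      band <- if (is.null(kk_band)) range(gshape$wavelength_nm) else kk_band
      ash <- alpha_increment(gshape, band, step_out = 1,
                             lambda_out = wl, extrapolate = TRUE)
      av <- ash$value
      ashape_fun <- function(l) stats::approx(wl, av, xout = l,
                                              rule = 2)$y
    }
  }
  gshape_wl <- if (!is.null(gshape)) interp_spectrum(gshape, wl, rule = 2)

  model_mu <- function(r, w, n2_scale) {
    n2f <- if (is.null(gshape)) {
      0
    } else {
      sg <- spectrum(wl, pmax(n2_scale * gshape_wl, 0))
      sg
    }
    n1i <- if (!is.null(ashape_fun) && n2_scale > 0) {
      s <- n2_scale
      function(l) s * ashape_fun(l)
    } else {
      0
    }
    pm <- particle_model(r, 1, width = w, shape = shape,
                         n_matrix = f_mat, n_medium = f_med,
                         n2 = n2f, n1_increment = n1i)
    cs <- spectral_cross_sections(pm, wl, n_nodes)
    list(sig_s = cs$sigma_s_nm2 * 1e-15, sig_a = cs$sigma_a_nm2 * 1e-15,
         g = cs$g)
  }

  profile_Np <- function(sig_s) {
    q <- sig_s / mu_s
    sum(q) / sum(q^2)
  }

  shape_resid <- function(r, w, n2_scale) {
    mm <- model_mu(r, w, n2_scale)
    Np <- profile_Np(mm$sig_s)
    c((Np * mm$sig_s - mu_s) / mu_s, mm$g - g_obs)
  }

  n2_scale <- 0
  # coarse scan for the radius (profiled residual), unless seeded
  if (is.null(r_init)) {
    r_grid <- exp(seq(log(100), log(2500), length.out = 60))
  } else {
    r_grid <- r_init * seq(0.85, 1.15, by = 0.025)
  }
  sub <- unique(c(seq(1, length(wl), by = 2), length(wl)))
  coarse <- vapply(r_grid, function(r) {
    mm <- tryCatch(
      model_mu_sub(r, 0.02, wl[sub], mu_s[sub], f_mat, f_med, shape),
      error = function(e) NULL)
    if (is.null(mm)) return(Inf)
    Np <- sum(mm$q) / sum(mm$q^2)
    sum((Np * mm$sig_s - mu_s[sub])^2 / mu_s[sub]^2)
  }, numeric(1))
  r_best <- r_grid[which.min(coarse)]

  diag_hist <- list()
  for (round in seq_len(max_rounds)) {
    # stage A: (log r, width) by Levenberg-Marquardt
    fitA <- minpack.lm::nls.lm(
      par = c(log_r = log(r_best), w = 0.02),
      lower = c(log(50), 0), upper = c(log(5000), width_max),
      fn = function(p) shape_resid(exp(p[1]), p[2], n2_scale),
      control = minpack.lm::nls.lm.control(maxiter = 60, ptol = 1e-10))
    r_best <- exp(fitA$par[[1]])
    w_best <- fitA$par[[2]]
    mmA <- model_mu(r_best, w_best, n2_scale)
    Np <- profile_Np(mmA$sig_s)

    # stage B: absorption
    if (max(mu_a) <= 0) {
      n2_scale <- 0
      break
    }
    if (!is.null(gshape)) {
      bres <- function(s) {
        mm <- model_mu(r_best, w_best, s)
        sum((Np * mm$sig_a - mu_a)^2 / pmax(mu_a, max(mu_a) * 1e-3)^2)
      }
      # mu_a is nearly linear in the n2 scale: bracket then polish
      s0 <- n2_guess(r_best, w_best, Np, wl, mu_a, gshape_wl, f_mat,
                     f_med, shape, n_nodes)
      opt <- stats::optimize(bres, interval = c(0, 4 * s0), tol = s0 * 1e-5)
      n2_scale <- opt$minimum
    }
  }
  mmF <- model_mu(r_best, w_best, n2_scale)
  Np <- profile_Np(mmF$sig_s)

  if (is.null(gshape) && max(mu_a) > 0) {
    # free per-wavelength n2 from mu_a (secant on the near-linear map)
    n2_free <- vapply(seq_along(wl), function(i) {
      target <- mu_a[i] / Np                     # sigma_a in 1/mm units
      if (target <= 0) return(0)
      solve_n2_single(target, r_best, w_best, wl[i], f_mat, f_med,
                      shape, n_nodes)
    }, numeric(1))
    n2_df <- data.frame(wavelength_nm = wl, n2 = n2_free)
    n2_fun <- spectrum(wl, n2_free)
  } else {
    n2_df <- data.frame(wavelength_nm = wl,
                        n2 = n2_scale * if (is.null(gshape)) 0 else
                          gshape_wl)
    n2_fun <- if (is.null(gshape)) 0 else spectrum(wl, n2_df$n2)
  }
  n1i_fun <- if (!is.null(ashape_fun) && n2_scale > 0) {
    s <- n2_scale
    function(l) s * ashape_fun(l)
  } else {
    0
  }
  particle <- particle_model(r_best, Np, width = w_best, shape = shape,
                             n_matrix = f_mat, n_medium = f_med,
                             n2 = n2_fun, n1_increment = n1i_fun)
  resid <- shape_resid(r_best, w_best, n2_scale)
  list(
    particle = particle,
    n2 = n2_df,
    diagnostics = list(
      residual_norm = sqrt(mean(resid^2)),
      resonance_contrast = contrast,
      resonances_detectable = contrast >= 0.01,
      n2_scale = n2_scale,
      rounds = max_rounds
    )
  )
}

# lightweight subsampled model for the coarse radius scan
model_mu_sub <- function(r, w, wl, mu_s, f_mat, f_med, shape) {
  pm <- particle_model(r, 1, width = w, shape = shape,
                       n_matrix = f_mat, n_medium = f_med)
  cs <- spectral_cross_sections(pm, wl, 16L)
  sig_s <- cs$sigma_s_nm2 * 1e-15
  list(sig_s = sig_s, q = sig_s / mu_s)
}

# initial n2 band scale from the peak-absorption wavelength
n2_guess <- function(r, w, Np, wl, mu_a, gshape_wl, f_mat, f_med,
                     shape, n_nodes) {
  i0 <- which.max(mu_a * gshape_wl)
  target <- mu_a[i0] / Np
  n2i <- solve_n2_single(target, r, w, wl[i0], f_mat, f_med, shape,
                         n_nodes)
  max(n2i / max(gshape_wl[i0], 1e-9), 1e-9)
}

# invert sigma_a(n2) at one wavelength (monotone, near-linear)
solve_n2_single <- function(target_sig_mm, r, w, lambda, f_mat, f_med,
                            shape, n_nodes) {
  sig_a_of <- function(n2) {
    pm <- particle_model(r, 1, width = w, shape = shape,
                         n_matrix = f_mat, n_medium = f_med, n2 = n2)
    spectral_cross_sections(pm, c(lambda - 1e-6, lambda + 1e-6),
                            n_nodes)$sigma_a_nm2[1] * 1e-15
  }
  n2 <- 1e-4
  for (it in 1:30) {
    s <- sig_a_of(n2)
    if (s <= 0) return(0)
    n2_new <- n2 * target_sig_mm / s
    if (abs(n2_new - n2) < 1e-9 * max(n2, 1e-12)) {
      n2 <- n2_new
      break
    }
    n2 <- n2_new
  }
  n2
}

#' Brightness report for one sample
#'
#' Assembles the final deliverable: absorption cross section and
#' efficiency at the excitation wavelength, quantum yield, brightness
#' `B = sigma_a * Phi_pl`, luminescence efficiency
#' `LE = Q_abs * Phi_pl`, and (when dye information is given) the number
#' of dye molecules per particle and the molecular-brightness
#' approximation.
#'
#' @param particle a fitted [particle_model()].
#' @param phi_pl measured quantum yield in `[0, 1]`.
#' @param lambda_ex excitation wavelength (nm).
#' @param mu_a_ex optional measured `mu_a(lambda_ex)` (1/mm); if given,
#'   `sigma_a` is taken from the radiation-transport path
#'   `mu_a / N_p`, otherwise from Mie theory directly.
#' @param N_dye optional dye molecules per particle.
#' @param epsilon_ex optional dye molar extinction at `lambda_ex`.
#' @return a `brightness_report` list.
#' @export
brightness_report <- function(particle, phi_pl, lambda_ex,
                              mu_a_ex = NULL, N_dye = NA,
                              epsilon_ex = NA) {
  stopifnot(inherits(particle, "particle_model"))
  sigma_a_cm2 <- if (!is.null(mu_a_ex)) {
    sigma_from_mu(mu_a_ex, particle$N_p_per_ml)
  } else {
    cs <- spectral_cross_sections(particle,
                                  c(lambda_ex - 1e-6, lambda_ex + 1e-6))
    cs$sigma_a_nm2[1] * 1e-14           # nm^2 -> cm^2
  }
  Q_abs <- absorption_efficiency(sigma_a_cm2, particle$r_p_nm)
  B <- brightness(sigma_a_cm2, phi_pl)
  LE <- luminescence_efficiency(Q_abs, phi_pl)
  structure(list(
    lambda_ex_nm = lambda_ex,
    sigma_a_cm2 = sigma_a_cm2,
    Q_abs = Q_abs,
    phi_pl = phi_pl,
    B_cm2 = B,
    LE = LE,
    N_dye = N_dye,
    B_molecular = if (is.finite(N_dye) && is.finite(epsilon_ex)) {
      molecular_brightness(N_dye, epsilon_ex, phi_pl)
    } else {
      NA_real_
    },
    r_p_nm = particle$r_p_nm,
    N_p_per_ml = particle$N_p_per_ml
  ), class = "brightness_report")
}

#' @export
print.brightness_report <- function(x, ...) {
  cat("Brightness report\n")
  cat(sprintf("  excitation            %g nm\n", x$lambda_ex_nm))
  cat(sprintf("  sigma_a               %.4g cm^2\n", x$sigma_a_cm2))
  cat(sprintf("  Q_abs                 %.4g\n", x$Q_abs))
  cat(sprintf("  Phi_pl                %.4g\n", x$phi_pl))
  cat(sprintf("  B  = sigma_a * Phi    %.4g cm^2\n", x$B_cm2))
  cat(sprintf("  LE = Q_abs * Phi      %.4g\n", x$LE))
  if (is.finite(x$N_dye)) {
    cat(sprintf("  N_dye                 %.4g per particle\n", x$N_dye))
  }
  if (is.finite(x$B_molecular)) {
    cat(sprintf("  B_molecular           %.4g L/(mol cm)\n",
                x$B_molecular))
  }
  invisible(x)
}
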