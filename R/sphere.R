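# Reduction of raw integrating-sphere detector spectra to physical
# observables: sphere magnification, absolute photoluminescence quantum
# yield, diffuse reflectance, total/diffuse transmittance, and
# trap-detector collimated transmittance. All reductions are ratios of
# dark-corrected signals and are therefore invariant under a common
# rescaling of every raw signal (detector gain).

#' Integrating-sphere configuration
#'
#' @param rho_S wall reflectivity: scalar, function of wavelength (nm) or
#'   [spectrum()].
#' @param ports list of ports, each a list with `f` (area fraction
#'   `A_i/A_S`) and `rho` (port reflectivity, same forms as `rho_S`).
#' @param rho_0 reflectivity of the first-strike surface (defaults to the
#'   wall reflectivity).
#' @param detector_area_fraction `A_D/A_S` of the detection port.
#' @return a `sphere_config` list.
#' @export
sphere_config <- function(rho_S = 0.97, ports = list(), rho_0 = NULL,
                          detector_area_fraction = 1e-3) {
  f_tot <- sum(vapply(ports, function(p) p$f, numeric(1)))
  if (f_tot >= 1) stop_invalid("sphere_config: port fractions sum to >= 1")
  if (detector_area_fraction <= 0) {
    stop_invalid("sphere_config: detector_area_fraction must be > 0")
  }
  structure(list(
    rho_S = as_index_fun(rho_S),
    ports = lapply(ports, function(p) list(f = p$f,
                                           rho = as_index_fun(p$rho))),
    rho_0 = as_index_fun(if (is.null(rho_0)) rho_S else rho_0),
    detector_area_fraction = detector_area_fraction
  ), class = "sphere_config")
}

#' Sphere magnification factor
#'
#' Gain of an integrating sphere from multiple wall reflections,
#' `M = rho_0 / (1 - rho_bar)` with the average surface reflectivity
#' `rho_bar = rho_S (1 - sum f_i) + sum rho_i f_i`.
#'
#' @param config a [sphere_config()].
#' @param wavelength_nm wavelength(s) in nm.
#' @return magnification factor (vectorised over wavelength).
#' @export
magnification <- function(config, wavelength_nm) {
  stopifnot(inherits(config, "sphere_config"))
  f_tot <- sum(vapply(config$ports, function(p) p$f, numeric(1)))
  rho_bar <- config$rho_S(wavelength_nm) * (1 - f_tot)
  for (p in config$ports) rho_bar <- rho_bar + p$rho(wavelength_nm) * p$f
  if (any(rho_bar >= 1)) {
    stop_invalid("magnification: average reflectivity >= 1, ",
                 "non-physical sphere")
  }
  config$rho_0(wavelength_nm) / (1 - rho_bar)
}

#' Raw quantum-yield scan set
#'
#' Sample and blank integrating-sphere emission spectra together with the
#' spectral responsivity and the window definitions needed by
#' [quantum_yield()].
#'
#' @param I_x,I_b sample and blank detector spectra ([spectrum()],
#'   counts) covering both the excitation and the emission window.
#' @param s spectral responsivity ([spectrum()], > 0 on both windows).
#' @param lambda_ex excitation wavelength (nm).
#' @param delta_lambda excitation half-bandwidth (nm): the excitation
#'   window is `lambda_ex +/- delta_lambda`.
#' @param emission_window numeric `c(lo, hi)` in nm; must not overlap the
#'   excitation window.
#' @return a `qy_scan` list.
#' @export
qy_scan <- function(I_x, I_b, s, lambda_ex, delta_lambda,
                    emission_window) {
  stopifnot(is_spectrum(I_x), is_spectrum(I_b), is_spectrum(s))
  ex_win <- c(lambda_ex - delta_lambda, lambda_ex + delta_lambda)
  if (emission_window[1] >= emission_window[2]) {
    stop_invalid("qy_scan: emission window limits out of order")
  }
  if (ex_win[2] > emission_window[1] && ex_win[1] < emission_window[2]) {
    stop_invalid("qy_scan: excitation and emission windows overlap; ",
                 "reduce the bandwidth or shift the emission window")
  }
  win_lo <- min(ex_win[1], emission_window[1])
  win_hi <- max(ex_win[2], emission_window[2])
  s_chk <- interp_spectrum(s, seq(win_lo, win_hi, length.out = 101),
                           rule = 2)
  if (any(s_chk <= 0)) {
    stop_invalid("qy_scan: responsivity must be > 0 on both windows")
  }
  structure(list(I_x = I_x, I_b = I_b, s = s, lambda_ex = lambda_ex,
                 delta_lambda = delta_lambda,
                 emission_window = emission_window, ex_window = ex_win),
            class = "qy_scan")
}

#' Absolute photoluminescence quantum yield
#'
#' `Phi_pl = N_em / N_abs`: the emitted photon flux is the
#' responsivity-corrected, photon-weighted net emission integral of
#' sample minus blank over the emission window; the absorbed photon flux
#' is the corresponding blank-minus-sample integral over the excitation
#' window. Negative net emission values (noise floor) are clipped at
#' zero with a warning; `Phi_pl > 1` is flagged, not errored.
#'
#' @param scan a [qy_scan()].
#' @return list with `phi_pl`, the photon fluxes `q_em` and `q_abs`
#'   (arbitrary common units), and a character vector `flags`.
#' @export
quantum_yield <- function(scan) {
  stopifnot(inherits(scan, "qy_scan"))
  wl <- scan$I_x$wavelength_nm
  grid_of <- function(win) {
    inside <- wl > win[1] & wl < win[2]
    unique(sort(c(win[1], wl[inside], win[2])))
  }
  photon_integral <- function(values_net, grid) {
    s_g <- interp_spectrum(scan$s, grid, rule = 2)
    trapz_(grid, values_net / s_g * grid)
  }
  flags <- character()
  g_ex <- grid_of(scan$ex_window)
  net_abs <- interp_spectrum(scan$I_b, g_ex, rule = 2) -
    interp_spectrum(scan$I_x, g_ex, rule = 2)
  q_abs <- photon_integral(net_abs, g_ex)
  if (q_abs <= 0) {
    stop_invalid("quantum_yield: no absorption detected ",
                 "(sample equals blank at the excitation wavelength)")
  }
  g_em <- grid_of(scan$emission_window)
  net_em <- interp_spectrum(scan$I_x, g_em, rule = 2) -
    interp_spectrum(scan$I_b, g_em, rule = 2)
  neg_area <- photon_integral(pmin(net_em, 0), g_em)
  if (neg_area < -1e-9 * q_abs) {
    warning("quantum_yield: negative net emission clipped at 0")
    flags <- c(flags, "emission_clipped")
  }
  net_em <- pmax(net_em, 0)
  q_em <- photon_integral(net_em, g_em)
  phi <- q_em / q_abs
  if (phi > 1) flags <- c(flags, "phi_above_one")
  list(phi_pl = phi, q_em = q_em, q_abs = q_abs, flags = flags)
}

check_ref <- function(E_Ref, E_D) {
  if (any(E_Ref - E_D <= 0)) {
    stop_invalid("invalid reference: indirect-illumination signal not ",
                 "above dark")
  }
}

#' Diffuse reflectance from integrating-sphere signals
#'
#' `R_d = R_Std * [(E_e - E_D)/(E_Ref - E_D)]_S *
#' [(E_Ref - E_D)/(E_e - E_D)]_Std`. The indirect (reference-beam) ratio
#' cancels the change of the sphere magnification factor between the
#' sample and standard mounts.
#'
#' @param sample,standard lists with band-integrated signals `E_e`
#'   (direct illumination), `E_Ref` (indirect illumination), `E_D`
#'   (dark); vectorised over wavelength.
#' @param R_std certified reflectance of the standard (0, 1].
#' @return diffuse reflectance (same length as the signals).
#' @export
diffuse_reflectance <- function(sample, standard, R_std) {
  if (any(R_std <= 0 | R_std > 1)) {
    stop_invalid("diffuse_reflectance: R_std must be in (0, 1]")
  }
  check_ref(sample$E_Ref, sample$E_D)
  check_ref(standard$E_Ref, standard$E_D)
  if (any(standard$E_e - standard$E_D <= 0)) {
    stop_invalid("diffuse_reflectance: standard direct signal not above ",
                 "dark")
  }
  R_std * ((sample$E_e - sample$E_D) / (sample$E_Ref - sample$E_D)) *
    ((standard$E_Ref - standard$E_D) / (standard$E_e - standard$E_D))
}

#' Total or diffuse transmittance from integrating-sphere signals
#'
#' `T = [(E_e - E_D)/(E_Ref - E_D)]_S *
#' [(E_Ref - E_D)/(E_e - E_D)]_Empty`, with the empty-sphere scan as the
#' reference mount. The same reduction serves the total and the diffuse
#' transmittance; the two differ only in the sphere configuration
#' (closed vs open reflectance port) that produced the signals.
#'
#' @param sample,empty signal lists as in [diffuse_reflectance()].
#' @return transmittance; values outside `[0, 1]` are flagged via warning.
#' @export
transmittance <- function(sample, empty) {
  check_ref(sample$E_Ref, sample$E_D)
  check_ref(empty$E_Ref, empty$E_D)
  if (any(empty$E_e - empty$E_D <= 0)) {
    stop_invalid("transmittance: empty-sphere direct signal not above ",
                 "dark")
  }
  T <- ((sample$E_e - sample$E_D) / (sample$E_Ref - sample$E_D)) *
    ((empty$E_Ref - empty$E_D) / (empty$E_e - empty$E_D))
  if (any(T < -1e-9 | T > 1 + 1e-9)) {
    warning("transmittance: values outside [0, 1]")
  }
  T
}

#' Collimated transmittance from trap-detector readings
#'
#' `T_c = (I_sample - I_dark) / (I_empty - I_dark)`. The trap detector
#' sees only the unscattered beam, avoiding the open-port losses that
#' corrupt `T_c = T_t - T_d` computed from sphere scans.
#'
#' @param I_sample,I_empty,I_dark trap readings (vectorised).
#' @return collimated transmittance.
#' @export
collimated_transmittance <- function(I_sample, I_empty, I_dark) {
  if (any(I_empty - I_dark <= 0)) {
    stop_invalid("collimated_transmittance: empty reading not above dark")
  }
  (I_sample - I_dark) / (I_empty - I_dark)
}
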