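# Synthetic-scene workbench: generates the complete raw-scan bundle of
# the measurement chain (integrating-sphere reflectance/transmittance
# scans, trap-detector readings, quantum-yield scans) from a known
# ground-truth particle model, and the pipeline driver that runs the full
# analysis back to a brightness report. Raw detector signals are built
# forward through the sphere model (lamp * responsivity * magnification,
# plus dark offset), so every reduction in the pipeline is exercised
# with its real cancellation structure (mount-dependent magnification,
# dark subtraction, gain invariance).

#' Synthetic measurement scene
#'
#' Ground truth plus instrument model for [synthesize_measurements()].
#' Defaults emulate the validation scenario of the package: a
#' quasi-monodisperse polystyrene-in-water dispersion in a 1 mm quartz
#' cell, optionally loaded with a Nile-Red-like dye (single Lorentzian
#' extinction band, center 530 nm, FWHM 60 nm, peak molar extinction
#' 5e4 L/(mol cm)).
#'
#' @param r_p_nm mean particle radius (nm).
#' @param width size-distribution coefficient of variation.
#' @param N_p_per_ml particle number concentration (1/mL).
#' @param c_dye_mol_l intra-particle dye concentration (mol/L); 0 for
#'   unstained beads.
#' @param phi_pl true photoluminescence quantum yield (ignored when
#'   `c_dye_mol_l = 0`).
#' @param dye list with `center_nm`, `fwhm_nm`, `peak_epsilon`
#'   (L mol^-1 cm^-1) describing the Lorentzian dye band.
#' @param use_kk_real_part include the Kramers-Kronig real-index
#'   increment of the dye in the ground truth (the physically complete
#'   model).
#' @param geometry a [slab_geometry()].
#' @param wavelength_nm reflectance/transmittance wavelength grid.
#' @param lambda_ex,delta_lambda excitation wavelength and
#'   half-bandwidth (nm).
#' @param emission_window `c(lo, hi)` nm, disjoint from the excitation
#'   window.
#' @param noise_cv multiplicative detector-noise coefficient of
#'   variation applied to every raw signal (0 = noise-free).
#' @return a `synthetic_scene` list.
#' @export
synthetic_scene <- function(r_p_nm = 625, width = 0.02,
                            N_p_per_ml = 1.5e9, c_dye_mol_l = 0,
                            phi_pl = 0.76,
                            dye = list(center_nm = 530, fwhm_nm = 60,
                                       peak_epsilon = 5e4),
                            use_kk_real_part = TRUE,
                            geometry = slab_geometry(1, n_slab = 1.33,
                                                     n_wall = 1.46),
                            wavelength_nm = seq(400, 800, by = 5),
                            lambda_ex = 530, delta_lambda = 10,
                            emission_window = c(560, 760),
                            noise_cv = 0) {
  if (noise_cv < 0) stop_invalid("synthetic_scene: noise_cv must be >= 0")
  if (c_dye_mol_l < 0) {
    stop_invalid("synthetic_scene: c_dye_mol_l must be >= 0")
  }
  structure(list(
    r_p_nm = r_p_nm, width = width, N_p_per_ml = N_p_per_ml,
    c_dye_mol_l = c_dye_mol_l,
    phi_pl = if (c_dye_mol_l > 0) phi_pl else 0,
    dye = dye, use_kk_real_part = use_kk_real_part,
    geometry = geometry, wavelength_nm = wavelength_nm,
    lambda_ex = lambda_ex, delta_lambda = delta_lambda,
    emission_window = emission_window, noise_cv = noise_cv
  ), class = "synthetic_scene")
}

# Lorentzian molar-extinction spectrum of the scene's dye
scene_epsilon <- function(scene, wavelength_nm = seq(300, 800, 0.5)) {
  hw <- scene$dye$fwhm_nm / 2
  spectrum(wavelength_nm,
           scene$dye$peak_epsilon * hw^2 /
             ((wavelength_nm - scene$dye$center_nm)^2 + hw^2),
           quantity = "epsilon_L_per_mol_cm")
}

# ground-truth particle model of a scene (with or without the KK term)
scene_particle <- function(scene) {
  if (scene$c_dye_mol_l > 0) {
    eps <- scene_epsilon(scene)
    gam <- gamma_increment(eps)
    band <- range(eps$wavelength_nm)
    n2 <- spectrum(gam$wavelength_nm, scene$c_dye_mol_l * gam$value)
    n1i <- if (scene$use_kk_real_part) {
      alp <- alpha_increment(gam, band, step_out = 1,
                             lambda_out = scene$wavelength_nm,
                             extrapolate = TRUE)
      spectrum(alp$wavelength_nm, scene$c_dye_mol_l * alp$value)
    } else {
      0
    }
    particle_model(scene$r_p_nm, scene$N_p_per_ml, width = scene$width,
                   n2 = n2, n1_increment = n1i)
  } else {
    particle_model(scene$r_p_nm, scene$N_p_per_ml, width = scene$width)
  }
}

#' Synthesize a full raw-scan bundle from a scene
#'
#' Runs the physics forward -- Mie cross sections, bulk coefficients,
#' adding-doubling slab observables, sphere magnification and detector
#' model -- and emits the complete set of raw scans the pipeline needs:
#' reflectance scans for sample and reflectance standard (direct,
#' indirect, dark), transmittance scans for sample and empty sphere in
#' the closed- and open-port configurations, trap-detector readings,
#' and sample/blank quantum-yield scans with the spectral responsivity.
#' Deterministic for a fixed seed.
#'
#' @param scene a [synthetic_scene()].
#' @param seed integer seed for the detector-noise generator.
#' @return a `scan_bundle` list with elements `scans` (named list of
#'   [spectrum()] objects), `config` (reduction/fit parameters incl. the
#'   dye extinction spectrum and dissolution photometry), and `truth`.
#' @export
synthesize_measurements <- function(scene, seed = 1L) {
  stopifnot(inherits(scene, "synthetic_scene"))
  set.seed(as.integer(seed))
  wl <- scene$wavelength_nm
  truth_particle <- scene_particle(scene)
  bo <- bulk_optics_from_particles(truth_particle, wl)
  tau_max <- max((bo$mu_a_per_mm + bo$mu_s_per_mm)) *
    scene$geometry$thickness_mm
  if (tau_max > 1e3) {
    stop("synthesize_measurements: infeasible scene, optical ",
         "thickness ", signif(tau_max, 4), " exceeds the solver guard",
         call. = FALSE)
  }
  slab <- vapply(seq_along(wl), function(i) {
    r <- forward_slab(bo$mu_a_per_mm[i], bo$mu_s_per_mm[i], bo$g[i],
                      scene$geometry)
    c(r$R_d, r$T_t, r$T_c, r$T_d)
  }, numeric(4))
  R_d <- slab[1, ]; T_t <- slab[2, ]; T_c <- slab[3, ]; T_d <- slab[4, ]

  # instrument model ------------------------------------------------
  lamp <- 1e6 * exp(-((wl - 560) / 250)^2)
  lamp_ref <- 0.3 * 1e6
  resp <- function(l) 0.8 + 0.4 * exp(-((l - 600) / 300)^2)
  dark <- 50
  sph_sample <- sphere_config(rho_S = 0.97, ports = list(
    list(f = 0.02, rho = 0), list(f = 0.01, rho = 0.5)))
  sph_std <- sphere_config(rho_S = 0.97, ports = list(
    list(f = 0.02, rho = 0)))
  sph_open <- sphere_config(rho_S = 0.97, ports = list(
    list(f = 0.02, rho = 0), list(f = 0.05, rho = 0)))
  M_S <- magnification(sph_sample, wl)
  M_Std <- magnification(sph_std, wl)
  M_open <- magnification(sph_open, wl)
  R_std <- rep(0.98, length(wl))
  nz <- function(v) {
    if (scene$noise_cv > 0) {
      v * (1 + scene$noise_cv * stats::rnorm(length(v)))
    } else {
      v
    }
  }
  sp <- function(values) spectrum(wl, nz(values))
  s_wl <- resp(wl)
  scans <- list(
    refl_sample_direct    = sp(dark + lamp * s_wl * M_S * R_d),
    refl_sample_indirect  = sp(dark + lamp_ref * s_wl * M_S),
    refl_std_direct       = sp(dark + lamp * s_wl * M_Std * R_std),
    refl_std_indirect     = sp(dark + lamp_ref * s_wl * M_Std),
    refl_dark             = sp(rep(dark, length(wl))),
    trans_sample_direct   = sp(dark + lamp * s_wl * M_Std * T_t),
    trans_sample_indirect = sp(dark + lamp_ref * s_wl * M_Std),
    trans_empty_direct    = sp(dark + lamp * s_wl * M_S),
    trans_empty_indirect  = sp(dark + lamp_ref * s_wl * M_S),
    trans_dark            = sp(rep(dark, length(wl))),
    tdiff_sample_direct   = sp(dark + lamp * s_wl * M_open * T_d),
    tdiff_sample_indirect = sp(dark + lamp_ref * s_wl * M_open),
    tdiff_empty_direct    = sp(dark + lamp * s_wl * M_open),
    tdiff_empty_indirect  = sp(dark + lamp_ref * s_wl * M_open),
    tdiff_dark            = sp(rep(dark, length(wl))),
    trap_sample           = sp(20 + 2000 * lamp / 1e6 * T_c),
    trap_empty            = sp(20 + 2000 * lamp / 1e6),
    trap_dark             = sp(rep(20, length(wl)))
  )

  # quantum-yield scans on a fine grid ------------------------------
  qy_wl <- seq(min(wl, scene$lambda_ex - scene$delta_lambda) - 50,
               max(wl, scene$emission_window[2]) + 50, by = 1)
  line <- exp(-(qy_wl - scene$lambda_ex)^2 /
                (2 * (scene$delta_lambda / 2.5)^2))
  A_abs <- stats::approx(wl, pmax(1 - R_d - T_t, 0), xout = qy_wl,
                         rule = 2)$y
  qp_b <- 1e5 * line
  qp_x_ex <- qp_b * (1 - A_abs)
  # absorbed flux within the reduction's excitation window, so that the
  # emitted flux is consistent with what the reduction will integrate
  in_ex <- qy_wl >= scene$lambda_ex - scene$delta_lambda &
    qy_wl <= scene$lambda_ex + scene$delta_lambda
  q_abs <- trapz_(qy_wl[in_ex], (qp_b - qp_x_ex)[in_ex])
  em_shape <- exp(-(qy_wl - 640)^2 / (2 * 25^2))
  em_shape[qy_wl < scene$emission_window[1] |
             qy_wl > scene$emission_window[2]] <- 0
  qp_em <- if (scene$phi_pl > 0 && q_abs > 0) {
    scene$phi_pl * q_abs * em_shape / trapz_(qy_wl, em_shape)
  } else {
    rep(0, length(qy_wl))
  }
  s_qy <- resp(qy_wl)
  I_b <- s_qy * qp_b / qy_wl
  I_x <- s_qy * (qp_x_ex + qp_em) / qy_wl
  scans$qy_sample <- spectrum(qy_wl, nz(I_x))
  scans$qy_blank <- spectrum(qy_wl, nz(I_b))
  scans$responsivity <- spectrum(qy_wl, s_qy)

  # dissolution photometry of the dye loading -----------------------
  dissolution <- NULL
  if (scene$c_dye_mol_l > 0) {
    v_particle_m3 <- 4 / 3 * pi * (scene$r_p_nm * 1e-9)^3
    ps_mass_mg <- 3
    rho <- 1050
    n_particles <- ps_mass_mg * 1e-6 / (rho * v_particle_m3)
    moles <- scene$c_dye_mol_l * n_particles * v_particle_m3 * 1e3
    volume_l <- 1e-3
    eps_solvent <- scene$dye$peak_epsilon
    dissolution <- list(
      absorbance = moles / volume_l * eps_solvent,
      epsilon_solvent = eps_solvent,
      volume_l = volume_l, ps_mass_mg = ps_mass_mg
    )
  }

  truth <- list(
    r_p_nm = scene$r_p_nm, width = scene$width,
    N_p_per_ml = scene$N_p_per_ml, c_dye_mol_l = scene$c_dye_mol_l,
    phi_pl = scene$phi_pl,
    n2_peak = if (scene$c_dye_mol_l > 0) {
      max(scene$c_dye_mol_l *
            interp_spectrum(gamma_increment(scene_epsilon(scene)), wl))
    } else {
      0
    },
    bulk_optics = bo,
    slab = data.frame(wavelength_nm = wl, R_d = R_d, T_t = T_t,
                      T_c = T_c, T_d = T_d)
  )
  structure(list(
    scans = scans,
    config = list(
      lambda_ex = scene$lambda_ex, delta_lambda = scene$delta_lambda,
      emission_window = scene$emission_window,
      R_std = spectrum(wl, R_std),
      geometry = scene$geometry,
      epsilon = if (scene$c_dye_mol_l > 0) scene_epsilon(scene),
      use_kk_real_part = scene$use_kk_real_part,
      dissolution = dissolution,
      seed = as.integer(seed)
    ),
    truth = truth
  ), class = "scan_bundle")
}

reduce_signals <- function(scans, prefix) {
  list(E_e = scans[[paste0(prefix, "_direct")]]$value,
       E_Ref = scans[[paste0(prefix, "_indirect")]]$value,
       E_D = scans[[paste0(sub("_(sample|std|empty)$", "", prefix),
                           "_dark")]]$value)
}

#' Reduce a raw-scan bundle to the physical observables
#'
#' Applies the sphere reductions to a bundle from
#' [synthesize_measurements()] (or read from disk): quantum yield,
#' diffuse reflectance, total and diffuse transmittance, and collimated
#' transmittance (trap detector if present, otherwise the
#' `T_t - T_d` fallback with a warning about open-port losses).
#'
#' @param bundle a `scan_bundle`.
#' @return list with `phi` (from [quantum_yield()]) and `measurement`
#'   (a [slab_measurement()]).
#' @export
reduce_bundle <- function(bundle) {
  scans <- bundle$scans
  cfg <- bundle$config
  scan <- qy_scan(scans$qy_sample, scans$qy_blank, scans$responsivity,
                  cfg$lambda_ex, cfg$delta_lambda, cfg$emission_window)
  phi <- tryCatch(quantum_yield(scan), error = function(e) {
    if (!grepl("no absorption", conditionMessage(e))) stop(e)
    # non-absorbing sample (e.g. unstained beads): Phi_pl is 0 by
    # definition, there is nothing to excite
    list(phi_pl = 0, q_em = 0, q_abs = 0, flags = "no_absorption")
  })
  wl <- scans$refl_sample_direct$wavelength_nm
  R_d <- diffuse_reflectance(
    sample = reduce_signals(scans, "refl_sample"),
    standard = reduce_signals(scans, "refl_std"),
    R_std = interp_spectrum(cfg$R_std, wl, rule = 2))
  T_t <- transmittance(sample = reduce_signals(scans, "trans_sample"),
                       empty = reduce_signals(scans, "trans_empty"))
  T_d <- transmittance(sample = reduce_signals(scans, "tdiff_sample"),
                       empty = reduce_signals(scans, "tdiff_empty"))
  if (!is.null(scans$trap_sample)) {
    T_c <- collimated_transmittance(scans$trap_sample$value,
                                    scans$trap_empty$value,
                                    scans$trap_dark$value)
  } else {
    warning("reduce_bundle: no trap scans; falling back to ",
            "T_c = T_t - T_d, which is biased by open-port losses")
    T_c <- T_t - T_d
  }
  eps_c <- 1e-12
  meas <- slab_measurement(
    R_d = spectrum(wl, pmin(pmax(R_d, eps_c), 1)),
    T_t = spectrum(wl, pmin(pmax(T_t, eps_c), 1)),
    T_c = spectrum(wl, pmin(pmax(T_c, eps_c), 1)),
    T_d = spectrum(wl, pmin(pmax(T_d, 0), 1)),
    geometry = cfg$geometry,
    tol = 0.1)   # noisy scans: flag only gross T_t vs T_d + T_c breaks
  list(phi = phi, measurement = meas)
}

#' Run the full analysis pipeline on a scan bundle
#'
#' Chains the complete workflow: sphere reductions (quantum yield,
#' `R_d`, `T_t`, `T_d`, `T_c`), per-wavelength inverse adding-doubling
#' (`mu_a`, `mu_s`, `g`), the Mie particle fit (`N_p`, `r_p`, width,
#' `n2`), and the brightness report (`sigma_a`, `Q_abs`, `B`, `LE`,
#' dye loading when dissolution photometry is available).
#'
#' @param bundle a `scan_bundle` (from [synthesize_measurements()] or
#'   [read_bundle()]).
#' @param use_kk_real_part override the bundle's Kramers-Kronig fit
#'   setting (default: take it from the bundle config).
#' @param r_init optional radius seed forwarded to [fit_particles()].
#' @param quiet suppress progress messages.
#' @return list with `phi`, `measurement`, `optics`, `fit`, `report`,
#'   and `provenance`.
#' @export
run_pipeline <- function(bundle, use_kk_real_part = NULL, r_init = NULL,
                         quiet = TRUE) {
  stopifnot(inherits(bundle, "scan_bundle") || is.list(bundle))
  cfg <- bundle$config
  say <- function(...) if (!quiet) message(...)
  stage <- "reduction"
  out <- tryCatch({
    say("reducing raw scans")
    red <- reduce_bundle(bundle)
    stage <- "radiation-transport inversion"
    say("inverting the radiation transport per wavelength")
    optics <- invert_spectrum(red$measurement)
    stage <- "Mie particle fit"
    say("fitting Mie theory")
    use_kk <- if (is.null(use_kk_real_part)) {
      isTRUE(cfg$use_kk_real_part)
    } else {
      use_kk_real_part
    }
    dye_gamma <- if (!is.null(cfg$epsilon)) gamma_increment(cfg$epsilon)
    fit <- fit_particles(optics, dye_gamma = dye_gamma,
                         use_kk_real_part = use_kk && !is.null(dye_gamma),
                         kk_band = if (!is.null(cfg$epsilon)) {
                           range(cfg$epsilon$wavelength_nm)
                         },
                         r_init = r_init)
    stage <- "brightness report"
    mu_a_ex <- stats::approx(optics$wavelength_nm, optics$mu_a_per_mm,
                             xout = cfg$lambda_ex, rule = 2)$y
    N_dye <- NA_real_
    if (!is.null(cfg$dissolution)) {
      dl <- dye_loading(cfg$dissolution$absorbance,
                        cfg$dissolution$epsilon_solvent,
                        cfg$dissolution$volume_l,
                        cfg$dissolution$ps_mass_mg,
                        fit$particle$r_p_nm)
      N_dye <- dl$N_dye
    }
    eps_ex <- if (!is.null(cfg$epsilon)) {
      interp_spectrum(cfg$epsilon, cfg$lambda_ex, rule = 2)
    } else {
      NA_real_
    }
    report <- brightness_report(fit$particle, red$phi$phi_pl,
                                cfg$lambda_ex, mu_a_ex = mu_a_ex,
                                N_dye = N_dye, epsilon_ex = eps_ex)
    list(phi = red$phi, measurement = red$measurement, optics = optics,
         fit = fit, report = report,
         provenance = list(
           package_version = tryCatch(
             as.character(utils::packageVersion("lumisphere")),
             error = function(e) "dev"),
           seed = cfg$seed,
           use_kk_real_part = use_kk,
           timestamp = format(Sys.time(), tz = "UTC")
         ))
  }, error = function(e) {
    stop("run_pipeline: failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  out
}

#' Write / read a scan bundle as CSV + YAML
#'
#' Each scan becomes a two-column CSV named `<role>.csv`; the reduction
#' parameters go to `config.yaml`. [read_bundle()] restores the bundle
#' (without the `truth` record, which is measurement-side only).
#'
#' @param bundle a `scan_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir` (write) or a `scan_bundle` (read).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (role in names(bundle$scans)) {
    write_spectrum(bundle$scans[[role]], file.path(dir,
                                                   paste0(role, ".csv")))
  }
  cfg <- bundle$config
  ycfg <- list(
    lambda_ex = cfg$lambda_ex, delta_lambda = cfg$delta_lambda,
    emission_window = cfg$emission_window,
    geometry = list(thickness_mm = cfg$geometry$thickness_mm,
                    n_slab = cfg$geometry$n_slab,
                    n_wall = cfg$geometry$n_wall,
                    n_outside = cfg$geometry$n_outside),
    use_kk_real_part = isTRUE(cfg$use_kk_real_part),
    dissolution = cfg$dissolution,
    seed = cfg$seed
  )
  yaml::write_yaml(ycfg, file.path(dir, "config.yaml"))
  write_spectrum(cfg$R_std, file.path(dir, "r_std_certificate.csv"))
  if (!is.null(cfg$epsilon)) {
    write_spectrum(cfg$epsilon, file.path(dir, "dye_epsilon.csv"),
                   value_name = "epsilon_L_per_mol_cm")
  }
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  cfgy <- yaml::read_yaml(file.path(dir, "config.yaml"))
  roles <- sub("\\.csv$", "",
               list.files(dir, pattern = "\\.csv$"))
  roles <- setdiff(roles, c("r_std_certificate", "dye_epsilon"))
  scans <- lapply(roles, function(r) {
    read_spectrum(file.path(dir, paste0(r, ".csv")))
  })
  names(scans) <- roles
  cfg <- list(
    lambda_ex = cfgy$lambda_ex, delta_lambda = cfgy$delta_lambda,
    emission_window = unlist(cfgy$emission_window),
    R_std = read_spectrum(file.path(dir, "r_std_certificate.csv")),
    geometry = slab_geometry(cfgy$geometry$thickness_mm,
                             cfgy$geometry$n_slab,
                             cfgy$geometry$n_wall,
                             cfgy$geometry$n_outside),
    epsilon = if (file.exists(file.path(dir, "dye_epsilon.csv"))) {
      read_spectrum(file.path(dir, "dye_epsilon.csv"))
    },
    use_kk_real_part = isTRUE(cfgy$use_kk_real_part),
    dissolution = cfgy$dissolution,
    seed = cfgy$seed
  )
  structure(list(scans = scans, config = cfg, truth = NULL),
            class = "scan_bundle")
}
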