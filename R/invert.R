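# Inverse adding-doubling: recover (mu_a, mu_s, g) of a slab from the
# measured triple (R_d, T_t, T_c). The measurement structure makes the
# problem nearly separable: T_c pins the total attenuation
# tau = (mu_a + mu_s) d in closed form (Beer-Lambert with incoherent
# window reflections), leaving a 2-D solve for the single-scattering
# albedo and the anisotropy factor against (R_d, T_t).

#' Slab measurement container
#'
#' @param R_d,T_t,T_c [spectrum()] objects on one common wavelength grid:
#'   diffuse reflectance (with specular term), total and collimated
#'   transmittance. `T_d` is optional (diffuse transmittance).
#' @param geometry a [slab_geometry()].
#' @param T_d optional diffuse-transmittance spectrum; checked against
#'   `T_t = T_d + T_c` when present.
#' @param tol consistency tolerance for the checks.
#' @return a `slab_measurement` list.
#' @export
slab_measurement <- function(R_d, T_t, T_c, geometry, T_d = NULL,
                             tol = 0.02) {
  stopifnot(is_spectrum(R_d), is_spectrum(T_t), is_spectrum(T_c),
            inherits(geometry, "slab_geometry"))
  wl <- R_d$wavelength_nm
  same <- function(s) length(s$wavelength_nm) == length(wl) &&
    all(abs(s$wavelength_nm - wl) < 1e-9)
  if (!same(T_t) || !same(T_c) || (!is.null(T_d) && !same(T_d))) {
    stop_invalid("slab_measurement: spectra are not on a common ",
                 "wavelength grid")
  }
  rng_ok <- function(s) all(s$value >= -1e-12 & s$value <= 1 + 1e-9)
  if (!rng_ok(R_d) || !rng_ok(T_t) || !rng_ok(T_c)) {
    stop_invalid("slab_measurement: values outside [0, 1]")
  }
  if (any(T_c$value > T_t$value + tol)) {
    stop_invalid("slab_measurement: T_c exceeds T_t")
  }
  if (!is.null(T_d) && any(abs(T_d$value + T_c$value - T_t$value) > tol)) {
    stop_invalid("slab_measurement: T_t != T_d + T_c beyond tolerance")
  }
  structure(list(R_d = R_d, T_t = T_t, T_c = T_c, T_d = T_d,
                 geometry = geometry), class = "slab_measurement")
}

# closed-form tau from collimated transmittance through two identical
# composite windows: T_c = (1-r)^2 t / (1 - r^2 t^2), t = exp(-tau)
tau_from_tc <- function(T_c, geometry) {
  rb <- boundary_reflectance(1, geometry$n_slab, geometry$n_wall,
                             geometry$n_outside)
  if (T_c <= 0) stop_invalid("tau_from_tc: T_c must be > 0")
  t <- if (rb > 0) {
    (-(1 - rb)^2 + sqrt((1 - rb)^4 + 4 * T_c^2 * rb^2)) /
      (2 * T_c * rb^2)
  } else {
    T_c
  }
  if (t <= 0 || t > 1 + 1e-9) {
    stop_invalid("tau_from_tc: T_c inconsistent with window reflectance")
  }
  -log(min(t, 1))
}

#' Invert one wavelength: (R_d, T_t, T_c) to (mu_a, mu_s, g)
#'
#' The total attenuation is obtained in closed form from `T_c`; the
#' single-scattering albedo and anisotropy are then solved from
#' `(R_d, T_t)` by a damped Newton iteration on the adding-doubling
#' forward model, seeded from a coarse grid (or a warm start).
#'
#' @param R_d,T_t,T_c measured values in (0, 1).
#' @param geometry a [slab_geometry()].
#' @param nq quadrature streams of the forward model.
#' @param tol acceptance tolerance: maximum absolute residual on each of
#'   `R_d`, `T_t` (default 1e-4).
#' @param max_iter iteration cap for the Newton polish.
#' @param init optional warm start `c(albedo, g)`.
#' @param lost_fraction optional fraction of light lost to stray
#'   scattering; `(R_d, T_t)` are rescaled by `1/(1 - lost_fraction)`
#'   before inversion (default 0, i.e. off).
#' @return list with `mu_a_per_mm`, `mu_s_per_mm`, `g`, `albedo`, `tau`,
#'   `residual` (max abs), `converged`.
#' @export
invert_slab <- function(R_d, T_t, T_c, geometry, nq = 16L, tol = 1e-4,
                        max_iter = 200L, init = NULL,
                        lost_fraction = 0) {
  stopifnot(inherits(geometry, "slab_geometry"))
  if (any(!is.finite(c(R_d, T_t, T_c))) ||
      any(c(R_d, T_t, T_c) <= 0) || any(c(R_d, T_t, T_c) >= 1)) {
    stop_invalid("invert_slab: measured values must lie in (0, 1)")
  }
  if (lost_fraction > 0) {
    R_d <- R_d / (1 - lost_fraction)
    T_t <- T_t / (1 - lost_fraction)
  }
  if (R_d + T_t > 1 + 1e-3) {
    stop_invalid("invert_slab: inconsistent measurement, R_d + T_t = ",
                 signif(R_d + T_t, 4), " > 1")
  }
  d <- geometry$thickness_mm
  tau <- tau_from_tc(T_c, geometry)
  if (tau <= 0) {
    return(list(mu_a_per_mm = 0, mu_s_per_mm = 0, g = 0, albedo = 0,
                tau = 0, residual = 0, converged = TRUE))
  }
  # unconstrained parameterization: albedo by logit, g by scaled atanh,
  # so the Newton iteration cannot stall on the a -> 1 boundary
  to_ag <- function(p) c(stats::plogis(p[1]), 0.999 * tanh(p[2]))
  from_ag <- function(a, g) {
    c(stats::qlogis(min(max(a, 1e-8), 1 - 1e-8)),
      atanh(min(max(g / 0.999, -1 + 1e-8), 1 - 1e-8)))
  }
  fwd <- function(a, g) {
    a <- min(max(a, 0), 1)
    g <- min(max(g, -0.999), 0.999)
    r <- forward_slab((1 - a) * tau / d, a * tau / d, g, geometry, nq)
    c(r$R_d - R_d, r$T_t - T_t)
  }
  fwd_p <- function(p) {
    ag <- to_ag(p)
    fwd(ag[1], ag[2])
  }
  # scattering-free shortcut: T_t indistinguishable from T_c
  r0 <- forward_slab(tau / d, 0, 0, geometry, nq)
  if (abs(r0$T_t - T_t) < tol && abs(r0$R_d - R_d) < tol) {
    return(list(mu_a_per_mm = tau / d, mu_s_per_mm = 0, g = 0,
                albedo = 0, tau = tau, residual =
                  max(abs(r0$T_t - T_t), abs(r0$R_d - R_d)),
                converged = TRUE))
  }
  seeds <- if (!is.null(init)) {
    matrix(init, ncol = 2)
  } else {
    as.matrix(expand.grid(a = c(0.3, 0.7, 0.9, 0.99),
                          g = c(0, 0.5, 0.8, 0.95)))
  }
  best <- NULL
  for (s in seq_len(nrow(seeds))) {
    p_s <- from_ag(seeds[s, 1], seeds[s, 2])
    r <- sum(fwd_p(p_s)^2)
    if (is.null(best) || r < best$r) {
      best <- list(p = p_s, r = r)
    }
  }
  p <- as.numeric(best$p)
  n_eval <- 0L
  resid <- fwd_p(p)
  repeat {
    n_eval <- n_eval + 1L
    if (max(abs(resid)) < tol * 1e-2 || n_eval > max_iter) break
    h <- 1e-5
    J <- cbind((fwd_p(p + c(h, 0)) - resid) / h,
               (fwd_p(p + c(0, h)) - resid) / h)
    step <- tryCatch(solve(J, -resid), error = function(e) NULL)
    if (is.null(step)) break
    step <- pmin(pmax(step, -3), 3)     # trust region in logit space
    lambda <- 1
    improved <- FALSE
    for (k in 1:10) {
      pn <- p + lambda * step
      rn <- fwd_p(pn)
      if (sum(rn^2) < sum(resid^2)) {
        p <- pn
        resid <- rn
        improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  if (max(abs(resid)) > tol) {
    # fallback: Nelder-Mead from the best point so far
    nm <- stats::optim(p, function(q) sum(fwd_p(q)^2),
                       method = "Nelder-Mead",
                       control = list(maxit = 500, reltol = 1e-14))
    if (nm$value < sum(resid^2)) {
      p <- nm$par
      resid <- fwd_p(p)
    }
  }
  residual <- max(abs(resid))
  if (residual > tol) {
    warning(sprintf(
      "invert_slab: no convergence to %.1e (best residual %.2e)",
      tol, residual))
  }
  ag <- to_ag(p)
  a <- ag[1]
  g <- ag[2]
  list(mu_a_per_mm = (1 - a) * tau / d, mu_s_per_mm = a * tau / d,
       g = g, albedo = a, tau = tau, residual = residual,
       converged = residual <= tol)
}

#' Invert a full slab measurement spectrum
#'
#' Per-wavelength inversion of a [slab_measurement()] with warm-starting
#' from the neighbouring wavelength.
#'
#' @param measurement a [slab_measurement()].
#' @inheritParams invert_slab
#' @return a [bulk_optics()] data.frame with an extra `residual` column.
#' @export
invert_spectrum <- function(measurement, nq = 16L, tol = 1e-4,
                            lost_fraction = 0) {
  stopifnot(inherits(measurement, "slab_measurement"))
  wl <- measurement$R_d$wavelength_nm
  n <- length(wl)
  mu_a <- mu_s <- g <- resid <- numeric(n)
  init <- NULL
  for (i in seq_len(n)) {
    fit <- tryCatch(
      invert_slab(measurement$R_d$value[i], measurement$T_t$value[i],
                  measurement$T_c$value[i], measurement$geometry,
                  nq = nq, tol = tol, init = init,
                  lost_fraction = lost_fraction),
      error = function(e) {
        stop("invert_spectrum: at ", wl[i], " nm: ",
             conditionMessage(e), call. = FALSE)
      })
    if (!is.null(init) && !fit$converged) {
      # retry cold in case the warm start trapped the solver
      fit2 <- invert_slab(measurement$R_d$value[i],
                          measurement$T_t$value[i],
                          measurement$T_c$value[i],
                          measurement$geometry, nq = nq, tol = tol,
                          lost_fraction = lost_fraction)
      if (fit2$residual < fit$residual) fit <- fit2
    }
    mu_a[i] <- fit$mu_a_per_mm
    mu_s[i] <- fit$mu_s_per_mm
    g[i] <- fit$g
    resid[i] <- fit$residual
    init <- c(fit$albedo, fit$g)
  }
  out <- bulk_optics(wl, mu_a, mu_s, g)
  out$residual <- resid
  out
}
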