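#' Monte-Carlo photon transport through a slab (validation reference)
#'
#' Independent stochastic solution of the same slab problem as
#' [forward_slab()]: collimated normal incidence, Henyey-Greenstein
#' scattering, Fresnel cuvette-wall boundaries. Used to validate the
#' adding-doubling forward model; it plays no role in any production
#' (inverse) computation. Reproducible under [set.seed()].
#'
#' @inheritParams forward_slab
#' @param n_photons number of photon packets.
#' @return list with `R_d`, `T_t` and their Monte-Carlo standard errors
#'   `R_se`, `T_se`.
#' @export
mc_slab <- function(mu_a_per_mm, mu_s_per_mm, g, geometry,
                    n_photons = 1e5) {
  stopifnot(inherits(geometry, "slab_geometry"))
  if (abs(g) >= 1) stop_invalid("mc_slab: require |g| < 1")
  mc_slab_cpp(mu_a_per_mm, mu_s_per_mm, g, geometry$thickness_mm,
              geometry$n_slab, geometry$n_wall, geometry$n_outside,
              as.integer(n_photons))
}
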