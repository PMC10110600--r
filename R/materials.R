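# Refractive-index dispersion of the stock materials of the workbench:
# water (dispersion medium), polystyrene (bead matrix), fused silica
# (cuvette walls). Standard published dispersion fits for the visible/NIR.

#' Refractive index of water
#'
#' Four-term Cauchy-type fit valid over the visible and near infrared
#' (about 400-1100 nm) at room temperature.
#'
#' @param wavelength_nm wavelength in nm (vectorised).
#' @return real refractive index.
#' @export
n_water <- function(wavelength_nm) {
  l <- wavelength_nm
  1.3199 + 6878 / l^2 - 1.132e9 / l^4 + 1.11e14 / l^6
}

#' Refractive index of polystyrene
#'
#' One-term Sellmeier fit for bulk polystyrene in the visible.
#'
#' @inheritParams n_water
#' @return real refractive index.
#' @export
n_polystyrene <- function(wavelength_nm) {
  l2 <- (wavelength_nm / 1000)^2       # micrometres squared
  sqrt(1 + 1.4435 * l2 / (l2 - 0.020216))
}

#' Refractive index of fused silica (cuvette windows)
#'
#' Malitson three-term Sellmeier equation.
#'
#' @inheritParams n_water
#' @return real refractive index.
#' @export
n_fused_silica <- function(wavelength_nm) {
  l2 <- (wavelength_nm / 1000)^2
  sqrt(1 +
    0.6961663 * l2 / (l2 - 0.0684043^2) +
    0.4079426 * l2 / (l2 - 0.1162414^2) +
    0.8974794 * l2 / (l2 - 9.896161^2))
}
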