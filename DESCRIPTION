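Package: lumisphere
Title: Brightness and Luminescence Efficiency of Scattering Luminescent
    Particle Dispersions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assigns an absolute brightness (B = sigma_a * Phi_pl) and a
    unitless luminescence efficiency (LE = Q_abs * Phi_pl) to
    light-scattering dispersions of luminescent particles such as dye-loaded
    polystyrene beads. Covers the full chain from integrating-sphere raw
    spectra (absolute photoluminescence quantum yield, diffuse reflectance,
    total/diffuse/collimated transmittance) through inverse adding-doubling
    radiation transport (absorption and scattering coefficients, scattering
    anisotropy), Lorenz-Mie fitting of particle radius, size-distribution
    width, number concentration and imaginary refractive index, and
    Kramers-Kronig modelling of the dye contribution to the complex
    refractive index. Includes a seeded synthetic-scene workbench emulating
    the complete measurement chain and a Monte-Carlo photon-transport
    reference solver for validating the adding-doubling model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    minpack.lm,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
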