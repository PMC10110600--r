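# lumisphere

Absolute brightness and luminescence efficiency of light-scattering
dispersions of luminescent particles, from integrating-sphere
spectroscopy.

Fluorescent calibration beads are usually assigned *relative*
intensities (MESF/ERF scales: "equivalent fluorophore molecules"). An
absolute alternative characterizes each particle by two measurable
quantities: the absorption cross section at the excitation wavelength,
σ_a(λ_ex), and the photoluminescence quantum yield, Φ_pl. Their product
is the particle **brightness**

    B = σ_a(λ_ex) · Φ_pl        [cm²]

and, normalized by the geometric cross section π r_p², the unitless,
size-independent **luminescence efficiency**

    LE = Q_abs · Φ_pl,   Q_abs = σ_a / (π r_p²).

Neither factor is directly observable for a scattering dispersion.
`lumisphere` implements the full inference chain:

| stage | in → out | method |
|---|---|---|
| sphere reduction | raw detector scans → Φ_pl, R_d, T_t, T_d, T_c | magnification-cancelling ratio reductions; photon-weighted quantum-yield integrals |
| radiation transport | (R_d, T_t, T_c) per λ → μ_a, μ_s, g | adding-doubling forward model (Henyey–Greenstein, Fresnel cuvette walls), closed-form τ from T_c, 2-D Newton inverse |
| particle fit | μ_s, g, μ_a spectra → r_p, width, N_p, n2(λ) | polydisperse Lorenz–Mie least squares, N_p profiled analytically |
| dye index model | ε(λ) → γ̃(λ), α̃(λ) | finite-band principal-value Kramers–Kronig transform, n = n_matrix + c_dye(α̃ + iγ̃) |
| report | → σ_a, Q_abs, B, LE, N_dye | σ_a = μ_a/N_p cross-checked against the direct Mie route |

A first-class synthetic workbench (`synthetic_scene()`,
`synthesize_measurements()`) generates complete raw-scan bundles from
known ground truth — Mie → transport → sphere signal model, with seeded
detector noise — and a compiled Monte-Carlo photon-transport solver
(`mc_slab()`) independently validates the adding-doubling model.

## Worked example

Synthesize a dye-loaded 1 µm polystyrene-in-water dispersion
(Nile-Red-like band, intra-particle concentration 0.02 mol/L,
Φ_pl = 0.76) and run the whole chain back to a brightness report:

```r
library(lumisphere)

scene  <- synthetic_scene(r_p_nm = 500, N_p_per_ml = 2.5e9,
                          c_dye_mol_l = 0.02, phi_pl = 0.76)
bundle <- synthesize_measurements(scene, seed = 42)
result <- run_pipeline(bundle)
print(result$report)
#> Brightness report
#>   excitation            530 nm
#>   sigma_a               1.519e-09 cm^2
#>   Q_abs                 0.1932
#>   Phi_pl                0.76
#>   B  = sigma_a * Phi    1.154e-09 cm^2
#>   LE = Q_abs * Phi      0.1468
#>   N_dye                 6.314e+06 per particle
#>   B_molecular           2.399e+11 L/(mol cm)
```

Reading the numbers: each bead presents an absorbing area of
1.5×10⁻⁹ cm² to 530 nm light — about 19 % of its geometric cross
section (`Q_abs`) — and re-emits 76 % of what it absorbs, so ~15 % of
the photons incident on the particle's silhouette come back as
fluorescence (`LE`). The fit recovered the ground truth radius to
0.04 % (500.2 nm) and the number concentration to 0.1 %; the dissolved
6.3 million dye molecules per particle give the molecular-brightness
approximation shown on the familiar L mol⁻¹ cm⁻¹ scale.

The same chain is scriptable from a shell:

```sh
Rscript inst/scripts/lumisphere synthesize --out bundle --seed 42 --dyed
Rscript inst/scripts/lumisphere pipeline --bundle bundle --out out
```

## Layout

```
R/                  implementation (Mie core, adding-doubling + inverse,
                    sphere reductions, Kramers-Kronig, particle fit,
                    synthetic workbench)
src/                Monte-Carlo photon-transport reference (Rcpp)
tests/testthat/     unit, property and acceptance suites
scripts/            acceptance.R
vignettes/          methods vignette: models, assumptions, numerics
inst/scripts/       command-line driver
```
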