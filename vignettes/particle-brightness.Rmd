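---
title: "From integrating-sphere scans to particle brightness: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From integrating-sphere scans to particle brightness: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Dispersions of dye-loaded polystyrene beads are the workhorse calibrants
of flow cytometry and quantitative fluorescence imaging, but the
intensity scales in routine use (MESF, ERF) are *relative*: a bead is
assigned the intensity of an equivalent fluorophore solution. An
*absolute* alternative assigns each particle a brightness

$$B = \sigma_a(\lambda_{ex})\,\Phi_{pl} \qquad [\mathrm{cm^2}]$$

the product of its absorption cross section at the excitation
wavelength and its photoluminescence quantum yield, and a unitless,
size-independent luminescence efficiency

$$LE = Q_{abs}\,\Phi_{pl}, \qquad Q_{abs} = \frac{\sigma_a}{\pi r_p^2}.$$

Both factors are measurable with one integrating-sphere setup — but only
through a chain of inferences, because the beads scatter strongly:
nothing in a raw transmission spectrum is directly an absorption cross
section. `lumisphere` implements that chain end to end:

1. **Sphere reductions** turn raw detector scans into the absolute
   quantum yield $\Phi_{pl}$, the diffuse reflectance $R_d$, the total
   and diffuse transmittance $T_t$, $T_d$, and the collimated
   transmittance $T_c$ (trap detector).
2. **Inverse adding-doubling** turns $(R_d, T_t, T_c)$ per wavelength
   into the bulk coefficients $(\mu_a, \mu_s, g)$ of the dispersion.
3. **A Mie least-squares fit** turns $\mu_s(\lambda)$, $g(\lambda)$ and
   $\mu_a(\lambda)$ into single-particle properties: mean radius
   $r_p$, size-distribution width, number concentration $N_p$, and the
   imaginary refractive index $n_2(\lambda)$ of the dye-loaded matrix.
4. **Kramers–Kronig modelling** links the dye's extinction spectrum to
   its contribution to the complex refractive index,
   $n = n^{matrix} + c^{dye}(\tilde\alpha + i\tilde\gamma)$.
5. The **report** assembles $\sigma_a = \mu_a/N_p$, $Q_{abs}$, $B$ and
   $LE$.

# Models and numerical choices

## Lorenz–Mie core

Scattering coefficients $a_n, b_n$ follow the Bohren–Huffman
formulation: the logarithmic derivative $D_n(y)$ of the Riccati–Bessel
function at the (complex) internal argument $y = mx$ is generated by
downward recurrence, $\psi_n$ and $\zeta_n = \psi_n - i\chi_n$ at the
real size parameter $x$ by upward recurrence. This split is what makes
absorbing spheres stable up to $x$ of a few thousand. The series is
truncated at the Wiscombe order $x + 4.05x^{1/3} + 2$. The suite checks
the implementation against Rayleigh-limit closed forms, the extinction
paradox ($Q_{ext}\to 2$), energy conservation over random draws, and an
independently coded series that evaluates the coefficient formulas
directly from power-series Riccati–Bessel functions.

Polydispersity is handled by number-weighted averaging over a 64-node
Gauss–Legendre quadrature spanning ±4 distribution widths; the
asymmetry factor is weighted by the scattering cross section. Lognormal
is the default family (a normal family is provided; the lognormal
cannot produce negative radii and matches how bead polydispersity is
usually reported). Widths up to ~20 % are resolved; the quadrature is
verified against a 10⁴-point brute-force average.

All internal lengths are nm and cross sections nm²; conversion to cm²
happens once, at the reporting layer.

## Slab radiation transport

The forward model computes $(R_d, T_t, T_c)$ of a plane-parallel
cuvette under collimated normal incidence. Discretization is discrete
ordinates in the angle cosine with a composite quadrature: Gauss nodes
below the critical cosine of total internal reflection, right-Radau
nodes above it so that $\mu = 1$ is an exact node carrying the
collimated beam. 16 streams are the default; with delta-M scaling
(forward-peak fraction $f = g^M$ treated as unscattered) this resolves
Henyey–Greenstein anisotropies up to $g \approx 0.95$. The
reflection/transmission operators of a moderate-thickness starter layer
come from the matrix exponential of the discrete-ordinates generator —
exact for the discretized problem, with no thin-layer truncation error —
and are then doubled to the full optical thickness; doubling on the
operator level is unconditionally stable, which matters because the
matrix exponential alone would overflow for optical depths beyond
$\sim\mu_{min}^{-1}$. Cuvette windows enter as diagonal Fresnel
operators for a medium|glass|air stack with incoherent wall
reflections; $R_d$ therefore includes the specular first-surface term,
as measured. $T_c$ is evaluated analytically (Beer–Lambert with
multiple window reflections) using the *unscaled* extinction, because a
trap detector does not accept the near-forward scattered light that
delta-M folds into its collimated channel.

The forward model is validated against an independent Monte-Carlo
photon-transport solver (`mc_slab()`, compiled code, weight tracking
with Russian roulette) to within 0.005 absolute on a 27-case grid
spanning $\mu_a \in \{0, 0.1, 1\}$/mm, $\mu_s \in \{0.1, 1, 10\}$/mm,
$g \in \{0, 0.7, 0.95\}$. The Monte-Carlo solver is validation-only; no
production path uses it.

The inverse exploits the measurement structure instead of a blind 3-D
search: $T_c$ fixes the total attenuation $\tau = (\mu_a + \mu_s)d$ in
closed form; the albedo and $g$ are then solved from $(R_d, T_t)$ by a
damped Newton iteration in logit/atanh coordinates (so the iteration
cannot stall at the $a \to 1$ boundary of weakly absorbing samples),
seeded from a coarse grid or warm-started from the neighbouring
wavelength. Acceptance: $10^{-4}$ absolute per observable, iteration
cap 200, Nelder–Mead fallback. Measurements with $R_d + T_t > 1$ are
rejected as inconsistent; an optional `lost_fraction` rescales
$(R_d, T_t)$ before inversion to make stray scattering losses (a
percent-level effect in real spheres) explicit rather than implicit.
The fluorescence source term of the transport equation never enters:
the reductions are excitation-band-integrated, so emitted photons are
spectrally separated before inversion.

## Sphere reductions

The quantum yield is the ratio of photon fluxes
$\Phi_{pl} = N_{em}/N_{abs}$, with both integrals
responsivity-corrected and photon-weighted ($\cdot\lambda$);
reflectance and transmittance are dark-corrected ratio reductions in
which an indirect-illumination reference beam cancels the
mount-dependent sphere magnification $M = \rho_0/(1-\bar\rho)$. Band
integrals use the trapezoidal rule on the native grid with the window
endpoints included exactly. Three policies are worth stating:

* the quotient is emitted-over-absorbed (values > 1 are flagged, not
  errored — resonant `Q_abs` can legitimately exceed 1, measurement
  noise cannot be silently truncated);
* spectra whose excitation and emission windows overlap are rejected
  outright — apportioning overlapping bands needs a reabsorption model
  the data cannot constrain;
* negative net emission after blank subtraction is clipped at zero
  (noise floor) with a warning, and only for the emission integral.

## Kramers–Kronig dye model

The imaginary increment follows the extinction spectrum directly,
$\tilde\gamma(\lambda) = (\ln 10 / 4\pi)\,\varepsilon(\lambda)\lambda$
(λ in cm, $\tilde\gamma$ in L/mol). The real increment is the
principal-value transform over a finite band $[\lambda_a, \lambda_b]$
on a 0.5 nm working grid, downsampled (default 5 nm) for Mie work. The
principal value is evaluated by singularity subtraction: the regular
part $(\tilde\gamma(\Lambda) - \tilde\gamma(\lambda))K(\lambda,\Lambda)$
is integrated by the trapezoidal rule and the kernel's own principal
value is added in closed form. We chose this over alternating-node
(Maclaurin-type) schemes after measuring that those lose their parity
error cancellation when $\tilde\gamma$ is nonzero at the band edges —
exactly the situation for Lorentzian dye bands with visible tails — while
the subtraction scheme matches an adaptive-quadrature reference to
$10^{-7}$ and changes by under 0.05 % of peak on grid halving (interior
points; the finite-band transform is genuinely singular *at* the band
edges, and values there are reported but not trusted). Only the band's
own contribution is reported; a user-supplied baseline can represent
out-of-band dispersion terms.

## The particle fit

The fit is staged rather than jointly nonlinear:

* $N_p$ enters $\mu = N_p\sigma$ linearly and is profiled out in closed
  form at every trial shape;
* $(r_p, \text{width})$ — the parameters that set Mie resonance
  positions and contrast — are fitted to $\mu_s(\lambda)$ (relative
  residuals) and $g(\lambda)$ (absolute residuals) by
  Levenberg–Marquardt, seeded by a coarse log-spaced radius scan;
* $n_2$ is recovered from $\mu_a(\lambda)$ either as a single scale on
  a known dye band shape (default when an extinction spectrum is
  available) or per wavelength (the map $\sigma_a(n_2)$ is monotone and
  near-linear at these loadings); with the Kramers–Kronig option the
  consistent $\tilde\alpha$ contribution enters $n_1$;
* the stages alternate (twice by default) because $n_2$ feeds back
  weakly into $\mu_s$.

Relative weighting on $\mu_s$ and $\mu_a$ with absolute weighting on
$g$ reflects their dynamic ranges; the weighting is a documented choice,
as is the residual-based tie-break of the multi-start. A dispersion
whose $\mu_s(\lambda)$ shows no resonance structure (contrast of
log $\mu_s$ about a quadratic trend below 1 %) cannot constrain both
$r_p$ and $N_p$; the fit then refuses to run without a user-supplied
radius, which mirrors how such samples must be handled in practice
(size from DLS/TEM, concentration from the fit). For very small
particles the scattering signal disappears entirely and the
molecular-brightness route
($N_{dye}\,\varepsilon(\lambda_{ex})\,\Phi_{pl}$, from dissolution
photometry) is the appropriate scale.

$B$ is reported in cm². $LE = Q_{abs}\Phi_{pl}$ is flagged, not
rejected, above 1.

# The synthetic workbench

No raw bead spectra are publicly available for this kind of chain, so
the package carries a first-class synthetic-scene generator
(`synthetic_scene()`, `synthesize_measurements()`) that runs the
physics forward — Mie, adding-doubling, sphere magnification, detector
responsivity, dark offsets — and emits the complete raw-scan bundle.
Its defaults are the package's study conditions: a quasi-monodisperse
(2 % CV) polystyrene-in-water dispersion in a 1 mm quartz cell,
1.25 µm diameter unstained or 1 µm dye-loaded, dye modelled as a single
Lorentzian band (center 530 nm, FWHM 60 nm, peak
$\varepsilon = 5\times10^4$ L mol⁻¹ cm⁻¹ — a Nile-Red-like stand-in),
intra-particle concentration 0.02 mol/L ($n_2$ peak ≈ 0.01),
$\Phi_{pl} = 0.76$, wall reflectivity 0.97, number concentrations
giving $\mu_s \approx 3.5$–7 mm⁻¹. Wavelength grids are 400–800 nm in
5 nm steps for reflectance/transmittance and 1 nm for the quantum-yield
scans; these sizes keep a full pipeline run near 15 s while resolving
the Mie resonances that carry the size information. Detector noise is
multiplicative Gaussian per spectral sample with a configurable CV, all
through one seeded generator; a fixed seed reproduces byte-identical
bundles.

What the workbench does *not* emulate — and therefore what passing
recovery tests do and do not show — deserves honesty: detector
nonlinearity and stray light, reabsorption of emitted light inside the
sample (the synthetic emission band does not re-enter the transport
model), wavelength-dependent sphere-wall aging, cuvette wall thickness
as a coherent etalon, and dependent scattering at high volume
fractions. Zero-noise recovery tests demonstrate that the inverse chain
is consistent with the forward chain to solver tolerance; they cannot
certify accuracy against instrument systematics absent from the model.

## Recovery under the study conditions

The acceptance suite runs the full chain at zero noise and requires
$r_p$ within 2 %, $N_p$ within 5 %, $n_2$ peak within 10 %, and
$\Phi_{pl}$ within 0.005 absolute; in practice the chain lands one to
two orders of magnitude inside these bounds. With 1 % detector noise,
$\Phi_{pl}$ stays within 2 % for strongly absorbing loadings; recovery
error statistics are non-decreasing in the noise level by test.

A physically interesting check reproduced by the suite: generating data
*with* the Kramers–Kronig real-index term and fitting *without* it
biases the fitted diameter low and the concentration high (≈ −2.5 % and
+6 % under the default dye band) — anomalous dispersion shifts the
resonance positions that encode the size, and ignoring it is not a
neutral simplification.

# Known limitations

* Homogeneous spheres only: no coated particles, no shape distributions.
* Unpolarized, time-independent transport; the Henyey–Greenstein
  phase function is an approximation to the true Mie phase function
  (adequate for the bulk observables used here, by the Monte-Carlo
  comparison).
* The per-wavelength $n_2$ mode has no smoothness constraint beyond the
  data; with noisy $\mu_a$ the band-shape mode is strongly preferred.
* The finite-band Kramers–Kronig transform omits out-of-band
  contributions by construction; a constant or normal-dispersion
  baseline is the user's responsibility when matrix and dye differ
  outside the band.
* Uncertainty is by seeded re-simulation only; no analytic error
  propagation.
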