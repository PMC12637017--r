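---
title: "Simulating image contrast in thick vitrified specimens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating image contrast in thick vitrified specimens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thickEM)
```

## The problem

Cryo-electron microscopy of objects thicker than a few tens of nanometres
leaves the weak-phase regime: at 200 keV the phase difference between protein
and vitreous ice reaches one radian after only a few tens of nanometres, so a
bacteriophage in a few hundred nanometres of ice is a mixed phase/amplitude
object.  On top of that, inelastic scattering (mean free path about 157 nm in
vitreous ice at 200 keV) removes most electrons from the zero-loss peak that
energy-filtered TEM relies on, while elastic scattering beyond the acceptance
angle produces amplitude contrast.  `thickEM` provides one consistent set of
tools to quantify these effects:

* **physics core** — relativistic beam quantities, mean-inner-potential phase
  per unit thickness, absorption coefficients from an angular window of the
  elastic scattering factors, attenuation and mean-free-path budgets;
* **specimen geometry** — a parametric T4-like phage (icosahedral protein
  shell, DNA as concentric cylinders) embedded in an ice slab and voxelised
  into per-slice material maps;
* **multislice engine** — complex (absorptive) phase gratings, Fresnel
  propagation, exit waves, and the slice-thickness error budget;
* **optics** — aberration function, CTF, temporal/spatial coherence
  envelopes, Scherzer defocus, depth of field;
* **TEM and tcBF-STEM pipelines** — aberrated bright-field images with
  zero-loss fluence budgeting and Poisson noise; 4D-STEM recording on
  segmented detectors with parallax-corrected (tilt-corrected) bright-field
  summation;
* **EELS model** — Poisson multiple-scattering synthesis of low-loss spectra
  and log-ratio thickness estimation;
* **incoherent Monte Carlo** — multiply-scattered electron trajectories
  through the voxelised specimen, binned on annular detectors.

## The model specimen

The phage capsid is the intersection of the twenty face half-spaces of a
regular icosahedron, scaled anisotropically along its five-fold axis; the
protein shell is the region between the outer capsid and an inner copy shrunk
by the shell thickness (for an anisotropic body a uniform inward offset is
not an exact scaled copy — the shell thickness is therefore approximate at
the apices, an accepted simplification).  The genome is modelled as
concentric cylindrical DNA shells, 2 nm thick with a 1 nm gap, clipped to the
capsid interior.

The published description of the original geometry is not available, so the
defaults are package choices, stated once: capsid length 110 nm and width
80 nm (the capsid roughly fills the 110 nm field of view used for the
scanned-probe simulations), shell thickness 3 nm, and a DNA volume fraction
of 0.40 of the capsid interior — dense but sub-crystalline packing,
consistent with the coarse literature figures for tailed phages.  The number
of DNA shells is chosen to approach the requested fraction and the axial
extent of the cylinders is then trimmed continuously (a "spool" shorter than
the capsid) so the fraction is met exactly; the trimming is deterministic,
computed from exact column heights of the inner polyhedron on a fixed
lattice, and no random numbers are used anywhere in geometry or
rasterisation.

```{r geometry}
phage <- build_phage()
phage$annuli           # DNA shells (outer/inner radii, nm)
model <- embed_in_ice(phage, ice_thickness = 200)   # centred, top view
maps <- rasterize(model, N = 128, L = 128, delta_t = 2)
voxel_volumes(maps)
```

## Materials and optical constants

Compositions and densities for vitreous ice, protein and nucleic acid ship
with the package, together with the averaged low-angle elastic scattering
factors (0.8885 / 1.5170 / 1.5808 Å), the absorption coefficients for the
>6 mrad multislice window (1.82, 2.71, 3.62 × 10⁻⁴ Å⁻¹) and measured mean
free paths (elastic 581/342/256 nm; inelastic 157 nm for ice) at 200 keV.
Two conventions about these constants deserve a note:

* The shipped "imaginary part" constants are stored as intensity absorption
  coefficients µ (Å⁻¹).  Their reciprocals (549/369/276 nm) track the quoted
  elastic mean free paths at about 93%, exactly what "nearly all elastic
  scattering falls beyond 6 mrad" implies; an amplitude-scale reading would
  give metre-scale mean free paths, which is unphysical.  The independent
  Eq.-(4)-style integral over the shipped scattering-factor table gives
  µ(>6 mrad) = 1.57 × 10⁻⁴ Å⁻¹ for ice, corroborating the magnitude.
* A parameterised five-Gaussian elastic scattering-factor table (H, C, N, O,
  P, S) is shipped for the derived route (absorption integrals, Monte Carlo
  screening, no-override materials).  Published one-radian-thickness values
  for protein against ice are *not* reproducible from the printed
  compositions and averaged factors — the evaluation gives ≈30 nm at
  200 keV, not ≈47 nm — so the package treats such printed values as soft
  checks (monotone increase and saturation with voltage) and
  `one_radian_thickness()` attaches the constants it used as attributes so
  any convention can be audited.

Mean free paths and µ rescale between voltages with the (λγ)² law, the same
scaling that makes MeV microscopy unattractive for penetration: λγ falls
from 3.49 pm at 200 keV towards the Compton wavelength, so the gain
saturates.

## Multislice conventions and the error budget

Propagation uses the unmodified Fresnel kernel `exp(-i π λ d k²)` in
spatial-frequency form (sign fixed by this convention; a positive distance
moves the wave towards the exit surface).  The engine uses symmetric (Strang)
splitting — half-slice propagation, grating at the slice centre, half slice —
matching the slice-centred voxel sampling of `rasterize()`.  A circular 2/3
band-limit mask is applied at every propagation; it is standard multislice
anti-aliasing hygiene, and tests that need strict unitarity use smooth
objects whose spectra lie inside the band.

The per-slice splitting error is budgeted as

E_slice = ½ · φ′(θ_M) Δt · (π θ_M² Δt / 2λ),

the product of the grating phase over one slice (scattering factor evaluated
at the largest sampled angle θ_M = λN/2L) and the propagator dephasing over
the half slice that the symmetric splitting exposes.  The overall error is
the per-slice value times the number of slices, hence linear in Δt.  For
2 nm slices of vitreous ice over 200 nm at θ_M ≈ 5 mrad this gives 8.8%,
below the 10% working bound that motivates the default `delta_t = 2`.  The
printed form of this budget is typographically ambiguous about a factor of
two in the propagator phase; the half-slice reading is the one consistent
both with the splitting actually implemented and with the stated sub-10%
conclusion, and the full-slice reading (17.6%) would contradict the latter.

## Optics, envelopes and the fluence budget

`chi()` implements χ(θ) = (π/λ)(Cs θ⁴/2 − Δf θ²) with underfocus positive.
Closed forms reproduce the standard instrument numbers:

```{r optics}
b <- beam_parameters(200)
scherzer_defocus(2.0, b)        # 81.8 nm for an F20-class instrument
depth_of_field(3e-3, b)         # ~279 nm at 3 mrad (printed as 277 nm)
round(angle_to_resolution(c(3e-3, 6e-3), b), 2)
round(100 * zero_loss_fluence(1, 200, 157))   # 28% zero-loss budget
```

Both resolution conventions λ/θ and λ/2θ exist in the field; the printed
instrument numbers (0.8 nm at 3 mrad, 0.42 nm at 6 mrad) fix λ/θ as this
package's default, with `convergence_for_resolution()` exposing the λ/2d
illumination requirement separately.

The temporal envelope is Gaussian in the focal spread (given directly in nm;
a chromatic-aberration constant is deliberately *not* a package parameter
because it is instrument-specific and not needed once the spread is stated).
The spatial envelope depends on the source distribution through |dχ/dθ|: a
Gaussian form for the elastic source (beam convergence) and an exponential
(Lorentzian-source) form for inelastic dipole scattering with the
relativistic characteristic angle θ_E = ΔE/(γmv²).  Both are exactly 1 at
stationary points of χ.  Printed coherence-limited resolutions that depend
on unstated envelope thresholds are treated as qualitative only.

## Reciprocity, parallax and tcBF-STEM

`record_4d()` computes, for every probe position, the multislice exit wave
of an aberrated convergent probe and bins the far-field intensity on a
segmented detector (default 20 rings × 90 segments over 4 mrad).
`tilt_corrected_bf()` undoes each bright-field bin's parallax displacement
−(Cs ω² − Δf)ω by Fourier phase ramps (exact for band-limited scan images)
and sums; per-segment shifting is the default, ring-averaging an option.

Three facts about the tcBF ↔ TEM correspondence that the implementation
makes explicit:

* **Reciprocity is exact for a point detector** — numerically, the on-axis
  bin of the 4D record equals the plane-wave TEM image computed through the
  slice stack *in reversed slice order* (the transpose of the multislice
  operator).  For z-mirror-symmetric specimens the distinction vanishes.
* **The identity degrades at the bright-field disc edge**: a detector pixel
  at tilt ω only transfers object frequencies θ with both sidebands inside
  the aperture (θ + ω < α); edge bins are single-sideband and genuinely
  differ from the TEM image.  The reciprocity regression therefore uses a
  detector whose outer tilt plus the object bandwidth stays inside the
  3 mrad aperture, where the summed tcBF image matches TEM with normalised
  cross-correlation above 0.98.
* **The parallax correction earns its keep at large defocus.**  At 0.5 µm
  defocus the shifts are sub-pixel and detector-pixel images also carry an
  odd differential-phase component that cancels only in the azimuthal sum;
  at 2 µm the measured bin displacements follow (Cs ω² − Δf)ω and the
  corrected sum clearly outperforms the uncorrected one (normalised
  cross-correlation with TEM ≈0.93 versus ≈0.21 in the scaled phage run).

Since STEM needs no energy filter, tcBF images keep the full incident
fluence; the TEM pipeline multiplies its fluence by exp(−t/λ_in) for the
zero-loss window before Poisson noise is drawn.

## EELS model

`synthesize_spectrum()` builds low-loss spectra from Poisson multiple
scattering: order n carries weight e^(−t/λ)(t/λ)ⁿ/n! and the n-fold
self-convolution of a Drude single-scattering profile (peak 20 eV, width
10 eV — the vitreous-ice plasmon), evaluated in closed form through the
exponential of the profile's Fourier transform on a padded axis.  The axis
(0.5 eV/channel over 512 eV by default) is treated as recording all
transmitted electrons; the vanishing beyond-axis tail is renormalised into
the inelastic part so the zero-loss fraction is exactly e^(−t/λ) and the
log-ratio estimator `thickness_from_spectrum()` round-trips to machine
precision in the noiseless model (and to |Δ(t/λ)| < 0.02 with a realistic
zero-loss window).  With increasing thickness the synthetic spectra walk
through the published regimes: zero-loss dominated below ~1.5 mean free
paths, plasmon dominated beyond, and a skewed high-loss peak far above one
plasmon energy for t/λ ≈ 5 — a Landau-like shape from convolved Poisson
orders, not the exact straggling theory, which is out of scope.  In this
pure multiple-scattering model the optimal 20 eV window moves from the
zero-loss peak to the plasmon at t/λ ≈ 1.2 — between the two-order Poisson
estimate (t/λ = ln 2 ≈ 0.7, which ignores window overlap and order-2
leakage) and the measured ~230 nm/157 nm ≈ 1.46; measured window fractions
also fold in instrument response that this model does not attempt.

## Monte Carlo of incoherent contrast

`run_mc()` emulates the published Penelope-based incoherent STEM runs with a
deliberately small model: Woodcock (delta) tracking against the densest
material's total scattering rate steps electrons through the voxel grid;
elastic deflections are screened-Rutherford with Thomas–Fermi screening
(η = (λZ^{1/3}/(2π·0.885·a₀))²/4, element chosen ∝ n_j Z_j^{4/3});
inelastic events deflect by a Lorentzian dipole angle with a Bethe-ridge
cutoff and tally a Drude-sampled energy loss that does not feed back into
the kinematics (tens of eV are negligible for deflection below a micron of
ice).  No secondaries, no bremsstrahlung, no detector response.  Mean free
paths come from the material table, rescaled by (λγ)²; the inelastic/elastic
ratio 0.27 measured for ice is the default for all materials.

Reproducibility contract: seeds are derived per (scan position, chunk of
electrons), so any partition of the electron budget at chunk granularity
sums exactly to the single-run tallies, and electron conservation per pixel
is exact integer bookkeeping.

The scaled-down acceptance runs (64×64 probes, 1,000 electrons per 1 nm
pixel, 400 nm ice) reproduce the qualitative published contrasts: concentric
DNA rings in the dark-field top view, bright-field/dark-field contrast
reversal over the capsid, axis-parallel banding at reduced contrast in the
side view, and no discernible top-bottom difference between the phage at
100 nm and 300 nm depth.  At a tenth of the published dose the 3 nm
shell/gap period is at the noise floor in the side view, so that check is
phrased as profile anisotropy rather than per-stripe significance.

## What a green test establishes — and what it does not

The synthetic specimen is a geometric idealisation: sharp material
boundaries, no solvation layer, no structural disorder in the DNA spooling
(the cylinder arrangement is a resolution test target, not a structural
claim), no tail or fibres.  The multislice is a mean-inner-potential model
at nm resolution: no atomic detail, no thermal diffuse scattering, no
Debye-Waller factors.  Energy-filtered imaging is modelled as a scalar
fluence fraction plus the appropriate envelope, not as a chromatically
blurred background.  Detectors are ideal (the published simulations made the
same assumption).  Agreement of the acceptance suite therefore validates the
numerics and the stated physics approximations against their own closed
forms and against the published headline numbers — not the fidelity of any
of these models to a particular instrument.

## Numerical choices

* FFT grids are unshifted (`fft` ordering); k = 0 is the first element.
  Images and waves are indexed `[x, y]` with x fastest, origin at the field
  corner, beam along +z, slices half-open in z.
* Band limit 2/3 of Nyquist, applied at each propagation.
* Absorption enters the gratings as exp(−µΔt/2) on the amplitude.
* Adaptive quadrature (split at 1, 10, 100 mrad) for the absorption
  integrals; relative tolerance 1e-9.
* Ties in voxel classification cannot occur (strict half-open comparisons);
  degenerate inputs (vacuum materials, zero-size bodies, empty windows)
  return the physically trivial limit rather than erroring where the limit
  is well defined.
* All stochastic stages (shot noise, spectra, Monte Carlo) take explicit
  integer seeds and restore the caller's RNG state.
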