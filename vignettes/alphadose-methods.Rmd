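---
title: "Small-scale alpha dosimetry from sequential-section autoradiographs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-scale alpha dosimetry from sequential-section autoradiographs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphadose)
```

## The problem

Alpha-particle radiopharmaceutical therapy deposits its dose within a few
cell diameters of each decay (the two At-211-chain alphas have ranges of
48 and 70 µm in water), so organ-level mean doses say little about what
the tissue actually receives. `alphadose` computes absorbed-dose-rate maps
at the ~10–30 µm scale from single-particle digital-autoradiography
measurements of sequential 12-µm cryosections, and quantifies how
non-uniform the result is.

The chain is: listmode events → per-slice activity images, decay-corrected
to biopsy time → a registered 3D activity stack → convolution with a
Monte Carlo energy-deposition kernel → central-slice dose-rate analysis
(uniformity partition, kinetics over biopsies, histology overlay), plus
two approximations for studies that can only afford 1–3 slices.

## Physics: the dose-point kernel

The kernel `K` is the mean energy deposited per voxel per alpha emission
from a point source in water. We transport straight-line tracks under the
continuous-slowing-down approximation (CSDA): each emission draws a decay
pathway (5.87 MeV with probability 0.418, or the 7.45 MeV Po-211 alpha
with probability 0.582, one alpha per parent decay under secular
equilibrium) and an isotropic direction, then loses `S(E)·Δs` per step
(`Δs = min(voxel/5, 0.2 µm)`) until the 0.01 MeV cutoff, where the
residual is deposited locally. Per-track energy conservation is therefore
exact, and events are apportioned to the two pathways by cumulative
rounding so the kernel total equals the branch-weighted mean energy
(6.7896 MeV) identically rather than fluctuating with branch sampling.

This is deliberately simpler than a general-purpose Monte Carlo code:
no energy-loss straggling, no angular scattering, no delta-ray transport.
Alpha tracks in water are nearly straight and the kernel is used only
after radial averaging, so the main cost of the simplification is an
underestimate of voxel-to-voxel statistical variance (see *Uncertainty
bookkeeping*).

The stopping-power table shipped in `inst/extdata/` is **synthetic**: a
physically shaped alpha-in-liquid-water curve (electronic-stopping peak
near 0.7 MeV, ~1/E fall-off above, rising from low energy) calibrated by
a smooth two-parameter factor so that the package's own range quadrature
reproduces the two published CSDA ranges exactly:

```{r ranges}
water <- load_stopping_water()
csda_range(c(5.87, 7.45), water)
```

Swapping this CSV for a measured table (e.g., a different medium density)
changes the medium; no interface corrections are attempted, so
heterogeneous structures (bone, lung interfaces) are out of scope — the
dose-point-kernel formalism itself is ill-posed there.

### Radial averaging and rebinning

`radial_average()` groups voxels by the *exact* distance of their centres
from the source voxel (the octahedral-orbit classes of the cubic lattice)
and replaces each voxel by its class mean. Exact-distance grouping was
chosen over fixed-width shells because it is parameter-free, preserves
the kernel total and the octahedral symmetry identically, and matches the
natural discrete radial average on a lattice; `bin_width_vox` restores
fixed-width binning when coarser pooling is wanted. `rebin_kernel()` then
block-sums (energy is extensive) onto the autoradiograph geometry —
10–30 µm in-plane, 12 µm axially — padding with zeros so totals are
preserved and keeping odd dimensions so a central voxel exists. For even
rebin factors the source sits half a fine voxel off the coarse-voxel
centre; that half-voxel asymmetry is the closest alignment an even factor
admits.

After 12-µm rebinning, all deposition lies within six slices of the
source (±72 µm covers the 70 µm maximum range), which is what makes
limited-slice approximations feasible at all.

### Uncertainty bookkeeping

Per-voxel relative standard errors are tracked from per-event sums of
squares, and radial averaging pools them as the standard error of the
class mean (`sqrt(sum SE_i^2) / m`). `kernel_uncertainty_summary()`
reports the mean relative standard error over nonzero voxels as a
percentage. Note that under deterministic CSDA transport the per-crossing
deposit varies only through chord-length geometry, so this statistic is
substantially smaller than the same estimator under a stochastic-physics
transport at equal event counts; it scales as `1/sqrt(n_events)` (a
property the test suite checks) and should be read as internal
Monte Carlo precision, not as a cross-code absolute.

## From events to activity

Cluster detection uses 8-connected components above threshold with
intensity-weighted centroids; overlapping clusters are not split, and
`min_area = 2` rejects single-pixel noise. The coordinate convention
everywhere is 0-based pixels, origin top-left, x = column, y = row,
half-open pixels.

Each tissue-slice ROI gets one temporal histogram (default 600 s bins)
and one exponential fit; per-pixel fits would be hopeless at ~1 event per
pixel. The decay correction

\[
A_i \;=\; N_i\,\lambda\, e^{\lambda t_\mathrm{start}}
  \big/ \big(\varepsilon\,(1 - e^{-\lambda T})\big)
\]

inverts decay during the acquisition window `T` and the detection
efficiency (default 0.49: half of the 98 % 4π efficiency in the 2π
source-on-scintillator geometry), yielding Bq per pixel at biopsy time.
The decay constant defaults to the per-ROI fit; fixing it to
ln 2 / 7.2 h is available (and recommended) for low-count slices.

ROI and tissue masks threshold the smoothed image at *half the
Otsu-located core level*: a Gaussian-blurred step crosses half-height at
the true boundary, so the rule neither erodes sparse Poisson-textured
slices (as a plain Otsu cut does) nor dilates them into the smoothing
halo (as a very low cut does); it is scale-invariant. The one-tenth-Otsu
rule is used where sparse and dense binaries must merely *cover* the
tissue extent for co-registration, in `iqid_binary()`.

## Stack registration

Consecutive 12-µm slices are treated as minimally distorted 2D rigid
transforms of their neighbours and registered in a chain (slice *k*
against the transformed slice *k−1*). The rotation is found by exhaustive
MSE scan at 1° steps; refinement then alternates a global rotation
re-scan with a translation-only fit, finishing with a golden-section
profile search over the angle (rotation and translation form a curved
valley in which a joint simplex reliably stalls — the profile objective
min-over-translation is smooth and unimodal). The refiner never returns
something worse than its input: if the search fails it reports the
initial transform with `converged = FALSE`.

Bilinear resampling changes cumulative intensity slightly; each slice is
rescaled by `sum(before)/sum(after)` (the compensation factor, recorded
per slice) so total activity is conserved exactly — a property audited at
1e-6 in the tests. The mean |compensation − 1| on our phantoms is of
order 1e-3–1e-2; its value on any real dataset is a property of those
images. Slice counts are forced odd (dropping the last slice, with a
warning) because the central-slice analyses need a symmetric middle
slice; torn slices are replaced by their nearest good neighbour (ties to
the lower index) before dosimetry.

## Dose-rate maps

`convolve_dose_rate()` evaluates the discrete dose-point-kernel
convolution with zero-padded FFTs:

\[
\dot{D}(r) \;=\; \sum_{r'} \frac{K(|r' - r|)}{\rho\,V}\, A(r'),
\]

with the mass `ρV` evaluated at the voxel where dose is scored (the
standard DPK convention; the density defaults to 1 g/cm³ water). Units
run Bq × MeV/emission → J/s via 1.602176634e-13 J/MeV → mGy/h. Tissue is
zero-padded — slices are mounted surrounded by inactive medium — and for
exactly that reason quantitative claims are restricted to the central
slice, which alone has measured tissue across the full alpha range on
both sides. FFT output is clipped at zero to remove round-off-scale
negatives; equivalence with direct summation is tested at 1e-9 relative.

## Limited-slice methods

**Slice contribution**: rerun the convolution keeping only the central
*N* = 1, 3, 5, … slices and record the central-slice voxel sum
\(\dot{D}_N\) against the all-slice value \(\dot{D}_0\). The ratio curve
is fitted with the asymptotic model

\[
\dot{D}_N/\dot{D}_0 \;=\; 1 - \alpha\, e^{-\beta (N-1)},
\]

chosen (the data source gives no formula) so the ratio tends to 1 at
large *N* while the single-slice correction \(C_N = 1/\mathrm{ratio}(N)\)
stays finite. Because the measured ratio reaches exactly 1 at
\(N_\mathrm{max}\) while the model only approaches it, corrected
estimates lose accuracy for large *N* — the correction is meant for the
small-*N* regime. Deriving \(C_N\) requires one full stack.

**Cloning** needs no full stack: keep the central *N* slices and pad each
side with copies of the outermost kept slice until the stack spans the
kernel's z half-extent (6 clone slices at 12 µm), then convolve. It is
exact when the activity pattern does not vary with depth, and otherwise
overemphasises features of the measured slice: hot spots confined to the
centre slice are overestimated, cold spots underestimated — a signed bias
the tests verify voxelwise.

## Uniformity and kinetics

The central-slice dose-rate histogram is partitioned at mean + 1σ and
mean + 2σ (population σ over masked voxels; a value exactly at a
threshold goes to the hotter region; σ = 0 flags a degenerate all-cold
partition). Region areas are voxel counts × pixel area.

Dose-rate time courses per region are fitted with the six-parameter
double exponential \(y = a e^{-b(x-m)} - c e^{-d(x-n)}\) by weighted
least squares (weights 1/error²), with amplitudes initialised from the
data maximum, rates at ln 2/T½ and 3 ln 2/T½, and five seeded restarts to
dodge local minima; individual parameters of this model are often poorly
constrained at n ≈ 14 points, but the fitted *curve* — and hence its
integral — is stable, which is what the tests pin down. Absorbed dose
integrates the curve from injection (t = 0) over six half-lives
(43.2 h, capturing 1 − 2⁻⁶ = 98.44 % of a pure-decay integral), clipping
negative model values to zero. The one-sided uncertainty scales the curve
through the maximum observation: `(s − 1) ×` dose, with
`s = max(observed/fitted)`.

## Histology fusion

High-resolution H&E scans are down-sampled (factor 20 in production; the
examples here use smaller images and factor 4), cast to binaries — Otsu
on inverted luminance for H&E (tissue is darker than the slide), one
tenth of Otsu for the much sparser dose-rate maps — brought to a common
µm/px scale from their metadata, lightly smoothed (anti-aliasing the
binary edges removes quantisation plateaus that bias sub-degree rotation
estimates), and co-registered with the same rotation-scan + rigid
machinery as the stack. Note the dose-rate binary necessarily includes
the alpha halo extending ~70 µm beyond the tissue outline, so a degree
or so of rotational ambiguity against the histology outline is inherent
to the data, not the optimizer. A small shear
(|shear| ≤ 0.2) absorbs the 50–100 µm section offset between the stained
and measured slices; it is searched in 1D with the rigid refiner as inner
solver, again because of valley-shaped coupling. Reflection (sections
mounted face-down) is a manual flag. The composed transform is returned
to full-resolution H&E coordinates, quality-scored by Dice overlap
(flagged below 0.5), and used to rasterise hot-region contours onto the
stain with a 1 mm scale bar.

## The synthetic phantom

Everything above is testable without data because the phantom module
generates the inputs the pipeline assumes: an ellipsoidal node
(650 × 500 × 120 µm semi-axes on a 64 × 64 × 21 grid of
26 × 26 × 12 µm voxels) with uniform background activity of 1e-4
Bq/voxel and two follicle-scale Gaussian hot foci (σ = 50 µm, 5×
background) near the central plane — small and central enough that their
closed-form integrals survive the node boundary, which is what the
conservation tests check. An optional `cut_fraction` truncates the node
to the asymmetric outlines of part-node biopsies (and incidentally breaks
the 180° near-symmetry that makes binary registration of a perfect
ellipse degenerate). The background level was chosen so that background
dose rates land at a few tens of mGy/h — the regime reported for
lymph-node sections — which corresponds to ~1–2 detected events per
voxel over a 15 h acquisition: sparse single-particle images, not
integrated ones.

Acquisition simulation is event-by-event: per-voxel Poisson counts with
mean `ε·A·(1 − e^{-λT})/λ`, event times by inverse-CDF sampling of the
window-truncated exponential, positions blurred with the 20 µm FWHM
detector PSF, per-slice mounting jitter uniform in ±10° and ±20 px, and
torn slices modelled as a zeroed wedge. What the phantom does *not*
emulate: real lymph-node microarchitecture, camera noise beyond the
Gaussian PSF, cluster-shape statistics, slice-to-slice biological
variation. Passing tests therefore demonstrate correctness of the
algorithms under the stated statistical model, not performance on any
particular tissue.

## Numerical choices, sizes, and limitations

* Quadrature: CSDA ranges by trapezoid on a 1e-4 MeV grid; log-log
  interpolation of the stopping table; transport and its plain-R test
  oracle share the same dense grid so they agree to float precision.
* FFT sizes are padded to products of 2/3/5; convolution equivalence is
  asserted at 1e-9 relative on grids up to 32³.
* Tests run the kernel at 1e4–5e4 events on 2-µm grids (seconds); the
  production kernel (1e7 events, 151³ at 1 µm) is exercised by the
  acceptance script and one acceptance test and takes a few minutes.
* Registration accuracy claims (0.5°, 0.5 px) hold for the phantom's
  smooth, asymmetric slices; featureless or symmetric binaries are
  genuinely ambiguous and degrade gracefully via the `converged` flag
  and Dice score.
* The electron-capture branch (Po-211 X-rays/Auger) is not in the
  kernel; RBE weighting and stochastic per-cell microdosimetry are out
  of scope.
* Activity quantification rests on the event-by-event premise (one count
  per detected alpha) and the configured efficiency; there is no
  gamma-counter cross-calibration.
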