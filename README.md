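# alphadose

Small-scale absorbed-dose estimation for alpha-particle
radiopharmaceutical therapy (αRPT) from single-particle digital
autoradiographs of sequential tissue sections.

Alpha particles deposit their full energy within a few cell diameters
(the two ²¹¹At-chain alphas, 5.87 and 7.45 MeV, have CSDA ranges of 48
and 70 µm in water), so a whole-organ mean dose can misstate what most
of the tissue receives by several-fold. `alphadose` turns event-by-event
camera data from sequential 12-µm cryosections into quantitative
dose-rate maps at the ~10–30 µm pixel scale and quantifies the
non-uniformity of the result.

The pipeline:

1. **listmode** — cluster detection in camera frames (8-connected,
   intensity-weighted centroids) and spatial/temporal binning of events;
2. **activity** — tissue-ROI segmentation, per-ROI exponential decay fit
   of the temporal histogram, and decay/efficiency correction to Bq per
   pixel at biopsy time:
   `A = N λ e^{λ t₀} / (ε (1 − e^{−λT}))`;
3. **registration** — neighbour-chained rigid alignment of consecutive
   slices (exhaustive MSE rotation scan + profile refinement), with a
   per-slice scalar compensation factor so cumulative activity is
   conserved exactly; torn slices are replaced by neighbours;
4. **physics** — a Monte Carlo energy-deposition kernel for the ²¹¹At
   chain: straight-track continuous-slowing-down (CSDA) transport in
   water, exact per-track energy conservation, radial averaging, and
   rebinning to the image voxel grid;
5. **dosimetry** — FFT dose-point-kernel convolution
   `Ḋ(r) = Σ_r′ K(|r′−r|) A(r′) / (ρV)` in mGy/h, analysed on the
   central slice;
6. **uniformity** — dose-rate-area histograms and a
   cold (< mean+1σ) / mid / hot (≥ mean+2σ) partition of the tissue;
7. **kinetics** — double-exponential fits
   `y = a e^{−b(x−m)} − c e^{−d(x−n)}` of hot/cold dose-rate time
   courses and absorbed dose by integration over six half-lives;
8. **histofusion** — automatic co-registration of dose-rate maps with
   H&E stains (Otsu / one-tenth-Otsu binaries, scale matching, optional
   shear) and contour overlays;
9. **limited-slice methods** — the slice-contribution correction
   `Ḋₑ = C_N Ḋ_N` and the cloning method, which replaces unmeasured
   tissue with copies of the outermost measured slices;
10. **synthetic phantom** — a lymph-node-like ground-truth generator
    (ellipsoidal node, Gaussian hot foci, Poisson event sampling under
    ²¹¹At decay, 20 µm FWHM PSF, per-slice jitter, torn slices) so the
    whole pipeline is testable without any external data.

## Worked example

A full phantom study — simulate a 15-h acquisition of 17 sections,
rebuild activity, register, convolve, and analyse:

```r
library(alphadose)

water <- load_stopping_water()
csda_range(c(5.87, 7.45), water)
#> [1] 48 70

kern <- radial_average(generate_kernel(nuclide_at211(), water,
                                       n_events = 1e5, voxel_um = 1,
                                       half_extent_um = 75, seed = 1))
kern
#> <dose_kernel> 151x151x151 voxels of 1x1x1 um; total 6.78956 MeV/emission; 1e+05 events

spec  <- phantom_spec(seed = 1)              # node + 2 hot foci
truth <- build_truth_stack(spec)
lms   <- simulate_acquisition(truth$stack, acquisition_config(),
                              nuclide_at211(), spec, seed = 1)
sum(vapply(lms, nrow, 0L))                   # detected alpha events
#> [1] 30619

acts  <- lapply(lms, function(lm)
  slice_activities(lm, expected_n = 1, fixed_half_life_h = 7.2)[[1]])
stack <- register_stack(acts)
stack
#> <activity_stack> 156x163 px x 17 slices; voxel 26x26x12 um; total 2.1367 Bq

kr <- rebin_kernel(kern, 26, 12)             # kernel on the image grid
cs <- central_slice(convolve_dose_rate(stack, kr))
partition_by_sigma(cs)
#> <region_partition> mean 54.047; sigma 24.039
#> # A tibble: 3 x 3
#>   region area_fraction mean_dose_rate
#>   <chr>          <dbl>          <dbl>
#> 1 cold          0.921            48.1
#> 2 mid           0.0288           88.3
#> 3 hot           0.0502          144.
```

The hot 5 % of the tissue receives ~2.7× the whole-section mean dose
rate — exactly the kind of non-uniformity a mean-only report hides.

How many sections does the answer really need? Keep only the central
`N` and compare:

```r
res <- slice_contribution_curve(stack, kr)
print(res$curve, n = 9)
#> # A tibble: 9 x 3
#>       N dose_rate_N ratio
#>   <dbl>       <dbl> <dbl>
#> 1     1      21568. 0.277
#> 2     3      46483. 0.596
#> 3     5      62318. 0.799
#> 4     7      71940. 0.922
#> 5     9      76193. 0.977
#> 6    11      77904. 0.999
#> 7    13      77984. 1
#> 8    15      77984. 1
#> 9    17      77984. 1

fit_contribution_correction(res)
#> <contribution_fit> ratio(N) = 1 - 0.7359 exp(-0.3381 (N-1)); C_1 = 3.786

sum(cloning_dose_rate(stack, 1, kr)$values) / res$dose_rate_full
#> [1] 1.047099
```

A single measured slice carries only 28 % of the central-slice dose
rate (out-of-slice tracks supply the rest); the curve saturates at
N ≈ 11–13 slices, i.e. once the stack spans the 70-µm alpha range on
both sides. The contribution fit supplies the empirical scale-up
`C₁ = 3.79`; the cloning method needs no full stack and lands within
~5 % high — high because cloning overemphasises features of the
measured slice.

Each result type has a plot: `plot_kernel_profile()`,
`plot_dose_rate_map()`, `plot_dose_rate_histogram()`,
`plot_contribution_curve()`, `plot_dose_rate_curve()` (and matching
`autoplot()` methods). Kinetics across biopsies:
`fit_double_exponential()` → `integrate_absorbed_dose()` →
`dose_uncertainty_maxscale()`, with broom-style `tidy()`/`glance()`.
See `vignettes/alphadose-methods.Rmd` for the models, assumptions and
numerical choices.

A thin CLI wraps the same functions
(`exec/alphadose <subcommand> --help`): `run`, `simulate`, `kernel`,
`dose`, `minimize`, `uniformity`, `kinetics`.

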