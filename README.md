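# fractometry

Single-cell **biophysical fractometry** in R: from knife-edge quantitative
phase images of individual cells to far-field light scattering, fractal
dimension, a 17-feature fractal/ALS profile, bulk dry-mass morphology, and
the cohort statistics used in label-free morphological profiling.

Cell architecture is statistically self-similar over a limited band of
length scales, and that fractality shifts with disease state, drug response
and cell-cycle phase — but it is invisible to ordinary Euclidean shape and
texture features. This package implements the Fourier-domain route to
measuring it at single-cell precision, for anyone building label-free
imaging flow cytometry or quantitative-phase profiling pipelines.

## The method in brief

1. **Field reconstruction.** Four half-blocked (knife-edge) intensity
   images encode the phase gradient of the complex field
   `E = A·exp(iφ)`:
   `∂φ/∂x ∝ (Ix⁺ − Ix⁻)/(Ix⁺ + Ix⁻)`, and the amplitude is
   `A = (Ix⁺ + Ix⁻)/B`. The gradient is integrated in one step by complex
   Fourier integration with kernel `1/(2π(fx + i·fy))` (DC fixed to 0).
2. **Fourier-transform light scattering (FTLS).** The far-field pattern is
   `S(kx, ky) = F[E]`; ring-averaging over constant wave vector
   `q = (4π/λ)·sin(θ/2)` gives the angular light-scattering (ALS) profile.
3. **Density correlation and fractal dimension.** By Wiener–Khinchin, the
   inverse transform of `|S|²` is the spatial autocorrelation `C_ρ(r)`;
   for a mass fractal `C_ρ(r) ∝ r^(−α)` and **FD = 3 − α**, fitted by
   log-log least squares. A *fractal-window* detector finds the scale band
   where the power law actually holds (most prominent steep-slope run) and
   refits inside it.
4. **Profiling.** Each cell yields 17 fractal/ALS features plus bulk
   dry-mass features (`σ = OPL / 0.19 ml·g⁻¹`); cohorts are compared with
   z-scored profiles, Cliff's delta effect sizes, one-vs-all AUROC, linear
   regression classifiers, Spearman networks and feature ranking.

Everything is testable end-to-end on synthetic phantoms: weak-phase
spheres with a Mie-series oracle, fractal fields with prescribed power-law
spectra, a knife-edge forward model, and labelled Gaussian cohorts.

## Worked example

```r
library(fractometry)

field   <- fractal_phantom(beta = 2, grid_size = 64, pixel_um = 0.2, seed = 7)
pattern <- far_field_pattern(field)
curve   <- density_correlation(pattern)
fit     <- fit_overall_fd(curve, r_lo = 0.4, r_hi = 3.2)
glance(fit)
#> # A tibble: 1 × 6
#>      fd  alpha        mse  r_lo  r_hi n_bins
#>   <dbl>  <dbl>      <dbl> <dbl> <dbl>  <int>
#> 1  2.90 0.0975 0.00000270   0.4   3.2     15
```

The fitted decay exponent α = 0.098 gives FD = 3 − α = 2.90: a nearly
space-filling mass distribution, with a tiny log-log residual (`mse`,
the "FD MSE2" feature) showing the power law holds well across the probed
scales. The full per-cell profile is one tibble row with exactly 17 named
features (`fractal_profile(field)`), ready to `bind_rows()` into a cohort
table.

Bulk dry mass on a bead phantom:

```r
bead <- sphere_phantom(radius_um = 2.4, delta_n = 0.01, pixel_um = 0.2,
                       grid_size = 64, wavelength_um = 1.064)
mask <- segment_cell(bead, method = "threshold", threshold = 0.01)
dry_mass(bead, mask)
#>   area_um2 opl_mean_nm opl_max_nm dry_mass_pg dry_mass_density_pg_per_um2
#> 1    17.92        32.3       47.9        3.05                        0.17
```

A 32 nm mean optical path over 17.9 µm² converts, at the 0.19 ml/g
refractive increment of biomolecules, to 3.05 pg of dry mass. ROC/effect
size tooling works on any feature table:

```r
coh <- synth_cohort(list(list(name = "ctrl", shift = c(fd = 0)),
                         list(name = "drug", shift = c(fd = 1))),
                    n_per_class = 2000, seed = 1)
auroc(coh$fd, coh$label == "drug")$auroc   # ≈ 0.76 for a 1σ shift
```

A thin command-line front-end (`inst/cli/fractometry.R`) exposes
`simulate`, `reconstruct`, `features`, `profile` and `validate`
subcommands over TIFF stacks and CSV feature tables.

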