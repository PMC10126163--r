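---
title: "Single-cell biophysical fractometry: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell biophysical fractometry: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(fractometry)
```

## The measurement model

Quantitative phase imaging records the complex optical field of a cell at the
image plane,

$$E(x, y) = A(x, y)\, e^{i\phi(x, y)},$$

where $A$ is the bright-field amplitude and $\phi$ the optical path delay in
radians. In a knife-edge (asymmetric-detection) instrument neither $A$ nor
$\phi$ is observed directly; instead the beam is half-blocked from four
orientations, producing intensity images $I_x^\pm$ and $I_y^\pm$ whose
normalised differences encode the phase gradient:

$$\frac{\partial \phi}{\partial x} \;=\; \frac{1}{g}\,
\frac{I_x^+ - I_x^-}{I_x^+ + I_x^-},$$

and likewise along $y$. The proportionality constant $g$ is an optical
calibration of the instrument and is exposed as the `gain` argument
(default 1): the forward model (`knife_edge_forward()`) and the inverse
(`phase_gradients()`) share it, so synthetic round trips are exact by
construction. The amplitude is recovered from the sum of an opposite pair
normalised by the sample-free background, $A = (I_x^+ + I_x^-)/B$; the $y$
pair provides the same estimate, and their maximum relative discrepancy is
kept as a per-cell quality metric.

### Fourier integration of the gradient field

`integrate_phase()` integrates $\nabla\phi = \partial_x\phi +
i\,\partial_y\phi$ in one step in the frequency domain. With frequencies
$f_x, f_y$ in cycles per pixel,

$$\phi = \mathrm{CF}\cdot\operatorname{Im}\!\left\{
\mathcal{F}^{-1}\!\left[\frac{\mathcal{F}[\nabla\phi]}
{2\pi\,(f_x + i f_y)}\right]\right\},
\qquad \mathrm{NF}(0) = 0 .$$

Dividing by $2\pi(f_x + i f_y)$ rather than $2\pi i (f_x + i f_y)$ and taking
the imaginary part are the same operation written two ways — the extra $i$
simply rotates the result into the imaginary channel; the recovered phase is
identical either way, and every periodic band-limited phase is recovered
exactly up to its mean. Numerical choices:

* **Gauge**: the zero-frequency bin of the kernel is set to 0 and the output
  is returned zero-mean. The absolute phase offset is unobservable from
  gradients; tests that compare full fields re-add the reference mean first.
* **Padding**: Fourier integration assumes periodicity. Non-periodic fields
  are replicate-edge padded by `pad_factor` (default 2 in the pipeline) and
  cropped after; an isolated Gaussian bump then reconstructs to about 0.3%
  relative RMSE.
* **$\varepsilon$-floor**: knife-edge denominators are floored at
  $10^{-12}\times$ the peak intensity so dark background pixels cannot blow
  up the gradients.
* **CF** (calibration factor) defaults to 1. On a real instrument it would
  be fitted once against a bead of known peak phase; for the synthetic
  phantoms used throughout, 1 is exact.

The forward model deliberately uses *central differences* rather than
spectral derivatives, so forward + inverse is not a trivial identity; the
round-trip tolerance of 1% is an honest statement about the integrator, not
about cancellation.

## Far field, ALS profile and density correlation

`far_field_pattern()` propagates the field numerically: the scattered
far-field is $S(k_x, k_y) = \mathcal{F}[E]$, with centred axes in rad/µm and
an unnormalised-transform convention under which
$\sum |E|^2 = \sum |S|^2 / N$ (checked as a standing Parseval test).
`angular_profile()` converts the pattern to an angular light-scattering
(ALS) profile by averaging intensity over rings of constant wave vector

$$q = \frac{4\pi}{\lambda}\sin(\theta/2),
\qquad k_r = \frac{2\pi}{\lambda}\sin\theta,$$

discarding evanescent bins ($\sin\theta > 1$). Ring bins are one frequency
pixel wide and empty bins are dropped — deterministic and matched to the
grid resolution. We average intensity $|S|^2$, not modulus.

`density_correlation()` realises the density–density correlation through
the Wiener–Khinchin relation: the inverse 2D transform of the full 2D
intensity pattern is the complex spatial autocorrelation of the field on
the image grid. We take its **modulus** (guaranteeing positivity for the
log-log fit), radially average over lag radius, normalise by the zero-lag
value and retain lags between one pixel and half the field of view. A 1D
transform of the 1D ALS curve would only agree for exactly isotropic
patterns; the 2D route is the exact ensemble average and is validated
against brute-force shift–multiply–sum autocorrelation (identical to
~1e-16 on the same realisation).

## Fractal dimension and the fractal window

For a mass-fractal object the density correlation decays as a power law,
$C_\rho(r) \propto r^{-\alpha}$, and the fractal dimension follows as

$$\mathrm{FD} = 3 - \alpha .$$

`fit_overall_fd()` estimates $\alpha$ by ordinary least squares of
$\log_{10} C$ on $\log_{10} r$; the mean squared log-log residual
(`fd_mse2`) measures how well fractal scaling holds across all probed
scales. The default analysis range is $r_\mathrm{lo} = 2\times$ pixel pitch
(below that, scales are not resolved) to $r_\mathrm{hi} =$ the equivalent
cell radius from the segmentation mask, or a quarter of the field of view
when no mask is supplied.

Cells are self-similar only over a limited band of scales — the *fractal
window* (FW). `detect_fractal_window()` computes local slopes from centred
$(2w+1)$-bin regressions (default $w = 2$), marks bins whose local slope is
at least as steep as the overall slope as eligible (this excludes the flat
short- and long-distance segments), and selects the contiguous eligible run
maximising the prominence integral
$\sum (s_\mathrm{overall} - s(r))\,\Delta\log_{10} r$. Ties go to the
longer run, then the smaller $r_\mathrm{min}$; eligibility is closed under
equality so a pure power law yields the full analysis range. A run must
span at least 5 bins *and* 0.3 decades; if nothing qualifies the whole
analysis range is returned flagged as a fallback, which makes the
within-window fit degrade gracefully to the overall fit.

### The 17-feature catalog (version 1)

`fractal_profile()` emits, in fixed order: `fd`, `fd_mse2`, `fd_with_fw`,
`fd_fw_mse`, `fw_width`, `fw_r_min`, `fw_r_max`, `fd_width`,
`fw_prominence`, then eight ALS statistics (`als_log_mean`, `als_log_sd`,
`als_log_skew`, `als_log_kurt`, `als_slope`, `als_frac_lowq`,
`als_frac_midq`, `als_frac_highq`). The first five fractal-fit quantities
are the ones named in the field's literature; the remainder complete the
catalog with window geometry, fit diagnostics and log-domain ALS moments so
that the profile keeps its 17-dimensional shape while every entry has an
explicit, reproducible formula. `fd_width` is defined here as
$|\mathrm{FD} - \mathrm{FD\ with\ FW}|$ — the divergence between global
and in-window scaling. ALS band fractions split the propagating $q$ range
at its 1/3 and 2/3 quantiles by default (`q_cuts`), a parameter-free
partition.

## Bulk dry-mass morphology

The optical path length is $\mathrm{OPL} = \phi\,\lambda/2\pi$; dividing by
the specific refractive increment of biomolecules
($\gamma \approx 0.19\ \mathrm{ml\,g^{-1}} = 0.19\ \mathrm{\mu m^3\,pg^{-1}}$)
gives the dry-mass surface density $\sigma = \mathrm{OPL}/\gamma$ in
pg/µm². A 4–8 nm optical-path sensitivity therefore corresponds to
$\sigma \approx 0.021$–$0.042\ \mathrm{pg\,\mu m^{-2}}$ — note the unit:
dimensional analysis requires pg per *square micrometre* (a figure
sometimes misprinted as pg mm⁻²). Segmentation uses Otsu's threshold on the
phase map by default (largest connected component, holes filled); the
threshold method is a pragmatic stand-in — any mask source can be passed
downstream.

## Synthetic phantoms: what they emulate, and what they do not

* **Sphere phantoms** (`sphere_phantom()`) are weak-phase projections of a
  homogeneous ball (anomalous-diffraction regime): phase
  $= (2\pi/\lambda)\,\Delta n\,2\sqrt{R^2-\rho^2}$, amplitude 1. Their FTLS
  output is validated on **minima positions** against the Airy prediction
  $\sin\theta = 0.61\lambda/R$, and the Mie series (`mie_amplitudes()`,
  truncation $N = \lceil x + 4x^{1/3} + 2\rceil$, logarithmic-derivative
  downward recurrence) is cross-checked against an independent
  Bessel-function implementation (1e-6 on $Q_\mathrm{ext}$) and the
  Rayleigh $1 + \cos^2\theta$ limit at $x = 0.05$. Absolute scattered
  intensities are *not* compared — the projection phantom is scalar, not
  vectorial. The validation geometry is a 64×64 grid at 0.2 µm pitch with
  $R = 12$ px: one q-bin is 0.49 rad/µm there, and the ball-projection
  first zero ($kR = 4.49$) sits within one bin of the Airy zero
  ($kR = 3.83$); at smaller $R/$grid ratios ring-grid quantisation can
  push the two apart.
* **Fractal phantoms** (`fractal_phantom()`) shape a complex Gaussian
  spectrum by $k_r^{-\beta/2}$, giving a phase field with isotropic
  power-law spectrum $\sim k_r^{-\beta}$, rescaled to 1.5 rad RMS (a
  typical quantitative-phase contrast for cells) and windowed by a
  cosine-tapered disk envelope standing in for the cell boundary.
* **Cohorts** (`synth_cohort()`) draw Gaussian feature vectors per class
  with prescribed shifts — the substrate for the profiling statistics.

**Direction of FD versus $\beta$.** The estimator correlates the complex
field $e^{i\phi}$, not the phase itself. For Gaussian phase its correlation
is $e^{-D_\phi(r)/2}$ with $D_\phi$ the phase structure function: a *white*
phase field ($\beta = 0$) decorrelates within a pixel and leaves a flat
curve ($\alpha \to 0$, FD $\to 3$), while smoother fields (larger $\beta$)
decay visibly across the analysis window, steepening the log-log slope.
Pipeline FD is therefore strictly *decreasing* in $\beta$ (means 2.956,
2.913, 2.820 at $\beta = 1, 2, 3$; 20 seeds, 128 px) — monotone, with the
white-field limit at 3, and within ±0.05 of a brute-force real-space
autocorrelation fit on every realisation. Phantoms exercise the estimator
chain; they do not model sub-resolution organelle scattering, partial
coherence, flow-induced blur or vectorial effects, so passing tests
demonstrate estimator correctness, not biological fidelity.

## Profiling statistics

Effect sizes use Cliff's delta (midrank implementation, identical to pair
enumeration), which is sample-size independent — the reason it is preferred
over p-values at cytometry-scale n; no multiple-testing correction is
applied and no p-values are computed. The rank AUROC obeys
$\mathrm{AUROC} = (d + 1)/2$ exactly, ties counted ½. The "linear
regression classifier" is least squares of a ±1 indicator on z-scored
features with an intercept and the minimum-norm solution for rank-deficient
designs (duplicated features change nothing); logistic regression is
deliberately not the default. Per-feature screening orients each AUROC as
$\max(a, 1-a)$; classifier AUROCs are reported unoriented. Spearman
correlation uses average ranks; the $|\rho| > 0.6$ edge list feeds network
views. Dimensionality-reduction embeddings are out of scope — the z-scored
matrix is exported for any external embedder.

On synthetic cohorts both training-set and held-out AUROCs can be computed;
the package reports training AUROC by default and documents the
permutation-null behaviour (a 17-feature classifier on 2000 permuted labels
trains to ≈0.55, not 0.50 — the expected optimism of an unregularised fit).

## A worked example

```{r example}
field <- fractal_phantom(beta = 2, grid_size = 64, pixel_um = 0.2, seed = 7)
pattern <- far_field_pattern(field)
curve <- density_correlation(pattern)
fit <- fit_overall_fd(curve, r_lo = 0.4, r_hi = 3.2)
glance(fit)
fw <- detect_fractal_window(curve, fit)
fw
fractal_profile(field, cell_id = "phantom_7")
```

```{r plot, fig.height = 3.5}
autoplot(curve, fit = fit, fw = fw)
```

## Problem sizes and determinism

Every generator is a pure function of its specification and seed, and the
pipeline is deterministic given inputs and configuration (feature CSVs are
byte-identical across reruns; each output carries the config hash). The
validation suite uses 32–64 px grids for oracle comparisons (the
brute-force autocorrelation oracle is O(N⁴)) and 128 px grids with 20 seeds
per spectral exponent for estimator-recovery statistics — sizes at which
every quantity stabilises well below the asserted tolerances.

## Known limitations

* The phase unwrap is implicit: fields with phase excursions beyond ±π
  between neighbouring pixels alias in the forward model (the knife-edge
  model clips $|g\,\nabla\phi| \ge 1$ and warns).
* The fractal window detector assumes a single dominant scaling band; for
  curves with several equally prominent bands the tie-break (longer run,
  then smaller $r_\mathrm{min}$) is a convention, not a claim.
* Otsu-on-phase segmentation under-segments low-contrast cells; masks from
  any external tool can be substituted.
* The 17-feature catalog is versioned (`catalog_version` attribute);
  feature definitions beyond the five literature-named ones are this
  package's own, stated above.
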