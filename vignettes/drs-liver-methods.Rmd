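---
title: "Methods: dielectric relaxation analysis of liver injury"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dielectric relaxation analysis of liver injury}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drsliver)
```

## The measurement and the model

Dielectric relaxation spectroscopy (DRS) with an open-ended coaxial probe
measures the complex relative permittivity of tissue,
$\varepsilon^*(f) = \varepsilon'(f) - j\,\varepsilon''(f)$, over a broad
microwave band. The real part stores field energy; the imaginary part
dissipates it, and is interchangeable with the dielectric conductivity
$\sigma(f) = 2\pi f \varepsilon_0\, \varepsilon''(f)$ (S/m), the quantity
the group statistics operate on. `drsliver` works on the 200 MHz–14 GHz
band with a default 167-point grid (`drs_grid()`), the working range of a
DAK 3.5 probe combined with an R140 vector network analyzer. The
instrument sweep spacing is not fixed by the hardware, so the grid is
configurable between linear (default) and logarithmic spacing.

Between 200 MHz and 14 GHz, liver tissue shows two overlapping
dispersion processes: the tail of the β-region, driven by molecules
larger than water (proteins, organic acids such as lactate, bound water),
and the γ-region relaxation of tissue water. Both are modeled jointly by
a two-pole Cole–Cole equation

$$\varepsilon^*(\omega) = \varepsilon_\infty +
  \frac{\Delta\varepsilon_1}{1 + (j\omega\tau_1)^{1-\alpha_1}} +
  \frac{\Delta\varepsilon_2}{1 + (j\omega\tau_2)^{1-\alpha_2}},
  \qquad \omega = 2\pi f,$$

where pole 1 (enforced $\tau_1 > \tau_2$) is the slow, low-frequency
process and pole 2 the water process. The broadening exponents
$\alpha_k \in [0, 1)$ describe the spread of relaxation times that
mixtures of water with biological solutes exhibit; $\alpha = 0$
degenerates to the Debye model used for pure water. The complex power
uses the principal branch, and the sign convention stores
$\varepsilon'' \ge 0$. No static (ionic) conductivity term and no
temperature correction are included: temperature is carried as metadata
only, and the model is intended for spectra acquired at a controlled
37.5&nbsp;°C.

## Fitting

`fit_cole_cole()` minimizes the unweighted stacked residual
$[\varepsilon'_{\mathrm{model}}-\varepsilon'_{\mathrm{data}};\;
\varepsilon''_{\mathrm{model}}-\varepsilon''_{\mathrm{data}}]$ with the
bounded Levenberg–Marquardt implementation in `minpack.lm`. Fitting the
two components jointly uses all the information the complex measurement
carries; because a loss-only convention is also defensible, a
`scale = "loss"` mode fits $\varepsilon''$ alone. Residuals are
deliberately unweighted: over this band $\varepsilon'$ and
$\varepsilon''$ have comparable magnitudes, so neither component
dominates.

Numerical choices that matter:

* **Parameterization.** Relaxation times are optimized as
  $\log_{10}\tau$. They span picoseconds to the microsecond bound, and
  the log transform keeps the Jacobian columns commensurate.
* **Bounds** (defaults, `default_fit_bounds()`):
  $\Delta\varepsilon \ge 0$, $\tau \in [0.1\ \mathrm{ps}, 1\ \mu s]$,
  $\alpha \in [0, 0.5]$, $\varepsilon_\infty \in [1, 20]$. They exclude
  unphysical optima without constraining realistic tissue values.
* **Initialization** (`initialize_parameters()`). The obvious start
  $\varepsilon_\infty \leftarrow \min \varepsilon'$ fails here: at
  14 GHz the band still sits *below* the water relaxation peak
  (a 7 ps pole peaks near 23 GHz), so the band minimum of
  $\varepsilon'$ is far above the true $\varepsilon_\infty$ and strands
  the optimizer in a wrong basin. Instead, the water pole is seeded at
  its characteristic liver values ($\tau_2 = 8$ ps, $\alpha_2 = 0.16$)
  and $(\varepsilon_\infty, \Delta\varepsilon_2)$ are solved from the
  real-permittivity model at two anchor frequencies (≈2 GHz, where the
  slow pole has fully relaxed, and the top of the band). The slow pole is
  then seeded from the static-limit estimate with $\tau_1 = 1$ ns and
  $\alpha_1 = 0.06$. On noise-free synthetic liver spectra this start
  recovers all seven parameters to machine precision (tested to 0.1%).
* **Convergence.** Step and residual tolerances $10^{-10}$, at most 2000
  function evaluations. Non-convergence is reported through the
  `converged` flag, never silently.
* **Identifiability and pole relabeling.** After fitting, poles are
  relabeled so $\tau_1 > \tau_2$ (ties broken by assigning the larger
  strength to the water pole). Because the band covers the water pole
  well but only the upper flank of the slow pole, $\Delta\varepsilon_2$
  and $\tau_2$ are strongly identified while $\varepsilon_\infty$ and
  $\alpha_1$ are weak: at the study's measurement-noise level the water
  pole is recovered within 10% and the slow pole's strength and time
  within 25%, but $\alpha_1$ (a small number near 0.06) can be off by
  ~±0.03 absolute. The reported 95% confidence intervals —
  $t$-quantile × standard errors from $(J^TJ)^{-1}s^2$ at the optimum,
  computed on the internal scale and back-transformed (so $\tau$
  intervals are asymmetric) — reflect this.
* **Degenerate inputs.** A spectrum with zero variance in the stacked
  observation vector leaves $R^2$ undefined; the fit is flagged
  `degenerate` with a warning.

Goodness of fit is the coefficient of determination on the stacked
vector, $R^2 = 1 - SS_{res}/SS_{tot}$ with $SS_{tot}$ about the stacked
mean (`compute_r_squared()`); the component scale is configurable because
conventions vary.

## Water content

Ischemia–reperfusion injury redistributes tissue water, so an
edema-sensitive summary is extracted from the fitted model:

$$\mathrm{water\ content}\,[\%] =
  \frac{\sum \varepsilon''_{\mathrm{water\ pole\ in\ liver}}}
       {\sum \varepsilon''_{\mathrm{deionized\ water}}} \times 100 .$$

The numerator is the pole-2 loss from `separate_dispersions()`, the
denominator the deionized-water loss, both summed over the identical
grid. The plain (unweighted) sum is the literal definition and the
default; on the linear default grid it is proportional to a trapezoidal
integral, and an explicit `method = "trapezoid"` is available for
non-uniform grids. The water reference is either a measured spectrum
(never regridded — grids must match exactly) or a single-pole Debye
model; the shipped parameters at 37.5 °C
($\varepsilon_s = 74.0$, $\varepsilon_\infty = 5.2$, $\tau = 6.2$ ps,
`water_debye_default()`) are literature-typical values for pure water
near body temperature. Either convention for the denominator (measured
curve or fitted Debye) is therefore supported.

The estimator is exactly linear in $\Delta\varepsilon_2$ and independent
of the slow pole by construction. It *underestimates* gravimetric water
content — tissue water is partially bound and relaxes more slowly than
free water, shifting loss out of the summation window — so only relative
comparisons between groups and timepoints are meaningful. No bound-water
correction is applied.

## Group statistics

Replicate spectra (2 sites × 10 replicates per liver and timepoint) are
averaged pointwise into one liver-level spectrum before any analysis;
this is also the spectrum that is fitted. Conductivity trends are
expressed as the relative change
$\Delta\sigma = (\sigma - \sigma_{\mathrm{control}})/
\sigma_{\mathrm{control}} \times 100\%$ against the per-frequency mean
conductivity of the control livers at in vivo hour 1 — the stable,
perfused baseline. The change is computed per liver against that common
reference and then summarized per group (mean and standard error over
the N = 7 liver-level values), which makes the operation invariant to
record order.

Hypothesis tests are run independently at each frequency point: a
two-factor (group × hour) fixed-effects ANOVA in its cell-means form on
liver-level conductivities, with the requested pairwise contrast tested
by a pooled-variance $t$ statistic. The exact ANOVA design is a genuine
design choice — a repeated-measures model over hours would also be
defensible — but per-frequency, per-group summaries with N = 7 livers
per cell are what the fixed-effects cell-means model matches, and it
keeps degenerate cells detectable (zero residual variance yields p = 0
or 1 with a warning). The Šidák correction
$p_{adj} = 1 - (1-p)^m$ is applied over the contrast family; the family
size defaults to 6 for within-group hourly pairs and 4 for between-group
hourly contrasts, and is configurable because the family definition is a
reporting convention. Contiguous significant grid points (p < 0.05) are
merged into frequency ranges and rendered as e.g. `"8.25-14 GHz"` or
`"NS"`. Under a simulated null the Šidák-corrected family is slightly
conservative (the six pairwise contrasts share cell means and the pooled
variance, so they are positively correlated), which the test suite
verifies as a familywise error rate at or below 0.06 over 500
replicates.

Liver weights (pre/post machine perfusion) are summarized as group means
with `mean_increase = mean_post − mean_pre` exactly.

## The synthetic study generator

No public broadband dielectric dataset of livers under machine perfusion
exists, so the package ships a generator (`generate_study()`) that
emulates the experiment the analysis assumes: 3 groups — healthy
controls (CON), hepatic-artery occlusion / biliary injury (AHEP), and
prolonged static cold storage / global injury (SCS) — × 7 livers ×
(in vivo and normothermic machine perfusion) × hours 1–4 × 2 sites × 10
replicates on the 167-point grid, i.e. 3360 spectra.

* **Baseline ground truth** (`liver_baseline_default()`):
  $\varepsilon_\infty = 4$, $\Delta\varepsilon_1 = 15$,
  $\tau_1 = 0.8$ ns, $\alpha_1 = 0.06$, $\Delta\varepsilon_2 = 37.614$,
  $\tau_2 = 7$ ps, $\alpha_2 = 0.16$. The broadening values and water
  relaxation time are the characteristic liver values; the water-pole
  strength is calibrated once so that the baseline water-content
  estimate against the default reference equals the healthy-liver level
  of 56.05%.
* **Trend profiles** (`default_trend_profiles()`) are data, not code:
  per (group, phase, hour) target relative conductivity changes at the
  two band edges, converted into multiplicative adjustments of the two
  pole strengths by solving a 2×2 system in the baseline pole shares.
  The shipped numbers are calibrated to the qualitative course of the
  experiment (controls drifting to ~7.5% low-band in vivo, AHEP rising
  to ~17%, an initial low-band drop / high-band rise on perfusion that
  resolves in controls but not in the injury groups). They are
  calibration targets, not mechanistic predictions.
* **Variability.** Inter-liver spread is lognormal (mean 1, CV 5%) on
  the four scale parameters plus a small additive jitter (SD 0.005) on
  the broadening exponents; measurement noise is multiplicative Gaussian
  (SD 1%) independent per frequency point and component, chosen for
  scale-invariance across the three-decade band (a correlated-noise
  model would be a natural extension). Outputs are clipped to physical
  ranges. The magnitudes of the inter-liver terms are realistic
  placeholders; true inter-animal variability is not published.
* **Weights** are Normal around the recorded group means (CON
  1666.9 → 1755.3 g, AHEP 1648.9 → 1774.3 g, SCS 1625.7 → 1790.0 g)
  with SD 60 g.
* **Reproducibility.** The dataset is a pure function of the
  configuration: liver multipliers are drawn in a fixed order from the
  seed, so `ground_truth()` can re-derive the exact parameters of any
  cell for parameter-recovery checks.

What the generator does **not** emulate — and hence what passing tests
cannot certify about real measurements: probe–tissue contact artifacts,
calibration drift between hourly sessions, spatial heterogeneity of
perfusion within a lobe, correlated (non-independent) spectral noise,
ionic conductivity at the low band edge, and any mechanistic link
between injury biology and the dielectric parameters. The generator
demonstrates that the pipeline recovers what was injected; it cannot
validate the biology.

## Problem sizes and runtime choices

The shipped tests and the acceptance script run the full default study
(3360 spectra; 168 liver-level fits), 50-draw parameter-recovery sweeps,
a 500-replicate null calibration of the Šidák family at a single
frequency, and a 20-replicate end-to-end trend-recovery study. These
sizes match the emulated experiment (N = 7 per group is the design
size); each fit takes a few milliseconds, so the complete suite runs in
about a minute on one core.

## Known limitations

* Absolute water content is systematically underestimated; only
  within-study contrasts are interpretable.
* $\alpha_1$ and $\varepsilon_\infty$ are weakly identified from a band
  that ends at 14 GHz; confidence intervals for them are wide and
  grid-spacing-sensitive.
* The per-frequency tests ignore correlation across frequencies; the
  reported ranges are descriptive, not a joint inference over the band.
* No model selection across pole counts is attempted, and
  Kramers–Kronig consistency is not enforced on inputs.
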