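# drsliver

Analysis of broadband dielectric relaxation spectroscopy (DRS) for
assessing liver ischemia–reperfusion injury, in vivo and during
normothermic machine perfusion (NMP).

Donor livers are discarded when their viability cannot be judged
reliably. Microwave dielectric spectra (200 MHz–14 GHz, open-ended
coaxial probe) are sensitive to the concentration and mobility of polar
molecules in tissue, and therefore to ischemic injury and edema.
`drsliver` implements the full analysis chain for such experiments, for
researchers working on organ viability assessment:

* **Two-pole Cole–Cole modeling** of complex permittivity
  $\varepsilon^*(\omega) = \varepsilon_\infty +
  \frac{\Delta\varepsilon_1}{1+(j\omega\tau_1)^{1-\alpha_1}} +
  \frac{\Delta\varepsilon_2}{1+(j\omega\tau_2)^{1-\alpha_2}}$,
  fitted by bounded Levenberg–Marquardt with 95% confidence intervals
  and stacked-residual $R^2$ (pole 1: large molecules / β-region;
  pole 2: tissue water / γ-region).
* **Dispersion separation and water-content estimation**:
  $\mathrm{water}[\%] = \sum\varepsilon''_{\mathrm{water\ pole}} /
  \sum\varepsilon''_{\mathrm{deionized\ water}} \times 100$ against a
  Debye water reference at 37.5 °C.
* **Conductivity trend analysis**: $\sigma = 2\pi f\varepsilon_0
  \varepsilon''$, relative change
  $\Delta\sigma = (\sigma-\sigma_{\mathrm{control}})/
  \sigma_{\mathrm{control}}\times 100\%$ against the in vivo hour-1
  control reference, summarized per group (N = 7, mean ± SE).
* **Per-frequency group statistics**: two-factor (group × hour) ANOVA
  on liver-level conductivities, Šidák-corrected pairwise contrasts, and
  merging of significant grid points into frequency ranges
  (`"8.25-14 GHz"` / `"NS"`).
* **A synthetic study generator** emulating the porcine experiment
  (3 groups × 7 livers × 8 hourly timepoints × 2 sites × 10 replicates
  on a 167-point grid) with seeded ground truth, so the entire pipeline
  is testable without any measurement data.

## Worked example

```r
library(drsliver)

# a full synthetic study: control (CON), biliary injury (AHEP),
# static-cold-storage injury (SCS)
study <- generate_study(study_config(seed = 42))

# liver-level spectrum = mean of 2 sites x 10 replicates, then fit
liver <- average_replicates(study, "CON-1", "invivo", 1)
fit <- fit_cole_cole(liver)
fit
#> <drs_fit> converged after 6 iterations (R^2 = 0.999980)
#>               estimate      lower      upper
#> eps_inf     4.0090e+00 3.7011e+00 4.3169e+00
#> delta_eps_1 1.6093e+01 1.5632e+01 1.6554e+01
#> tau_1       8.2906e-10 8.0374e-10 8.5518e-10
#> alpha_1     5.7038e-02 4.3876e-02 7.0199e-02
#> delta_eps_2 3.4344e+01 3.3945e+01 3.4743e+01
#> tau_2       7.4964e-12 7.4033e-12 7.5906e-12
#> alpha_2     1.5980e-01 1.5454e-01 1.6505e-01
```

The fit reproduces a liver-like spectrum almost exactly
($R^2 > 0.9999$): a weak slow pole (relaxation time ~0.8 ns) under a
dominant water pole at 7.5 ps with moderate broadening
($\alpha_2 \approx 0.16$), all inside physically plausible bounds.

```r
# water content from the separated water dispersion
ref <- water_reference(study$grid)
estimate_water_content(fit, ref)
#> <water_content_estimate> 52.86% (grid 2e+08-1.4e+10 Hz, 167 points)
```

~53% is a typical DRS estimate for a healthy liver: the method
underestimates gravimetric water content (bound water relaxes out of
band) but tracks relative edema changes between groups and hours.

```r
# where do control and biliary-injured livers differ after 4 h of NMP?
per_frequency_anova(study, list("CON", 4, "AHEP", 4), "NMP",
                    family_size = 4)
#> <drs_comparison> CON 4 h vs AHEP 4 h, NMP (Sidak m = 4, p < 0.05)
#>   significant: 7.93-8.01 GHz; 8.18-8.18 GHz; 8.35-8.35 GHz;
#>   8.51-8.6 GHz; 8.76-8.76 GHz; 8.93-9.18 GHz; 9.34-14 GHz

weight_summary(study$weights, group = "SCS")$mean_increase
#> [1] 199.3925   # grams gained over machine perfusion
```

The injured group separates from controls in the upper frequency band —
where the water pole dominates — matching the elevated water content and
weight gain of injured livers. `run_pipeline(study, out_dir = "report")`
runs every stage (168 fits, water-content and relative-change tables,
all comparison tables, weight summaries) and writes the report bundle as
CSV/JSON. A thin command-line wrapper with `simulate` and `report`
subcommands ships in `inst/scripts/drs-pipeline.R`.

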