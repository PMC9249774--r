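Package: drsliver
Title: Dielectric Relaxation Spectroscopy Analysis of Liver
    Ischemia-Reperfusion Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of broadband (200 MHz-14 GHz) complex permittivity
    spectra of liver tissue measured with an open-ended coaxial probe.
    Provides two-pole Cole-Cole relaxation modelling with bounded
    Levenberg-Marquardt fitting and 95% confidence intervals, separation
    of the low-frequency (large-molecule) and high-frequency (water)
    dispersions, dielectric-loss-based water-content estimation against a
    deionized-water Debye reference, relative-conductivity trend analysis,
    per-frequency two-way ANOVA with Sidak-corrected pairwise contrasts
    and significant-frequency-range reporting, and a synthetic study
    generator emulating a three-group porcine liver experiment monitored
    in vivo and during normothermic machine perfusion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    MASS,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
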