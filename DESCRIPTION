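Package: rhinoflow
Title: Rhinomanometry Pressure-Flow Modelling and Nasal Airflow Resolution Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Models rhinomanometry (RMM) pressure-flow curves with an unsteady
    Bernoulli duct model of nasal airflow: Darcy friction factors with
    laminar/turbulent/blended regimes (Haaland correlation), Hagen-Poiseuille
    resistance, hysteresis widths caused by the inertial term, and the
    Reynolds and Womersley numbers that characterise the flow regime.
    Generates synthetic tidal-breathing RMM time series with optional
    measurement noise, measures hysteresis widths from pressure-flow loops,
    and fits hydraulic diameter and effective channel length to RMM data by
    fixed-length and hysteresis-constrained least squares. A companion
    diagnostics module computes the dimensionless audit battery used to judge
    nasal-airflow CFD resolution (wall units and the law of the wall, CFL
    numbers, Kolmogorov microscales, WALE mixing lengths, and
    resolution-ratio histograms with exceedance fractions) from per-cell
    summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
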