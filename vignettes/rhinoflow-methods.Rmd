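---
title: "Modelling rhinomanometry curves with an unsteady Bernoulli duct"
author: "rhinoflow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling rhinomanometry curves with an unsteady Bernoulli duct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhinoflow)
```

## The model

Rhinomanometry (RMM) records the transnasal pressure drop $\Delta P$ against
the volumetric flowrate $Q$ over the breathing cycle. `rhinoflow` represents
the nasal passage as a straight, rigid duct of hydraulic diameter
$D_h = 4A/O$, length $L$ and relative wall roughness $\epsilon_r$, and models
the pressure drop of unsteady, fully developed, incompressible flow through
it as the sum of a friction term and an unsteady inertial term:

$$\Delta P \;=\; L\left[\frac{8\rho\, f_D\, Q\lvert Q\rvert}{\pi^2 D_h^5}
  \;+\; \frac{4\rho}{\pi D_h^2}\,\frac{\partial Q}{\partial t}\right].$$

The Darcy friction factor $f_D$ is $64/Re$ in laminar flow
($Re = 4\lvert Q\rvert/(\pi\nu D_h) \le 2000$), the Haaland correlation

$$\frac{1}{\sqrt{f_D}} = -1.8\,\log_{10}\!\left[\left(\frac{\epsilon_r}{3.7}\right)^{1.11}
  + \frac{6.9}{Re}\right]$$

in turbulent flow ($Re \ge 4000$), and a smooth weighted average of the two
in the transitional band. For steady laminar flow the model reduces exactly
to the Hagen–Poiseuille resistance $R = 128 L \mu/(\pi D_h^4)$, so steady
laminar pressure–flow curves are straight lines through the origin.

With sinusoidal breathing $Q = Q_{max}\sin\omega t$
($\omega = 2\pi/\tau$), the unsteady term opens the pressure–flow curve into
a closed loop that does not pass through the origin. Evaluating the model at
$Q = 0$ gives the analytic hysteresis width and its normalised form

$$W = \frac{8\rho L \omega Q_{max}}{\pi D_h^2}, \qquad
  W_{rel} = \frac{W}{R\,Q_{max}} = \frac{\omega D_h^2}{16\nu},$$

so the relative width depends only on the hydraulic diameter and the
breathing period. These two relations are the backbone of the package: the
generator produces loops whose measured width must converge to $W$, and the
hysteresis-constrained fit uses $W$ to eliminate the unknown channel length,

$$\Delta P = \frac{W}{\omega Q_{max}}\left(\frac{f_D\, Q\lvert Q\rvert}{\pi D_h^3}
  + \frac{1}{2}\frac{\partial Q}{\partial t}\right), \qquad
  L = \frac{W \pi D_h^2}{8 \rho\, \omega Q_{max}}.$$

### Assumptions

The duct surrogate assumes fully developed, single-phase, isothermal,
incompressible flow in a rigid channel of constant cross-section. None of
these hold exactly in a nasal cavity: cross-sections vary dramatically along
the passage, walls are compliant mucosa, and flow is developing rather than
fully developed. The model is therefore an *interpretive* tool — it gives
the effective $(D_h, L)$ of the equivalent duct that best explains a
measured curve, not anatomical dimensions. Recovered effective lengths
shorter than the anatomical passage are expected and diagnostic of the
model's scope rather than a numerical failure.

## Parameters that matter

| Parameter | Meaning | Unit | Default |
|---|---|---|---|
| $\rho$, $\mu$ | air density, dynamic viscosity | kg m⁻³, Pa s | 1.225, 1.7894×10⁻⁵ (`air_properties("cfd")`) |
| $\nu$ | kinematic viscosity | m² s⁻¹ | derived $\mu/\rho$; `"rounded"` preset fixes 1.5×10⁻⁵ |
| $D_h$ | hydraulic diameter | m | 0.01 (a patent adult passage) |
| $L$ | effective channel length | m | 0.1 (the conventional fitting assumption) |
| $\epsilon_r$ | relative roughness | – | 0 (smooth mucosa) |
| $Q_{max}$ | peak flowrate | m³ s⁻¹ | 600×10⁻⁶ (restful unilateral tidal breathing) |
| $\tau$ | breathing period | s | 5 |
| blend band | laminar→turbulent transition | Re | 2000–4000 |

The two air presets differ only in rounding; the `"rounded"` preset exists
because order-of-magnitude conventions (Womersley numbers, relative
hysteresis widths) are usually quoted at $\nu = 1.5\times10^{-5}$ m² s⁻¹.
The default protocol ($Q_{max} = 600$ mL s⁻¹, $\tau = 5$ s) gives a tidal
volume $Q_{max}\tau/\pi \approx 955$ mL — deliberately above quiet-breathing
volumes, matching the protocol used for transient unilateral simulation
(`protocol_preset("tidal_cfd")`, which adds the 1 s phase offset and three
cycles of the negative-cosine waveform, in whose sign convention negative
flow is inhalation).

## The synthetic-data generator

`generate_rmm_timeseries()` samples the protocol waveform on a uniform grid
(1000 samples per cycle by default), evaluates the analytic flow derivative,
and computes each sample's pressure with the model above. It emulates:

* four-quadrant clinical curves via `to_clinical_quadrants()` — inspiration
  plots at positive pressure, expiration negative; right side at positive
  flow ordinate, left side negative;
* transducer noise, as additive Gaussian pressure noise per sample;
* breath-to-breath variability (nasal cycle, posture, mucosal state), as a
  per-cycle multiplicative jitter of $D_h$ with a chosen coefficient of
  variation.

It does **not** emulate asymmetric or plateaued in-vivo waveforms,
compliance-induced flow limitation (collapse), intra-breath diameter
variation, or instrument-specific artefacts. Passing tests on synthetic data
therefore demonstrate that the estimation pipeline is *self-consistent* —
it recovers the parameters of data its own model generated, at the stated
noise levels — not that the duct model captures all real nasal physics.

Loop direction follows directly from the model: at the zero-flow crossing
into the accelerating half-cycle the unsteady term is positive, so the
accelerating branch carries the higher pressure. The generator makes no
attempt to arbitrate between conflicting loop-direction conventions reported
for clinical charts; the quadrant mapping preserves magnitudes and labels
each point with its phase and sub-phase so either convention can be drawn.

## Numerical choices

* **Friction at zero flow.** $64/Re$ diverges as $Q \to 0$, but the laminar
  friction *term* is linear in $Q$: the implementation evaluates it
  analytically as $128 L \mu Q/(\pi D_h^4)$, which is algebraically
  identical and finite everywhere, so the blended policy needs no special
  case at flow reversal. The friction term is written $f_D\,Q\lvert Q\rvert$
  so dissipation opposes the flow in both directions.
* **Transitional taper.** The blend weight is a half-cosine in $Re$ over
  [2000, 4000]: continuous, monotone, and parameter-free. Both bounds and a
  linear taper are configurable.
* **Optimiser.** Both fits are single-parameter least squares in $D_h$,
  solved with bounded Brent minimisation (`stats::optimize`) on
  $D_h \in [1, 30]$ mm with a $10^{-6}$ m tolerance: derivative-free,
  bracketed and deterministic, so identical inputs give identical fits.
  The objective is unweighted by default; $\lvert Q\rvert$ weighting is
  available as a flag.
* **Width measurement.** Zero crossings of $Q$ are located by linear
  interpolation between bracketing samples; the width of a cycle is the
  difference of its two crossing pressures, and multi-cycle series report
  the per-cycle mean. On the default grid the measured width converges to
  the analytic $W$ at second order in the sample spacing.
* **Resistance read-off.** `resistance_at()` interpolates linearly in flow
  along one monotone branch (accelerating or decelerating) and refuses
  zero-flow or out-of-range references rather than extrapolating.
* **Law of the wall.** The buffer layer (5 < $y^+$ < 35) follows neither
  the linear nor the log law; values there are linear interpolation in
  $\ln y^+$ between the two laws at the layer bounds and always carry an
  explicit `"buffer"` flag, since wall-adjacent cells in this band are a
  known source of wall-shear misrepresentation.
* **Resolution histograms.** Bin width defaults to 0.1 with 0.01
  selectable; exceedance fractions are computed from the raw ratios and are
  invariant to binning. Cells with $\epsilon = 0$ are laminar: they are
  excluded from the ratios and counted separately, never treated as ratio 0.
* **Degenerate inputs.** Occluded sides are explicit `NA` markers, not 0 or
  infinity; zero hysteresis width degenerates the constrained fit with an
  error; unidirectional series have no defined width; fully laminar cell
  populations have no defined resolution ratios.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data at
deliberately modest sizes: 1000 samples per breathing cycle for single-loop
checks, 24 parameter combinations for the width oracle grid, 20 noise
replicates for the noisy-recovery check, 100 breaths for the
jitter-propagation check, and 100–200 cells for resolution reports. These
sizes put interpolation error well below the 1% width tolerance and keep
every check comfortably reproducible on a single CPU.

## Known limitations

* The duct model omits minor losses (bends, area changes) and any
  pressure-dependence of $D_h$; it cannot reproduce flow-limited
  (plateaued) in-vivo curves.
* The hydraulic-diameter/Reynolds framework itself is of limited validity
  for strongly non-circular nasal cross-sections; fitted parameters are
  effective values.
* Phase labelling of imported data relies on a sign convention
  (`inspiration_sign`); clinical exports with explicit phase columns
  override it.
* The resolution diagnostics audit per-cell summary tables; they do not
  compute dissipation rates or wall shear from flow fields, which is solver
  territory.
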