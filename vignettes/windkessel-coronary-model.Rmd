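---
title: "Windkessel electrical-equivalent modelling of coronary flow"
author: "coroflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windkessel electrical-equivalent modelling of coronary flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coroflow)
```

## The model

`coroflow` represents a patient's coronary circulation as a lumped-parameter
("zero-dimensional", Windkessel) electrical circuit. The hydraulic/electrical
dictionary is the standard one: pressure drop in dyn/cm² plays the role of
voltage, volumetric flow in cm³/s the role of current, viscous hydraulic
resistance in dyn·s/cm⁵ the role of electrical resistance, and vessel or
chamber compliance (volume stored per unit pressure) the role of capacitance.

Each vessel segment — a stretch of artery between branch points, described by
a length $l$ (cm) and a mean lumen radius $r$ (cm) — contributes a Poiseuille
resistance

$$R = \frac{8\mu l}{\pi r^4},$$

with $\mu$ the working-fluid viscosity in poise. For a diseased segment, $r$
is the mean radius along the stenosis, so a lesion appears implicitly as a
high-resistance segment rather than as a separate object. Because $R$ scales
with $r^{-4}$, a halved radius multiplies resistance by 16; this is the lever
through which stenoses dominate a path's hydraulics.

The segment's wall compliance comes from the printed-material area compliance
$c_A$ (mm²/mmHg, default 0.0975 — the midpoint of the healthy-vessel range
0.075–0.120 replicated by soft photopolymers): the volume compliance is
$C = c_A\,l$ converted to CGS units. Resistance and compliance combine into a
single scalar impedance magnitude at the fundamental cardiac frequency,

$$Z = \frac{1}{\sqrt{(1/R)^2 + (2\pi C/T_c)^2}},$$

with $T_c$ the cardiac period (default 0.8 s, i.e. 75 bpm; the period is not
otherwise constrained by the model and is configurable). $Z \le R$ always,
$Z \to R$ as $C \to 0$, and $Z \to T_c/(2\pi C)$ as $R \to \infty$.

The analysis mode is deliberately *steady mean-flow on impedance magnitudes*,
not time-domain ODE integration: every element is a single positive scalar,
the source is the mean aortic pressure (default 100 mmHg), and the solved
currents are mean flows. This matches a design whose outputs are
single-number flow rates per activity state; pulsatile waveform dynamics are
out of scope. A consequence worth keeping in mind is that "pressure" in the
flow equation always means the *drop across a path*, never an absolute
pressure — using absolute distal pressure would predict nonzero flow at an
FFR of 1, which is unphysical.

## Network assembly

`build_network()` turns a validated vessel table into a circuit:

* one impedance element per segment; children of a branch node in parallel,
  each in series with its parent;
* each main artery's leaves drain into a *collection chamber*: an inherent
  viscous resistance (LAD/LCX/RCA = 1671/1820/591 dyn·s/cm⁵) in parallel
  with a trapped-gas compliance obtained from Boyle's law,
  $$C_{ch} = \frac{P_0 V_0 (1/P_d - 1/P_s)}{P_s - P_d},$$
  with $P_0 = 760$ mmHg and $V_0 = 4.4\times10^4$ mm³ and default working
  pressures $P_s/P_d = 120/80$ mmHg (standard physiologic systole/diastole;
  the model only needs the pair's ratio structure, and users with measured
  chamber pressures can override both). The parallel pair is collapsed to
  one impedance element via the same magnitude formula;
* in series after the chamber, the *activity-state distal resistance* — the
  arteriolar/capillary bed, realisable physically as catheters spanning
  50,000–300,000 dyn·s/cm⁵. Defaults per artery: rest R = 250,000, light
  exercise E1 = 120,000, moderate exercise E2 = 60,000, monotone with
  activity and inside the realisable band. The exact per-state values used
  with any particular phantom rig are configurable per artery;
* an aortic outlet resistor from source to ground carrying non-coronary
  flow. `calibrate_outlet()` sizes it in closed form so the total source
  current equals the configured total input flow (default 8.33 cc/s);
  calibration fails loudly if the coronary bed alone already exceeds the
  target;
* the venous/ground reference is 0: with no downstream pressure specified,
  all equivalences are to ground-referenced voltage. Multiple roots of one
  artery (early branching) attach in parallel directly at the source node.

Two independent solution routes are implemented and cross-checked: exact
series/parallel reduction (with pruning of dangling dead-end nodes, which
carry no current) and a general nodal solver that stamps conductances into
the Kirchhoff system and solves it with a dense LU factorisation. Tree-built
networks always reduce fully; should reduction stall on a non-series/parallel
graph it falls back to the nodal equivalent. The suite requires the two
routes to agree to 1e-9 relative on a thousand random trees of up to 30
segments, and every solution to satisfy the current law to the same
tolerance.

### Where the material compliance sits (`compliance_mode`)

Whether wall compliance should be distributed per segment or lumped per
artery is genuinely open at this level of abstraction. The default,
`per_segment`, gives every segment its own RC pair — the finer-grained
reading. `per_artery` instead treats segments as pure resistors and adds the
artery's summed material compliance to its chamber capacitance — the reading
in which one lumped compliance terminates each artery. Both are supported;
at the default material compliance the difference in solved flows is far
below measurement noise, so the choice is about interpretation rather than
results.

## Local flow at a stenosis, three ways

For a measurement site (the location where a pressure wire would sit, just
distal to a lesion) the package reports:

* **Model (Windkessel) flow** `windkessel_site_flow()`: the solved current
  through the site's segment element.
* **Invasive-derived flow** `invasive_site_flow()`: an FFR reading gives the
  distal pressure $P_d = \mathrm{FFR}\cdot P_a$, and the flow is
  $(P_a - P_d)/Z_\text{path}$.
* **Benchtop-derived flow** `benchtop_site_flow()`: identical, with $P_d$
  taken directly from the phantom's pressure sensor (mmHg).

$Z_\text{path}$ is the **series sum of the per-segment impedance
magnitudes** along the ostium-to-site chain. An alternative would be to
apply the magnitude formula once to the cumulative resistance and cumulative
compliance of the path; we use the series-sum form because it is exactly the
series rule the network itself obeys, which makes the three methods an
internally consistent family: feeding the model's own distal pressure into
the benchtop formula recovers the model's flow to numerical precision when
the path carries all of the site's flow. At the default (tiny) material
compliance the two forms differ only around one part in 10⁵, and they
coincide exactly whenever compliance is zero.

The ratio of distal to aortic pressure predicted by the model
(`model_ffr()`) is also reported alongside the flows. Note that the ratio of
site flows between activity states is *not* the FFR — epicardial resistance
and distal resistance respond differently to vasodilation — and the
discrepancy between pressure ratios and flow ratios is left observable
rather than corrected, since it is informative about where the Poiseuille
resistance assumption (laminar flow in a rigid circular tube) strains.

FFR readings slightly above 1 occur in practice from wire drift; they are
clamped to 1 (zero gradient, zero flow) with a warning rather than rejected,
while readings above 1.2 are treated as errors.

## Method comparison

`pearson()` and `bland_altman()` compare paired flow vectors: the product-
moment correlation, and the mean difference with 95% limits of agreement
$\bar d \pm 1.96\,s_d$ using the sample (n−1) standard deviation — the
conventional Bland-Altman choice. Per-model correlations use that model's
six site-by-state flows (LAD/LCX × R/E1/E2), and the cross-model summary is
their arithmetic mean; `compare_methods()` also exposes a pooled grouping
over all site-by-state points at once, since either convention is defensible
for limits-of-agreement analysis.

## The synthetic cohort generator

No vessel-by-vessel patient geometry is publicly deposited, so the package
ships a generator (`generate_tree()`, `generate_dataset()`) that emulates
the study conditions rather than any specific patient:

* three main arteries with diameters drawn uniformly from 3–5 mm;
* 2–5 Murray-tapered daughters per artery ($r_\text{child} =
  r_\text{parent}\,2^{-1/3}$), branch segment lengths 2–12 cm;
* one stenosed segment on each of LAD and LCX with a measurement site just
  distal to it; the RCA is healthy and unsampled;
* lesion severity is solved, not drawn: each site receives a target
  hyperemic (E2-state) distal/aortic pressure ratio — LAD uniform on
  0.55–0.75, LCX uniform on 0.60–0.82 — and the stenosis radius is found by
  root-finding on the artery's own subnetwork. The targets emulate a
  catheterisation cohort dominated by hemodynamically significant disease
  (every LAD lesion significant, LCX mixed), which is the population in
  which FFR is measured at all. The solved radius is clamped to a fractional
  reduction between 0.2 and 0.7 of the parent calibre; when a large vessel
  cannot reach its target within that bound the lesion is lengthened
  instead (diffuse disease), up to 8 cm;
* measurements are the solved truth plus additive Gaussian sensor noise:
  SD 0.03 on the FFR reading and 2 mmHg on the benchtop distal pressure,
  the simplest model consistent with independent sensor error.

Daughters attach *distal* to the measurement site. This is a deliberate
idealisation: it keeps the ostium-to-site path free of take-offs, so the
invasive derivation — which can only see the path's series impedance — refers
to the same flow the model predicts at the site. Real coronary anatomy
branches proximally too; with proximal take-offs the invasive formula
attributes branch outflow to the site and the three methods disagree by the
leaked fraction. Passing the self-consistency suite therefore validates the
pipeline's internal arithmetic, not the claim that path-impedance flow
reconstruction is unbiased in branched anatomy.

Everything is a pure function of `(seed, model_index)`: trees, noise draws
and manifests reproduce bit-for-bit, and generation restores the caller's
RNG state.

## Numerical choices

* All algebra is in CGS units (cm, dyn, s); files store cm only, and
  pressures convert at 1 mmHg = 1333.22 dyn/cm². Tree files round-trip at
  full double precision (17 significant digits) in both CSV and JSON.
* The nodal system is dense; trees of interest have tens of nodes, where
  dense LU is both fastest and simplest. A singular system is reported as a
  topology error (disconnected component).
* Outlet calibration is closed-form, so conservation holds to solver
  precision (observed ~1e-13 relative) rather than to an iteration
  tolerance.
* Root-finding for lesion severity uses bisection-safeguarded `uniroot` with
  a radius tolerance of 1e-5 cm, well below segmentation accuracy.
* Validation tolerates a 1e-9 slack when checking that a site's recorded
  ostium distance does not exceed its cumulative path length, to absorb
  round-trip arithmetic.

## Problem sizes in the test suite

The suite exercises: hand-checkable 1–9 segment fixtures; 200–1000 random
trees of 3–30 segments for the reduction-vs-nodal oracle; five-model
synthetic cohorts for the pipeline properties; and 100 independently seeded
five-model studies for the correlation-recovery property. These sizes keep
the full suite around one to two minutes while leaving every property
non-trivially exercised.

## Known limitations

* Poiseuille resistance assumes laminar flow in rigid circular tubes;
  post-stenotic turbulence and wall elasticity are not modelled, and no
  nonlinear (flow-dependent) stenosis resistance is included.
* Steady magnitude analysis cannot produce waveforms, phase lags, or
  systolic/diastolic flow splits.
* Compliance is held constant across activity states.
* The distal boundary is three lumped chambers; there is no autoregulation
  or microvascular recruitment model — activity is exactly a distal
  resistance change.
* The generator reproduces topology, calibres and severity statistics, not
  anatomically realistic 3-D geometry, tortuosity, or proximal branching
  (see above); conclusions drawn from synthetic cohorts are about the
  pipeline, not about patients.
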