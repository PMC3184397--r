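---
title: "Modelling oxidative crisis in G6PD-deficient red cells: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling oxidative crisis in G6PD-deficient red cells: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxrbc)
library(dplyr)
```

## What the package models

A mature red blood cell has no mitochondria and no protein synthesis; its
entire defence against oxidative attack runs through a small, well-understood
reaction cycle. Hydrogen peroxide entering (or generated inside) the cell is
cleared by catalase (CAT) and by glutathione peroxidase (GSHpx), the latter
at the price of oxidising two reduced glutathiones (GSH) to one GSSG.
Glutathione reductase (GR) re-reduces GSSG using NADPH, and the *only*
erythrocyte source of NADPH is the oxidative pentose phosphate pathway, whose
gatekeeper is glucose-6-phosphate dehydrogenase (G6PD). A patient's G6PD
variant therefore sets how fast the cell can re-arm its redox buffer after an
oxidative hit, and the GSH/GSSG ratio is the natural readout of that contest.

`redoxrbc` implements this antioxidant core as a kinetic ODE model in µM and
seconds, runs a standardised perturbation experiment against it, and scores
each subject with three indicators of redox imbalance.

## The reduced network

The full published erythrocyte models from which this line of work descends
include glycolysis, adenine-nucleotide metabolism, ion pumps and
hemoglobin/Mg²⁺ binding. Those subsystems influence the redox cycle only
through a handful of boundary quantities (ATP, 2,3-BPG, the G6P supply), so
the package ships a deliberately reduced closure with eight dynamic species —
intracellular H₂O₂, O₂⁻, GSH, GSSG, NADPH, NADP, G6P and the lumped
6-phosphogluconolactone pool (GL6P) — and four clamped ones (extracellular
H₂O₂, ATP, 2,3-BPG, glucose). The eleven reactions:

| reaction | rate law | default parameters | notes |
|---|---|---|---|
| H₂O₂ influx | $k_d([\mathrm{H_2O_2}]_{ext}-[\mathrm{H_2O_2}]_{in})$ | $k_d = 1\,\mathrm{s^{-1}}$ | passive membrane diffusion; signed (efflux when the inside exceeds the outside) |
| O₂⁻ generation | constant | $2\,\mathrm{\mu M\,s^{-1}}$ | basal autoxidation load (e.g. hemoglobin) |
| SOD | $k[\mathrm{O_2^-}]$, 2 O₂⁻ → H₂O₂ | $k = 10\,\mathrm{s^{-1}}$ | fast, far from saturation |
| CAT | $k[\mathrm{H_2O_2}]$, 2 H₂O₂ → products | $k = 3\,\mathrm{s^{-1}}$ | first-order; catalase's Km is millimolar, so it never saturates here |
| GSHpx | two-substrate Michaelis, H₂O₂ + 2 GSH → GSSG | $V = 2\,\mathrm{\mu M\,s^{-1}}$, $K_{H_2O_2} = 1\,\mathrm{\mu M}$, $K_{GSH} = 100\,\mathrm{\mu M}$ | low $K_{H_2O_2}$: saturates early in a crisis |
| GR | two-substrate Michaelis, GSSG + NADPH → 2 GSH + NADP | $V$ calibrated (4.0198 µM/s), $K_{GSSG} = 65\,\mathrm{\mu M}$, $K_{NADPH} = 20\,\mathrm{\mu M}$ | Michaelis constants are literature-scale values |
| G6PD | patient-specific rate law (below) | per subject | the package's focal reaction |
| 2nd PPP step | $k[\mathrm{GL6P}]\frac{[\mathrm{NADP}]}{K+[\mathrm{NADP}]}$ | $k = 1\,\mathrm{s^{-1}}$, $K = 0.05\,\mathrm{\mu M}$ | lumps lactonase + 6PGD; yields the second NADPH |
| G6P supply | constant | calibrated (2.6530 µM/s) | hexokinase inflow |
| G6P drain | $k[\mathrm{G6P}]$ | $k = 0.06\,\mathrm{s^{-1}}$ | glycolytic consumption (≈ 2.4 µM/s at 40 µM G6P) |
| NADPH drain | $k[\mathrm{NADPH}]$ | $k = 0.005\,\mathrm{s^{-1}}$ | basal non-glutathione NADPH use |

Two moieties are conserved exactly by this stoichiometry and are checked at
run time: total glutathione $[\mathrm{GSH}] + 2[\mathrm{GSSG}]$ (3209 µM from
the initial state) and total nicotinamide $[\mathrm{NADP}] + [\mathrm{NADPH}]$
(62 µM). Glutathione synthesis/export and NADP kinase act on hour-to-day
timescales and are omitted from the 30-minute experiment.

The network ships as a declarative YAML file
(`inst/extdata/redox_network.yaml`); `read_model()` loads any structurally
similar file, so a fuller transcription of a published whole-cell model can
replace the default without code changes. When the loaded model matches the
packaged network's shape, integration uses a compiled C right-hand side;
anything else falls through to an R rate-law evaluator, and the two paths are
tested against each other.

### The G6PD rate law

G6P + NADP → GL6P + NADPH with

$$v = \frac{V_{max}[\mathrm{NADP}][\mathrm{G6P}]}
{K_{mNADP} K_{mG6P}\left(1 + \frac{[\mathrm{NADP}]}{K_{mNADP}}
\left(1 + \frac{[\mathrm{G6P}]}{K_{mG6P}}\right)
+ \frac{[\mathrm{NADPH}]}{K_{iNADPH}} + \frac{[\mathrm{ATP}]}{K_{iATP}}
+ \frac{[\mathrm{2,3BPG}]}{K_{i2,3BPG}}\right)}.$$

The six constants $(V_{max}, K_{mG6P}, K_{mNADP}, K_{iNADPH}, K_{iATP},
K_{i2,3BPG})$ are what distinguishes one patient from another; the packaged
`reference_patients()` table carries ten biochemically characterised
deficient variants plus a healthy control. The law is zero exactly when
either substrate is absent, strictly below $V_{max}$, monotone increasing in
each substrate and decreasing in each inhibitor — all property-tested.

The published source tabulates $V_{max}$ as "M/s", which is not physically
interpretable at face value (64 mol/L/s would turn over the cell's G6P pool
in microseconds). The package follows the convention of treating the printed
numerals as velocities in model units (µM/s): what matters for every analysis
here is the *relative* capacity across subjects, which is unit-independent.

### NADPH inhibition is the severity amplifier

At rest the healthy control runs G6PD almost fully product-inhibited (NADPH
near the top of the nicotinamide pool) and substrate-starved (NADP well below
$K_{mNADP}$); its resting flux is < 1% of $V_{max}$, leaving an enormous
reserve that is unlocked the moment NADPH is consumed. Deficient variants
differ not only in $V_{max}$ but in how much reserve this feedback leaves
them, which is why severity in the model (as in patients) is not a function
of $V_{max}$ alone.

## Calibration

Two constants are not conventional choices but are pinned by the healthy
control (`scripts/calibrate.R`, deterministic):

* the GR $V_{max}$ is chosen by bisection so the control's steady-state
  GSH/GSSG equals 700.38, the published steady-state value for the control
  subject — this anchors the model's redox scale;
* the constant G6P supply equals the glycolytic drain at 40 µM plus the
  control's steady-state G6PD flux, so the G6P pool sits at its stated
  initial value.

Everything else is stated above and in the YAML. The packaged defaults give
the control a steady state at GSH/GSSG = 700.38 by construction; all other
subjects' values are predictions of the calibrated network, and the tests
treat them only qualitatively (rank order, trend directions), since the
reduced network is not the published full model.

## The perturbation protocol

`find_steady_state()` integrates from the model-file initial state over a
long horizon (to 10⁵ s) and then polishes with damped Newton iterations in
which the glutathione and nicotinamide balance rows are replaced by their
conservation constraints — the stoichiometry makes the plain Jacobian
singular along those directions. Convergence demands
$\lVert \dot{y} \rVert_\infty \le 10^{-8}\,\mathrm{\mu M/s}$.

`run_perturbation()` applies the dose at $t = 0$ and integrates with `lsoda`
(deSolve), relative tolerance $10^{-8}$, absolute $10^{-10}$ µM. Defaults
follow the study design: a 100 µM (0.1 mM) dose observed for 1800 s. Two dose
modes are provided because the published description ("added a perturbation")
does not say whether the dose was intracellular or a clamped extracellular
concentration: `bolus_internal` (default — the intracellular H₂O₂ jumps by
the dose) and `clamp_external` (the dose enters through the diffusion term).
The bolus reading matches the published trajectory shape of a sharp dip with
full recovery; a sustained external clamp holds the system depressed for as
long as the clamp lasts.

Numerical guards: recorded concentrations are clipped to zero only for
reporting when they exceed −10⁻⁶ µM; a more negative value aborts the run
rather than being silently repaired. Identical configurations produce
bit-identical trajectories, and halving both tolerances moves every recorded
series by less than 10⁻⁵ relative (tested).

## Indicators

For each subject the package reports:

* **initial ratio** — GSH/GSSG at the pre-perturbation steady state;
* **amount of change** — $(r_{ss} - r_{min})/r_{ss}$, the fractional dip;
* **recovery time** — the first $t$ after the ratio minimum with
  $r(t) \ge \theta\, r_{ss}$, located by linear interpolation between
  recorded samples; `NA` (not recovered) if no such $t$ exists inside the
  window.

Numerical choices, made here because the published text never quantifies
"return to the normal level":

* $\theta = 0.99$ by default. The recovery is asymptotic, so exact equality
  is unattainable; 0.99 is tight enough to separate subjects and is reported
  alongside every recovery time. Looser thresholds can only shorten recovery
  times (tested).
* The ratio minimum uses parabolic refinement through the three samples
  bracketing the discrete minimum (applied only when the fitted parabola
  opens upward and its vertex falls inside the bracket, and never allowed to
  raise the minimum). On synthetic exponential recoveries the interpolated
  crossing is within half a recording step of the closed form
  $\tau \ln(a/(1-\theta))$ (tested).
* A trajectory that never drops below the threshold has recovery time 0.
* In correlations, non-recovered subjects are capped at the window length
  (1800 s) by default; this `window_cap` policy reproduces the published
  recovery/amount correlation from the published indicator table, which is
  how the original analysis evidently treated its one non-recovering
  subject. A `drop` policy is provided as the alternative.
* The indicators are modestly sensitive to the recording step (a coarse grid
  samples a sharp dip less precisely, even with refinement); the default is
  1 s, and the cohort analyses use 2 s where throughput matters.

## Cohorts, virtual patients and grids

`evaluate_cohort()` runs the full protocol per subject, isolating failures
row by row. `virtual_cohort()` draws each kinetic parameter independently
and uniformly from the published min-to-max ranges of the deficient
reference subjects (Vmax 1–64, KmG6P 7–152 µM, KmNADP 3–155 µM, KiNADPH
1–56 µM, KiATP 125–11000 µM, Ki2,3BPG 520–35000 µM), 500 patients per trial
run and 15 runs by default. Design decisions:

* **Uniform, independent draws.** The source describes only "randomly
  chosen" parameters; independent uniforms on the stated closed intervals
  are the minimal-assumption reading, with bounds treated as inclusive. A
  log-uniform option exists for the wide inhibition-constant ranges but is
  off by default. No dependence structure is imposed between parameters —
  deliberately, since the original analysis imposed none either; this means
  some draws are biologically implausible combinations, which is a known
  property of the design, not a bug.
* **Seeding.** All randomness flows through one integer seed per draw;
  per-run seeds are `seed, seed + 1, ...`. Sampling runs in an isolated RNG
  scope (the caller's stream is untouched) with R's default generator, and a
  fixed seed reproduces cohorts byte-identically. Bound respect is a hard
  postcondition, not a statistical one.

`vmax_km_grid()` sweeps Vmax 0–64 (step 1) × even KmG6P 0–200 with the four
remaining parameters fixed at the healthy-control values (3.7, 3.1, 749,
2289) — the published sweep does not state its fixed values, so the control
is the declared default and is echoed in output headers. Zero axis values
would make the steady-state problem degenerate (a cell with literally no
G6PD flux has no NADPH source), so zeros are floored at 0.01 with both the
requested and the substituted value recorded per cell. Grid cells are
independent single-subject runs; permuting cell order cannot change results
(tested).

## The synthetic trajectory generator

`synth_ratio_trajectory()` produces ratio curves
$r(t) = r_0(1 - a e^{-t/\tau})$ with known ground truth. It emulates exactly
one feature of real trajectories — monotone exponential return to baseline
from an initial dip — which is the regime in which the recovery-time
indicator must be exact, and its closed-form crossing time anchors the
indicator tests. It deliberately does *not* emulate the early transient
(the dip itself), non-exponential tails, or solver noise; passing those
tests therefore validates the indicator arithmetic, not the ODE model.
Conversely, the simulated-trajectory tests (conservation, refinement,
dose-response) validate the solver but take no stance on the real cell.
What the combined suite shows about real data is limited by the reduced
network: absolute indicator values depend on the calibration, so only the
control's calibrated steady state and cross-subject orderings and trend
directions are asserted.

## Problem sizes and determinism

The compiled right-hand side makes the full study design tractable on one
CPU: a single subject takes ~20 ms, the 11-subject reference cohort well
under a minute, and the complete 500 × 15 virtual study a few minutes at a
2 s recording step — the sizes exercised by the test suite. The acceptance
script uses 3 virtual trial runs of 500 to keep its total runtime low while
still estimating the cohort-level trends.

## Known limitations

* The reduced network is a stand-in closure, not a transcription of the full
  published erythrocyte model; absolute recovery times and dip magnitudes
  are calibration-dependent, and only the control's steady-state ratio is
  anchored. Non-control absolute indicator values differ from the published
  per-subject table even though every published rank and trend checked in
  the tests is reproduced.
* ATP and 2,3-BPG are clamped; feedback from adenine-nucleotide metabolism
  during a crisis is absent by design.
* Virtual patients ignore the biological coupling between kinetic
  parameters (e.g. low NADP affinity co-occurring with weak NADPH
  inhibition), so cohort tails contain implausible phenotypes.
* Repeated dosing, stochastic kinetics and hemoglobin-binding equilibria are
  out of scope.
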