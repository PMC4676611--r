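---
title: "A multi-scale lattice model of myeloma growth and the osteoblast-osteoclast balance"
author: "myelomaABM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-scale lattice model of myeloma growth and the osteoblast-osteoclast balance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myelomaABM)
```

## The biological problem

Multiple myeloma (MM) grows in the bone marrow and derails bone
remodeling: osteoblast (OB) activity collapses while osteoclast (OC)
activity expands, producing osteolytic lesions.  The package models the
three populations as agents on a 100 x 100 x 100 lattice (5 um spacing,
about the radius of a myeloma cell) coupled through four cytokine
fields and three drug fields:

* MMs secrete DKK1, a Wnt inhibitor that starves OBs of their
  proliferative signal, and RANKL;
* OBs secrete OPG, the decoy that neutralizes RANKL; the local
  OPG:RANKL ratio inhibits OC expansion;
* OCs secrete TNF-alpha, which feeds back positively on MM
  proliferation;
* BHQ880 (an anti-DKK1 antibody), glucocorticoids (GCs) and Lidamycin
  perturb this loop pharmacologically.

## Model structure

### Phenotype switching (intracellular scale)

At every 2-hour step each living agent runs the same decision sequence:

1. **Apoptosis.**  A hazard rate `lambda` (per hour) is converted to a
   per-step probability `1 - exp(-lambda * dt)`.  The hazard is basal
   plus a Hill-2 drug response: Lidamycin raises the MM hazard,
   glucocorticoids raise the OB and OC hazards with widely separated
   thresholds (`K_GC_1 = 0.15` for OBs, `K_GC_2 = 1.5e-6` for OCs), so
   a low absolute GC level is OC-selective.  A cell that triggers
   apoptosis occupies its site for 10 further steps before absorption.
2. **Cycle entry.**  A Bernoulli draw against the proliferation
   probability: MMs respond to local TNF-alpha, OBs to the effective
   Wnt signal, OCs are inhibited by the OPG:RANKL ratio
   (`P0_oc + P_pathway_oc / (1 + (O_RL/K_O_RL)^2)`).  Sums are clamped
   to [0, 1].
3. **Cycle progression.**  G0/G1 -> S -> G2 -> M with configurable
   per-type phase lengths; the cell migrates during the first three
   phases and divides in M into an empty face-neighbor site (daughter
   age 0, quiescent).  If no site is free the cell becomes reversibly
   quiescent with its phase retained.
4. **Migration / quiescence.**  Non-cycling cells migrate to an empty
   face neighbor chosen by roulette over ranked candidates, or quiesce
   when boxed in.

### Site ranking (intercellular scale)

Candidate sites (the six face neighbors; a "six nearest neighbors" rule
is the only reading consistent with the six-term diffusion stencil) are
scored `R_l = (1/4) p(r_l) V_l`, where `p(r)` is a Gaussian-type kernel
in the distance and `V_l` prefers 1-2 occupied neighbors (weight 1)
over crowded (1/4, 1/8) or isolated (1/16) sites.  Scores are
normalized and partitioned into half-open intervals of [0, 1); a
uniform draw selects the site, so ties at interval boundaries cannot
occur.  At the default search radius all candidates share r = 1 and the
kernel prefactor cancels in the normalization.

### Fields (tissue scale)

Each species updates synchronously from the time-t snapshot:

```
C'(P) = [C(P)(1 - lambda) + (lambda/6) * sum_nb C + chi(P) * influx] * (1 - decay)
```

with secretion masks at the secreting cell type's sites (cytokines,
influx `Se_G`) or drug influx `Pe_d * dose * reference` (uptake `U_d`
instead of degradation `DEG`).  The default boundary rule is no-flux
(each missing neighbor's `lambda/6` share stays at the boundary site),
which conserves mass exactly; an absorbing variant is available.  Drug
delivery defaults to `drug_source = "uniform"` - influx at every site
while the schedule is active, representing vascular delivery - because
the printed alternative (influx only at OC-occupied sites) makes the
systemic drugs vanish wherever OCs are absent; that variant is retained
as `"as_printed"`.

## Design choices on genuinely open points

* **Amplitude binding (`beta_binding`).**  The published parameter
  table labels the value 0.5 "maximum activation of MM proliferation"
  but attaches it to the symbol the apoptosis equation uses, and vice
  versa for 0.05.  The package defaults to the row labels (0.5 drives
  MM proliferation, 0.05 drives Lidamycin-induced apoptosis): with the
  opposite binding MM proliferation saturates at 0.20, which cannot
  produce the late MM expansion past the OC curve that the disease
  course shows.  `options$beta_binding = "symbols"` switches to the
  other reading.
* **Gate rest period (`cycle$<type>$rest`).**  After a failed
  cycle-entry draw a cell waits `rest` steps before drawing again
  (`rest = 1` re-draws every step).  With per-step re-drawing the
  expected wait `1/p` (at most a few steps) is negligible against the
  fixed cycle length, so the Hill responses would have almost no
  leverage on growth; a rest period of a few steps restores
  gate-probability control over division timing.  Osteoblasts use
  `rest = 1` so that their Wnt-driven birth rate can balance their
  substantial basal death rate (0.035 per hour) in the healthy state.
* **Per-type cycle lengths.**  24 h (12 steps: 5/4/2/1) for MMs and
  OCs and 20 h (4/3/2/1) for OBs; lengths and rests are per-type
  configurable because the three lineages differ in turnover.  The
  shorter OB cycle is what lets a fully Wnt-stimulated OB population
  out-divide its high basal death rate, which is the mechanism of OB
  recovery under the anti-DKK1 antibody.
* **Cycle desynchronization at t = 0.**  Cells start at a random
  position of the cycle with the steady-state in-cycle fraction
  (`C / (C + rest/p0)` at zero-field gate probability `p0`); a cold
  start produces artificial synchronized division waves.
* **Effective DKK1 under BHQ880.**  `D_e = D^2 / (D + B)`: equals `D`
  without antibody and decreases in `B`.
* **Division after mitosis.**  The parent returns to the resting pool
  (it must pass the gate again); the daughter starts quiescent with age
  0.  This keeps the per-step Bernoulli reading of cycle entry
  meaningful throughout a lineage.
* **Relative dose units.**  A schedule dose of 1 means one reference
  unit of that drug; `dosing$<drug>$reference` converts it to the
  influx scale.  References are calibrated per drug because the printed
  GC thresholds are OC-selective only at low absolute concentration,
  while BHQ880 must reach DKK1-comparable levels to matter in
  `D^2/(D + B)`.

## Calibration of the free rates

The diffusion, secretion, uptake and motility rates carry no published
values; the shipped baseline (`inst/extdata/calibrated.yaml`; equal to
`defaultConfig()` except for the GC-on-OC amplitude noted under
limitations) was chosen once so that the drug-free simulation
reproduces the qualitative disease course: the three curves separate
after about 20 steps, OBs decay toward zero, OCs roughly triple, MMs
roughly quadruple and overtake OCs late in the run.

Two calibration facts are worth recording.  First, cytokine
*degradation* is the clock of the model: with fast degradation
(`DEG ~ 0.05`) the fields equilibrate within ~20 steps and colony
dilution keeps the TNF-alpha level at MM sites flat, so MM growth never
accelerates late; the slow default `DEG = 0.001` integrates secretion
over the run, producing the late TNF-alpha ramp (and long-lived OPG
that keeps the OC brake engaged) that places the MM-over-OC crossing
late.  Second, the OC amplitude `P_pathway_oc` sets the early OC lead,
and the per-type rests (MM 16, OC 17 steps) set the overall expansion
factors.  These pulls trade off against each other: the same amplitude
that gives OCs their early lead also raises their final count, so the
shipped values are a joint compromise between the expansion windows,
the OB collapse and the timing of the crossing, not a per-quantity
optimum.

## What the synthetic generator does and does not emulate

`initializeState()` seeds ~100 cells of each type uniformly in the
smallest central lattice ball that holds them, ages uniform on 0-24 h,
fields zero.  `makeGridFixture()` / `makeCurveFixture()` build exact
micro-states and analytic dose-response curves for tests.  The
generator emulates a well-mixed avascular focus; it does not emulate
marrow anatomy, vasculature, stromal cells, immune populations, or
pharmacokinetic compartments - passing tests demonstrate internal
consistency and qualitative agreement with the modeled disease course,
not predictions about patients.

## Numerical choices

* Explicit first-order field updates; stability is guaranteed for
  `lambda in [0, 1]` because the stencil is a convex combination.
* Agents act in a freshly randomized order each step (a fixed order
  imprints directional drift on the colony).
* A master seed spawns one placement stream and one dynamics stream;
  identical (config, seed) pairs are bit-identical.
* The OPG:RANKL ratio is guarded by `epsilon_ratio = 1e-9`.
* Dose-response inversion interpolates linearly in log-dose and is
  restricted to the monotone branch containing the reference dose; a
  target outside the achieved range is an error, never an
  extrapolation.
* Spearman p-values use the t approximation with n - 2 degrees of
  freedom on the per-setting means.

## Problem sizes used by the shipped checks

The unit and property tests run on 3^3 to 21^3 lattices with tens of
agents and complete in seconds.  The full-scale checks (drug-free
course, seven-regimen comparison, acceptance script) use the 100^3
lattice, 120 steps and nine seeds, a few hundred agents per run.

## Known limitations

* The four printed "sub-compartments" of the cube are never used by
  any equation and are not implemented.
* GC-induced OC apoptosis has tabulated amplitude 0; the treatment
  narrative requires it to be positive, so the calibrated baseline sets
  `beta2_GC > 0` while the table's zero remains the documented default
  of the symbol.
* Whether OBs and OCs use the same ranked-site migration rule as MMs is
  not stated; all three types share the rule here.
* Drug fields persist after the dosing window and decay only through
  uptake.
* No nutrient field exists; "greater nutrition" in site choice is
  expressed entirely by the ranked preference weights.
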