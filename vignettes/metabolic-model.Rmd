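---
title: "A whole-body glucose-lipid model with antidiabetic PK/PD: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A whole-body glucose-lipid model with antidiabetic PK/PD: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(visp)
```

## Scope

`visp` couples three layers:

1. a deterministic ODE model of whole-body glucose and lipid homeostasis
   (the metabolic core),
2. compartmental pharmacokinetic sub-models for metformin and the GPR40
   agonist fasiglifam (TAK-875), whose exposures act on the core through
   Hill-type rate multipliers, and
3. a model-agnostic simulation manager that expands virtual-patient and
   therapy selections into batches of fully specified simulation tasks.

This vignette is the package's account of the science: the model equations
and their assumptions, the parameters that matter, the calibration
strategy, numerical choices, and known limitations.

## The metabolic core

### Nutrient handling

Meals (up to three per day, each with a caloric content and
carbohydrate/fat/protein energy fractions) and OGTT glucose loads enter a
stomach pool, empty first-order into a gut lumen pool (`k_gastric`,
1.0 h⁻¹), and are absorbed first-order into the circulation
(`k_abs_carb` = 1.0 h⁻¹ for carbohydrate).  The bioavailable fraction
reaches the blood; the remainder is tracked as a loss so that at every
instant *ingested = stomach + gut + absorbed + lost* holds exactly.  A
drug-induced `gut_absorption_delay` multiplier below 1 slows the whole
gut chain — gastric emptying and the carbohydrate absorption constant
together: the appearance peak moves later while the total amount
absorbed is unchanged — the model's rendering of delayed, more distal
glucose absorption (with its modest gastric slowing) under metformin.
The exported `gut_absorption_flux()` helper exposes the mucosal-uptake
part of that multiplier for direct flux queries.

### Liver

Hepatic glucose handling cycles through a glucose-6-phosphate (G6P) pool:

* glucokinase (glucose → G6P), increasing with plasma glucose
  (power law, exponent 1.5) and activated by insulin;
* G6Pase export (G6P → glucose), driven by the G6P pool (weak exponent
  0.4, so export is hormone- rather than substrate-dominated) and by
  glucagon;
* glycogen synthase / phosphorylase, the former insulin-activated and
  capacity-limited (`Gly_liver_max` 150 g), the latter glucagon-driven,
  insulin-suppressed and zero at an empty store;
* gluconeogenesis from a lumped three-carbon substrate pool (lactate,
  glycerol, alanine equivalents), glucagon-stimulated and
  insulin-suppressed.

Insulin suppression in the liver uses a saturating function normalised to
1 at the healthy fasting signal with a low half-constant
(`K_ins_phos` = `K_ins_gng` = 0.5), giving the steep disinhibition at low
insulin signal that makes fasting hyperglycemia reachable when hepatic
insulin sensitivity (`SI_hepatic`) collapses — the dominant lesion of the
representative T2DM patient.  The `hepatic_glucose_production` drug
multiplier scales gluconeogenesis, glycogenolysis *and* the G6Pase export
step: the first two are the biochemical targets, and scaling the export
step as well makes the multiplier's effect on the plasma-glucose
derivative immediate rather than routed through the slow G6P pool.

### Muscle, brain, kidney, other tissues

Muscle uptake is `(u_basal + u_ins · z^h) · γ(G)` with `z` the delayed,
sensitivity-scaled insulin signal (`h_ins_muscle` = 1.3 gives the
super-linear recruitment of glucose transport at high insulin) and `γ`
a Michaelis-Menten glucose dependence.  Uptake splits into
capacity-limited glycogen storage and oxidation; muscle glycogen is spent
locally and never returns glucose to the circulation.  The brain consumes
glucose at a constant, insulin-independent rate (25 mmol/h).  Kidneys
reabsorb all filtered glucose below a 10 mM threshold; above it excretion
grows at 4 mmol/h per mM (of the order of the glomerular filtration rate)
with a 0.1 mM quadratic knee so the right-hand side stays smooth for the
stiff integrator.  Splanchnic/GI tissue uptake carries the
`gi_glucose_utilization` drug multiplier.

### Hormones

Insulin secretion is a multistep, glucose-coupled process: plasma glucose
sets a Ca²⁺ signalling activity (Hill, `K_ca` 7.5 mM, n 2.5) and a cAMP
activity (Hill in glucose plus incretin potentiation), each relaxing as a
state on a minutes time scale; their product, scaled by β-cell mass and
function, gives the secretion rate, with equal molar C-peptide co-release.
Secreted insulin enters a portal pool; a fixed 50% hepatic first-pass
extraction feeds the systemic pool, which clears first-order, while
C-peptide clears first-order renally.  Insulin *action* is realised as
one intermediate effect compartment per tissue (liver τ = 0.3 h driven by
a portal/systemic blend; periphery τ = 0.3–0.5 h driven by systemic
insulin) — the model's answer to the open question of how many
receptor/post-receptor steps to carry explicitly.

Glucagon follows a two-compartment model (secretory and peripheral pools
exchanging conservatively, clearance from the first).  Secretion falls
with both glucose and insulin; its scale is tied to the clearance constant
so the reference state is an exact fixed point and `k_gn_clear = 0` yields
an exactly conservative system.  GLP-1 and GIP are single pools with
basal plus carbohydrate-absorption-driven secretion (the intestinal
branch carries the `incretin_secretion_gain` multiplier) and first-order
clearance; both potentiate the cAMP branch of secretion.

Lipids are pools of plasma TAG, plasma FFA and adipose TAG with hepatic
TAG export, lipoprotein-lipase clearance into adipose, insulin-suppressed
lipolysis (the `ffa_release` multiplier's target), re-esterification and
FFA oxidation.  β-cell mass and function are parameters, constant over
the ≤ 28-day horizons simulated here; no slow disease-progression
dynamics are modelled.

### Design-by-steady-state

Every rate constant is chosen so that the healthy reference state (plasma
glucose 5 mM, insulin 60 pM, glucagon 70 pM, FFA 0.5 mM, fluxes of
realistic magnitude: fasting turnover ≈ 40 mmol/h, brain ≈ 25 mmol/h) is
an exact fixed point of the equations.  This makes the fasting steady
state a structural property rather than a numerical accident, and lets
`steady_state()` polish any parameterisation with a damped Newton
iteration after a 300 h damping pre-integration (slow pools — adipose
TAG, glycogen — have multi-hundred-hour time constants, so integration
alone never quite lands).  Gut pools and cumulative trackers are pinned
at zero during root finding; they are neutral directions of the flow.

### The fed orbit versus the fasting fixed point

Under a daily meal schedule the model settles onto a 24 h periodic orbit.
With strong insulin resistance the overnight relaxation is slow, so the
pre-breakfast ("morning") glucose sits a few percent above the meal-free
fixed point.  Clinical fasting measurements are morning measurements, so
`calibrate_vp()` offers both `fasting_glucose` (fixed point) and
`morning_glucose` (fed-orbit, pre-dose pre-meal) observables; trial-table
anchors are calibrated on the morning values, and the package's simulated
"FPG" endpoint is always the morning value, read just before the 08:00
events.

## Drug models

### Metformin

Oral three-compartment kinetics — gut depot counted as a compartment,
plus central and peripheral — with first-order absorption (ka 0.9 h⁻¹,
F 0.55), inter-compartmental clearance 20 L/h and elimination clearance
34 L/h: a 500 mg dose peaks near 1.3 µg/mL at ~1.5–2.5 h with a terminal
half-life near 12 h, matching published single-dose and steady-state
profile shapes; the same kinetics serve healthy and T2DM patients.

Pharmacodynamics are Hill multipliers on five physiological rates.
Systemic effects (hepatic glucose production ↓, peripheral insulin
sensitivity ↑, lipolysis ↓, and — behind the off-by-default
`metformin_beta_cell` hypothesis switch — β-cell function ↑) are driven
by instantaneous plasma concentration.  Intestinal effects (absorption
delay ↓, GI glucose utilisation ↑) are driven by a *gut-tissue exposure*
compartment that first-order-tracks plasma concentration with a ~17 h
half-time: metformin accumulates in intestinal mucosa, and the 28-day
trial table shows a large OGTT-AUC reduction already at a 24 h
once-daily trough where plasma drug is nearly gone — only a slow local
driver reproduces that pattern while fasting glucose stays untouched at
the same time point.

### TAK-875 (fasiglifam) and enterohepatic recirculation

Oral kinetics with a small central volume and slow net clearance (long
half-life), plus an enterohepatic loop: a fraction of central elimination
is secreted via a bile-duct compartment into the gallbladder, which
releases 60% of its content into the gut at each meal or OGTT start (the
trigger the physiology suggests; the source material does not state one).
Recirculated drug re-enters through its own depot and is completely
reabsorbed, so the total mass cleared to infinity equals `F · dose`
regardless of the biliary fraction — the loop redistributes exposure in
time (secondary concentration rises after meals) without changing it in
total.  The pharmacodynamic effect is one lumped amplification of the
Ca²⁺ gain on glucose-stimulated insulin secretion; GPR40-driven
intestinal incretin secretion exists as the `gpr40_incretin_secretion`
hypothesis, off by default because multiple-dose clinical data showed no
incretin rise.

### Combining drugs

Effects of different drugs on the same rate tag multiply — the simplest
composition consistent with independent mechanisms.  With no drug on
board every multiplier is exactly 1 and the arithmetic of the coupled
right-hand side is bit-for-bit that of the drug-free model.

## Calibration strategy

Calibration proceeds in two frozen stages, both performed once and
shipped as fixtures:

1. **Virtual patient.**  The representative T2DM patient moves only the
   three canonical defects — `SI_hepatic`, `SI_peripheral`, `B_func` —
   until the day-0 anchors hold: morning FPG 10.1 mM, fasting insulin
   90 pM, total OGTT glucose AUC 29.9 mM·h over the package's 0–2 h
   window.  The fit lands on a hepatic-dominant lesion
   (`SI_hepatic` ≈ 0.09, `SI_peripheral` ≈ 0.75, `B_func` ≈ 0.46).
2. **Metformin pharmacodynamics.**  With the patient fixed, the Hill
   parameters of the five metformin effects are fitted to the
   escalating-regimen outcomes (days 7/14/28 fasting glucose, OGTT AUC
   and fasting-insulin change), day 0 having been anchored in stage 1.
   The day-14/28 values then act as held-out checks in the test suite.

The OGTT AUC convention deserves a note: the package reports *total* AUC
over a 0–2 h window by default (window and total-vs-incremental are
protocol options).  A 2 h total window is the only convention arithmetically
consistent with anchoring both a ~10 mM fasting glucose and a ~30 mM·h
day-0 AUC, and it is held fixed between calibration and prediction so
that table comparisons are internally consistent.

The simulated trial enables the `metformin_beta_cell` hypothesis: a rise
in fasting insulin while glucose falls cannot arise from the pure
glucose→β-cell feedback loop, and the β-cell-function pathway is the
mechanism the pharmacology literature (and this model's effect list)
offers for it.  The package-wide default for the switch remains off.

## Protocols, endpoints and day indexing

Day 0 is the first dosing day; a protocol day `d` event at clock time `c`
sits at `t = 24 d + c` hours.  Fasting values are read just before the
08:00 morning events.  On OGTT mornings, meals are suspended until 3 h
post-load and any dose scheduled inside that window is taken at its end,
so tolerance-test mornings are strictly pre-dose — the convention of an
escalating-dose study in which each OGTT measures the *previous* dose
level.  Endpoints (FPG, FPI, OGTT AUC by trapezoid with edge
interpolation, 2 h post-load glucose, percent FPI change versus a
reference day) are interpolated from the sampled output grid and are
stable under halving the output interval to well below one percent.

## Numerical choices

* Integrator: `deSolve::lsoda` (stiffness-switching), relative tolerance
  10⁻⁶, absolute 10⁻⁸; every meal, dose and OGTT is a discrete event at
  which the integrator restarts with a state jump.
* `steady_state()`: 300 h pre-integration at tighter tolerances, then
  damped Newton with a finite-difference Jacobian on the dynamic states;
  convergence is declared at a scaled residual below 10⁻⁹ and a
  5000 h integration is the fallback.
* Renal threshold, glycogen capacity and similar knees are smooth
  (quadratic knee, soft capacity factors) to avoid integrator chatter.
* `calibrate_vp()` uses Nelder-Mead on log-transformed parameters
  (positivity by construction) minimising summed squared relative errors;
  it is deterministic for fixed settings and errors out, reporting the
  worst residual, if any target misses its 2% tolerance.
* Task identity is a content hash over the serialised task document, so
  identical inputs always map to the identical task id and result file.

## Problem sizes

The shipped tests and the acceptance script run, on one CPU: a 32-day
coupled simulation (29 protocol days plus run-in, ~37 states, ~175
events) in tens of seconds; the three-parameter patient calibration in a
few minutes; and the dose-response and combination batteries as 15-day
simulations at a half-hour output interval.  These sizes were chosen so a
complete verification pass stays at desk scale.

## What the synthetic patients do and do not show

The virtual patients are parameter sets of this model, not samples from a
population: they emulate trial-mean phenotypes (enrollment-criteria
fasting glucose, insulin and OGTT response) under idealised meals — identical
daily schedule and composition, perfect adherence, no circadian hormone
rhythms, no measurement error.  Passing the table-reproduction tests
therefore shows that the mechanism set and its calibration are jointly
consistent with the reported trial means; it does not validate the model
against individual-level variability, and no claim is made about
populations (automated virtual-population generation is out of scope).

## Known limitations

* The metabolic parameterisation is anchored to one representative
  healthy and one T2DM phenotype; far-from-anchor parameter regions
  (e.g. extreme hypoglycemia) are not calibrated.
* Protein metabolism is lumped into gut absorption plus a gluconeogenic
  substrate contribution; nitrogen balance is not tracked.
* β-cell mass/function are static parameters: no long-term disease
  progression.
* The incretin and lipid branches are deliberately coarse (single pools,
  linear clearances); they stabilise the physiology and carry the drug
  hypotheses but are not calibrated to incretin or lipid time courses.
* The simulation manager replaces the original platform's web UI,
  relational database and cloud dispatch with files, a process pool and
  structured logs; the scientific contracts (full-listing tasks, crossed
  and combination expansion, text results) are preserved.
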