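---
title: "Methods: PBK-based reverse dosimetry of AChE inhibition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PBK-based reverse dosimetry of AChE inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, what the
synthetic-data generators do and do not emulate, the numerical choices, and
the known limitations — in particular a dose-scale caveat that anyone
comparing predicted benchmark doses against published reference values
should read first.

## The modelling chain

The package predicts in vivo dose-dependent acetylcholinesterase (AChE)
inhibition by the organophosphate profenofos without animal data, in four
coupled stages:

1. **In vitro kinetics.** Rates of hydrolysis of profenofos to its phenol
   metabolite (BCP) measured in liver microsomes, liver cytosol and plasma
   are fitted to the Michaelis–Menten law, V = Vmax·[S]/(Km + [S])
   (`fit_michaelis_menten()`); Vmax/Km is the catalytic efficiency.
2. **PBK model.** A generic 14-compartment flow-limited model
   (`pbk_model()`, `simulate_pbk()`) converts an oral dose into internal
   concentration–time profiles. The in vitro Vmax values are scaled to
   whole-organ capacities with standard protein contents
   (35 mg microsomal and 80.7 mg cytosolic protein per g liver;
   550 mg plasma per g blood), and all saturable clearance acts on unbound
   concentrations.
3. **Reverse dosimetry (QIVIVE).** The unbound blood peak,
   C~max,u~, is the internal dose metric. The monotone dose→C~max,u~ map is
   inverted so that every concentration used in the in vitro AChE assay
   corresponds to an oral dose (`dose_to_cmax_map()`,
   `concentration_to_dose()`), turning the fitted in vitro unit-slope
   log-logistic activity curve, Y = 100/(1 + 10^(X − logIC50)), into a
   predicted in vivo dose–response curve (`predict_dose_response()`).
4. **Benchmark-dose analysis.** Exponential and Hill families are fitted to
   the predicted curve; AIC weights average their BMD10s and a
   residual-resampling bootstrap yields the BMDL10
   (`fit_dose_response_models()`, `model_average_bmdl()`).

Key assumptions, stated once: distribution is flow-limited (no membrane
permeability limits); all absorbed chemical passes through the liver;
metabolism and renal filtration act on the free fraction; the in vitro
nominal concentration equals the in vivo unbound blood concentration (an
optional `fu_invitro` correction is available and defaults to 1); AChE
inhibition depends on C~max,u~, a static single-time-point view that
ignores the cumulative, essentially irreversible nature of organophosphate
binding — appropriate for single-dose predictions only.

## Parameters, units, defaults

Package-wide units: amounts µmol, volumes L, flows L/h, concentrations µM,
time h, doses mg/kg bw.

| parameter | default | why |
|---|---|---|
| k~a~ (gut absorption) | 1 h⁻¹ | first-order oral uptake, complete absorption |
| renal clearance | 0.078 (rat), 6.7 (human) L/h | glomerular filtration of the unbound fraction |
| scaling factors | 35 / 80.7 / 550 mg/g | standard protein-content scaling of in vitro Vmax |
| f~umic~, f~ucyt~, f~upla~ | 1 | binding in the incubations taken as negligible; they act through the in vivo Km |
| logK~ow~ (profenofos) | 4.44 | literature (experimental) value |
| f~up~ (profenofos) | 0.078 | derived from the Austin (2002) lipophilicity–binding regression, log((1−fu)/fu) = 0.56·logP − 1.41; **not a measured value** |
| blood:plasma ratio | 1 | predictions are reported as plasma-equivalent "blood" concentrations |
| BMR | 0.10 | ten percentage points of inhibition above a zero background |
| bootstrap | n = 200, seed recorded | residual resampling; 5th percentile = BMDL |

The physiology tables (volumes, flows, cardiac output for a 0.25 kg rat and
a 70 kg human) are transcribed from the standard reference-compendium
lineage and ship as editable YAML; validation enforces the full
14-compartment set, positivity, and flow balance within 1%.

Partition coefficients use the tissue-composition method (Berezhkovskiy's
correction of Poulin–Theil): neutral-species octanol:water partitioning
into tissue lipids for non-adipose tissues with the binding correction
f~ut~ = 1/(1 + 0.5(1 − f~up~)/f~up~), the vegetable-oil coefficient
logD~vo~ = 1.115·logK~ow~ − 1.35 for adipose, and Henderson–Hasselbalch
speciation at pH 7.4 (profenofos itself is neutral there; the acid/base
pathway is exercised by unit tests). Estimated values can be overridden
per tissue in the chemical config, and overrides take precedence
(`resolve_partitions()`).

The rat model can be extended with a metabolite sub-model (`bcp = TRUE`):
every mole of parent metabolised forms one mole of BCP, which distributes
with its own estimated partition coefficients, is glucuronidated in the
liver (saturable; default kinetics are labelled synthetic approximations of
published rat phenol-glucuronidation parameters and are configurable), and
the glucuronide is filtered to urine from a central blood pool. Because
glucuronidation is BCP's only elimination route, the late-time urinary
plateau equals the fraction of parent metabolised — a mole-balance
identity the tests exploit. The human model deliberately omits this
sub-model; it exists to permit evaluation against rat urinary-excretion
data.

## Numerical choices

* Stiff integration via deSolve's `lsoda` at rtol 1e-8 / atol 1e-10. (The
  model family is classically integrated with Rosenbrock-type stiff
  solvers; any stiff integrator at these tolerances gives identical results
  to well below the reporting precision, and halving the tolerances moves
  C~max,u~ by < 0.1%, which is a test.)
* The venous peak is sharp relative to plausible output grids (the blood
  compartment clears fast), so `simulate_pbk()` is two-pass: a coarse solve
  locates the peak, a second solve adds a dense 120-point window around it,
  and a local quadratic refines the maximum between grid points. The
  reported C~max,u~ is grid-independent to ~6 significant digits.
* Dose inversion: 40 log-spaced doses over 10⁻⁴–10³ mg/kg by default,
  monotone Hermite (log–log) interpolation, root-finding at relative
  tolerance 1e-6, automatic upward grid extension on range errors.
  Round-tripping dose → C~max,u~ → dose is accurate to ≪ 1% at the default
  grid density.
* Nonlinear fits use Levenberg–Marquardt (minpack.lm) with positivity
  bounds. The Michaelis–Menten fitter tries the (max-rate,
  half-max-concentration) start first, then a Hanes–Woolf linearisation
  start, then coarse fallbacks, before declaring non-convergence.
  Identifiability matters more than the optimiser: a 1–100 µM design
  cannot pin down a 0.34 µM Km, so parameter-recovery checks for
  sub-micromolar-Km matrices use designs spanning the Km.
* BMD fits are unweighted least squares on the percent-inhibition scale
  with background fixed at 0; BMDs invert the fitted families in closed
  form and are verified against the model function; the model-averaged BMD
  is the AIC-weight average and the reported BMDL never exceeds it.
* Sensitivity coefficients use one-sided +5% perturbations by default
  (central differences optional); coefficients at 1% and 5% agree within
  10% for the influential set, which is a test.

## What the synthetic data emulate — and what they do not

The generators reproduce the *statistical structure* the analysis assumes:
Michaelis–Menten mean rates with proportional noise (default CV 5%, 3
replicates), log-logistic activities with additive noise (default SD 3
percentage points, 3 replicates, clipped to [0, 120]%), and cumulative
urinary excretion with proportional noise forced isotonic. Defaults were
chosen once to resemble the between-replicate scatter typical of such
assays. They do not emulate systematic assay artefacts: substrate
depletion, chemical hydrolysis blanks, solvent effects, inter-day drift,
or time-dependent (progressive) AChE inhibition. Passing tests therefore
demonstrate that the *estimators and the chain* behave correctly under the
assumed error model, not that any particular laboratory dataset would be
reproduced.

## Design decisions on genuinely open points

* Plasma-enzyme scaling basis: the literal factor "550 mg plasma per g
  blood" is applied to a Vmax expressed per mg plasma protein, i.e. mg
  plasma and mg plasma protein are treated as interchangeable. This is the
  conventional reading of that scaling factor and is the default; a
  plasma-protein basis (~41 mg protein/g blood) is available as a config
  switch in `scaling_factors()` and lowers blood clearance ~13-fold.
* Blood-borne metabolism is split over the venous and arterial
  compartments in proportion to their volumes; renal filtration acts on
  venous blood.
* IC50 fits are on pooled replicate points (replicate means optional), with
  the Hill slope fixed at 1; a free-slope variant exists behind a flag.
* Per-tissue partition overrides beat estimation; the pluggable surface
  would admit other partition schemes but only the tissue-composition
  method is implemented.
* Fits for the BMD stage use the exponential and Hill families with AIC
  weights — a minimal engine in the spirit of the EFSA/PROAST
  model-averaging workflow, not a reimplementation of it; numerical
  agreement with PROAST output is therefore approximate by construction.

## Known limitations, including the dose-scale caveat

**Dose scale.** The absolute dose scale of the predicted curves is driven
by the effective metabolic clearance, and the literal whole-blood scaling
of the measured plasma hydrolysis rates implies an extremely fast
elimination: the rat plasma catalytic efficiency (0.19 ml/min/mg protein),
multiplied by 550 mg/g blood, corresponds to an intrinsic blood clearance
of ~6,300 L/h per kg blood — a free-profenofos half-life in blood of
seconds. Under any plausible f~up~ (swept 0.01–1) and either plasma-scaling
basis, the model therefore predicts that tens of mg/kg are needed to reach
the unbound blood concentrations at which the in vitro assays show 10%
AChE inhibition. Predicted BMDL10 values on this package's defaults are
accordingly of order 50 mg/kg (rat) and 5 mg/kg (human) — the species
*contrast* (humans ~10–15-fold higher C~max,u~ at equal dose, driven by
the ~30-fold lower human plasma catalytic efficiency) is robust, but the
absolute benchmark doses are highly sensitive to inputs that are not
measured quantities here (f~up~, partition coefficients, the plasma
scaling basis). Comparisons with externally published benchmark doses
should therefore be read as order-of-scale only, and a user with better
chemical-specific inputs should supply them through the config files
rather than edit code — all
quantities involved (f~up~, partition overrides, scaling basis, kinetic
parameters) are inputs.

Other limitations: single-route (oral), single-dose predictions only; no
AChE resynthesis or repeated-dose steady-state inhibition; no
enterohepatic recirculation; no esterase-inhibition feedback on clearance;
no inter-individual variability; the oxidative metabolite pathways are
omitted (hydrolysis dominates); and the bundled rat in vivo reference
curve for ordinal comparisons is a synthetic reconstruction anchored on
published regulatory landmark values (a reported rat RBC BMDL10 of
1.99 mg/kg bw and a brain-AChE NOAEL of 100 mg/kg bw), clearly labelled as
such — it is not measured data.

## Problem sizes used by the tests

The test-suite and acceptance computations run at deliberately modest
sizes, chosen as the smallest that exercise each property: 8-concentration
× 3-replicate in vitro designs; 10–40-dose C~max~ maps; 120-point peak
windows; bootstrap n = 60 in unit tests and n = 200 for reported BMDLs;
20-seed averages for IC50 recovery. These are the package's own choices of
scale and are stated in the relevant roxygen defaults.
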