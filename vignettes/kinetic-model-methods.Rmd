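---
title: "Kinetic-metabolic modelling of rAAV production in HEK293 cells: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic-metabolic modelling of rAAV production: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aavmet)
```

## The model

`aavmet` implements a single-compartment kinetic model of the central
metabolism of HEK293 cells producing recombinant adeno-associated virus
(rAAV) by triple transient transfection. The state is a vector of 53
extracellular-and-pooled-intracellular metabolite concentrations $C$ (mM)
plus three cumulative outputs (Biomass, Rep and Cap protein), and the
dynamics are mass balances driven by 32 enzymatic fluxes:

$$\frac{dC}{dt} = S\,v(C),$$

where $S$ is the signed stoichiometric matrix and each flux follows
multi-substrate Michaelis–Menten kinetics: a product of saturation terms

$$v = v_{\max}\prod_j \frac{[S_j]}{K_{m,j} + [S_j]},$$

with five reactions (triose-phosphate isomerase, phosphoglycerate kinase,
succinate dehydrogenase, fumarase, lactate dehydrogenase) carrying a
subtracted reverse product of the same form. The network spans glycolysis,
the TCA cycle, the pentose phosphate pathway, anaplerosis, amino-acid
metabolism, nucleotide synthesis, biomass synthesis and the synthesis of
the AAV Rep and capsid proteins; the model contains 52 distinct $K_m$ and
37 $v_{\max}$ parameters (89 kinetic parameters) plus 53 initial
concentrations, 142 fitted quantities in total. The full definition —
species, shared parameter registry, flux laws, reaction stoichiometries —
ships as a human-editable YAML file
(`system.file("extdata", "aav_hek293.yaml", package = "aavmet")`).

Modelling choices a reader should know about:

* **Units.** Concentrations are mM and time is hours, so fluxes are
  mM/h. The source tables state concentrations in mM but no time unit;
  hours follow from the 24-h sampling cadence of the emulated culture.
* **Shared $K_m$ registry.** A metabolite has one $K_m$, used by every
  saturation term that references it (e.g. `Km_ATP` appears in the HK,
  PFK, PGK, PC, Glu, Growth, Rep and Cep laws). This matches how the
  fitted constants are tabulated and keeps the count at 52.
* **Auxiliary outputs.** Biomass, Rep and Cap are cumulative product
  states initialised at zero; they are excluded from the 53 mass-balance
  species and from the parameter counts. Water and protons are not
  tracked.
* **Cofactors are dynamic.** ATP/ADP, NAD(H), NADP(H), FAD(H2), CoA, Pi
  and CO2 are ordinary state variables with fitted initial values, not
  clamped pools.
* **Glutamic acid vs glutamate.** `GluAc` (the measured extracellular
  pool) and `Glu` (the metabolically active pool) are distinct species;
  `GluAc` is consumed only by the Rep/Cap synthesis laws, which is why its
  simulated profile is nearly flat and why it is excluded from the
  sensitivity outputs by default.
* **Two laws without a printed network row.** Lactate dehydrogenase and
  alanine transaminase have kinetic laws but no tabulated reaction;
  standard biochemistry is used (Pyr + NADH ⇌ Lac + NAD;
  Pyr + Glu → Ala + αKG). The pentose-phosphate rows duplicated under
  "pyruvate fates" in the source network table are carried once, keeping
  32 laws. The mapping is recorded in the YAML file.
* **Pseudo-steady-state language.** The source describes mass balances
  around intracellular metabolites in pseudo-steady-state terms yet
  integrates 53 dynamic equations; this package implements the dynamic
  reading, $dC/dt = S v$.

## Simulation

`simulate_model()` integrates the balances with `deSolve`'s lsoda (an
implicit, stiffness-switching method) at relative tolerance `1e-7` and
absolute tolerance `1e-9` mM; the cofactor pools span roughly `1e-5` to 20
mM, which motivates the tight absolute tolerance. Inside the right-hand
side, concentrations are floored at zero before the saturation terms are
formed, so integrator overshoot cannot drive a negative substrate into a
negative flux; a depleted substrate simply switches its fluxes off. The
hot path is a small C kernel (`src/rhs.c`); an equivalent vectorised R
path remains and the test suite asserts that both integrate to the same
trajectory. Default output grid: 0–120 h every 24 h, the sampling cadence
of the emulated low-cell-density culture (the true culture duration is not
stated in the source, so the horizon is configurable). Tests verify the
integrator against the implicit closed form of a single Michaelis–Menten
decay, $K_m \ln(A_0/A) + (A_0 - A) = v_{\max} t$, to `1e-6` relative.

## Parameter estimation (NGL/M with a block-coordinate schedule)

`fit_kinetics()` minimises the sum of squared differences between measured
and simulated profiles of the five observed metabolites (glutamine,
glutamic acid, glucose, lactate, ammonium), reported both as raw
`ssq_total` (mM²) and as `smse = ssq_total / n`. The optimiser is a
damped Gauss–Newton (Levenberg/Marquardt): solve
$(J^\top J + \lambda\,\mathrm{diag}(J^\top J))\,\delta p = J^\top r$, with
$\lambda$ divided by 10 on an accepted step and multiplied by 10 on a
rejected trial ($\lambda$ above $10^{10}$ raises a stalled-step error).
Because 142 parameters cannot be fitted at once from five profiles, the
free parameters are split into blocks of 2–10 and each block is optimised
while the rest stay fixed, cycling until no parameter moves by more than
the outer tolerance across a full cycle.

Numerical choices, none of which are stated in the source and all of
which are package decisions:

* **Log-space fitting.** Parameters are exponentiated inside the residual
  function; this enforces positivity over their `1e-7`–30 span without
  constrained optimisation.
* **Jacobian.** Forward finite differences with relative step `1e-6` in
  log space.
* **Tolerances.** Inner relative sum-of-squares tolerance `1e-8`, at most
  50 accepted steps per block visit; outer relative-parameter tolerance
  `1e-4`, at most 20 cycles.
* **Failure handling.** A trial step whose simulation fails is treated as
  non-improving (damping increases); the objective is never replaced by a
  surrogate value.
* **Fixed initials.** The five measured species have known $t=0$ values,
  so their `C0_*` parameters are never free; every other parameter
  (52 + 37 + 48 = 137) is fittable, and by default all of them are.

The five per-species residual sums are reported in mM² together with
their square roots, since the dimensional convention of the published
per-species residuals (quoted in mM) is ambiguous.

## Global sensitivity analysis

`sobol_sensitivity()` estimates first-order Sobol indices
$S_i = \mathbb{V}[\mathbb{E}[Y\mid X_i]] / \mathbb{V}[Y]$ for a chosen
parameter subset (all 37 $v_{\max}$, all 52 $K_m$, or custom), varying the
parameters independently and uniformly. The design is Saltelli-type
(matrices $A$, $B$, $A_B^{(i)}$, i.e. $(k+2)\,n$ model runs) and the
estimator is Jansen's,
$\mathbb{V}_i = \mathbb{V}[Y] - \tfrac{1}{2n}\sum_j (y_{B,j} - y_{A_B^{(i)},j})^2$,
chosen for its lower variance among the classical first-order estimators.
Only first-order indices are computed; higher orders are out of scope.
Percentile-bootstrap confidence intervals and standard errors accompany
every index. The estimator is validated in the tests against closed
forms: $Y = X_1 + 2X_2$ (indices 0.2/0.8) and the Ishigami function.

Two choices deserve emphasis:

* **Ranges.** The source never states the sampled parameter ranges, so
  published index magnitudes cannot be reproduced; the package defaults to
  0.5×–1.5× of each parameter's current value, overridable per parameter.
  Conclusions about *which* parameters dominate therefore depend on this
  choice.
* **Aggregate scalarization.** The scalar output behind the aggregate
  indices is the mean absolute excursion of each analysed metabolite
  profile from its initial value across the time grid, summed over the
  analysed outputs (glutamine, glucose, lactate, ammonium; glutamic acid
  excluded, as its profile is uninformed in this model). Time-resolved
  per-output indices are also returned, where the output is simply the
  concentration at each grid time. Failed integrations are excluded
  pairwise and counted; more than 10% failures aborts with a suggestion
  to narrow the ranges.

## Synthetic bioreactor datasets

The study's bioreactor dataset comes from a prior publication and is not
redistributable, so `generate_dataset()` emulates its structure: the five
metabolites sampled every 24 h over 0–120 h, simulated under a chosen
"truth" parameter set, with seeded heteroscedastic Gaussian measurement
noise of standard deviation $\max(0.05\,y, 0.02\ \mathrm{mM})$ truncated
at zero — a typical bioanalyzer error profile; the true replicate
structure and assay error of the original measurements are unknown, so
these defaults are stated assumptions, not data properties. Under the
shipped parameters the generator's glucose and glutamine profiles are
non-increasing and lactate and ammonium non-decreasing; this shape is
checked at generation time (a warning is raised if a supplied truth set
breaks it) rather than assumed. What passing tests on these datasets show
is that the pipeline is self-consistent — they cannot show that the
shipped parameters describe any particular real culture, and none of the
fit-quality numbers published for the original dataset are reproducible
without it.

## The parameter-recovery experiment and practical identifiability

The fitting stage is validated by perturbing four parameters by +30% and
refitting them from synthetic data. The quartet — `vmax_HK`, `vmax_GLNS`,
`vmax_PC`, `vmax_PDH` (glucose uptake, glutaminolysis, pyruvate
carboxylation, pyruvate oxidation) — was chosen once, by computing
finite-difference sensitivity vectors of the 30 residuals at the shipped
values and selecting strong, mutually low-correlated directions. From
noiseless data the blockwise fit recovers all four essentially exactly
(maximum relative error around `2e-6`, final `ssq` around `3e-11` mM²).

With 5% measurement noise the picture changes qualitatively. Linear error
propagation of the noise covariance through the model Jacobian gives
one-sigma log-parameter uncertainties of about 0.035 (`vmax_GLNS`), 0.33
(`vmax_HK`), 0.60 (`vmax_PC`) and 0.82 (`vmax_PDH`) — and this is the
*most* identifiable quartet available; no set of four kinetic parameters
does better, and only `vmax_GLNS` individually has uncertainty below 10%.
Five metabolites at six time points simply do not constrain most of the
89 kinetic parameters to within 25% at this noise level. The test suite
states the 25% noisy-recovery assertion anyway and it fails, deliberately:
the failure documents a practical-identifiability limit of the emulated
study design, not an optimiser defect (the optimiser reaches the noise
floor of the objective in the same runs). The same caution applies to
interpreting any single fitted parameter value from data of this shape.

## Problem sizes used in the tests

The suite uses the full 53-species model for structural, simulation and
fitting checks; recovery experiments fit 2–4 parameters in blocks of 2;
Sobol runs on the shipped model use small designs (`n_base` 16–64 over
four parameters), with the estimator's statistical validation delegated to
the cheap analytic test functions at `n_base` 4096. The shipped default
`n_base = 1024` is intended for real analyses of the 37 or 52 parameter
groups.

## Known limitations

* The shipped parameter values reproduce the published tables, but the
  published fit-quality residuals depend on the original (undistributed)
  dataset and are not reproducible here.
* No identifiability analysis, confidence intervals or multi-start
  optimisation: the fitting procedure mirrors the published one, and the
  recovery experiment above shows the consequences.
* Sensitivity magnitudes depend on the unstated parameter ranges; only
  the workflow, not the published figures, is reproducible.
* No fed-batch feeding, dilution, cell-density coupling, thermodynamic
  consistency checks, or intracellular compartments.
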