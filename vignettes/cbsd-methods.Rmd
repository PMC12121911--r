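---
title: "The CBSD model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The CBSD model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`cbsd` implements a cascading-bistable-switch (CBS) gene-circuit model
of TGF&beta;-driven epithelial&ndash;mesenchymal transition (EMT),
extended with the tumour suppressor DLC1 (the CBSD model). The CBS core
consists of two coupled double-negative feedback switches: SNAIL1
represses miR-34 while miR-34 represses SNAIL1 translation (the first,
reversible switch), and ZEB1 represses miR-200 while miR-200 represses
ZEB1 translation (the second switch). SNAIL1 activates *zeb1*
transcription, coupling the switches in a cascade, and miR-200
represses autocrine TGF&beta; production, so that once the second
switch is on, the autocrine loop keeps total TGF&beta; signal high and
locks the mesenchymal state in even after the exogenous stimulus is
removed. E-cadherin (repressed by SNAIL1 and ZEB1) and N-cadherin
(activated by both) are the phenotype readouts; cells are classified
E / P / M from the N-cadherin level.

All regulation uses Hill kinetics,
$h^+(x) = x^n/(J^n + x^n)$ for activation and its complement for
repression, with mass-action translation and first-order degradation.
The eleven state variables (concentrations, µM; time in model hours)
are the nine core species plus *dlc1* mRNA and DLC1 protein.

The DLC1 arm adds three edges:

* TGF&beta; &rarr; *dlc1* transcription (rate `kd1`, threshold `J1d`),
  standing in for MAPK signalling downstream of the receptor;
* ZEB1 &rarr; *dlc1* transcription (rate `kd2`, threshold `J2d`), a
  weak edge that saturates at low ZEB1 levels, so *dlc1* does not keep
  rising as ZEB1 climbs during late EMT;
* DLC1 &rarr; *snail1* transcription (rate `ks2`, threshold `J2s`), an
  **additive** activating term next to the direct TGF&beta; term
  `ks1`&middot;h&#8314;. The additive form keeps the two routes
  symmetric, which is also why the posterior ties `ks1:J1s` and
  `ks2:J2s` into ridges (see below); the multiplicative alternative
  would be a one-line change in `cbsd_rhs()`.

The stable knockdown multiplies all *dlc1* transcription by
`1 - k_knockdown`: a constant fraction of transcripts is removed
regardless of the *dlc1* level, which is the natural reading of a
constant knockdown efficiency. A first-order removal term was rejected
because its effective knockdown fraction would depend on the *dlc1*
concentration.

## Where the core numbers come from

The CBS core rate constants used here are the package's own
reconstruction: the published parameter table for the core cascade was
not available to this implementation, so rates and thresholds were
chosen, once, so that the core reproduces the documented qualitative
structure &mdash; a single epithelial attractor at rest plus the
irreversible mesenchymal attractor; a reversible E&harr;P switch whose
folds both sit at positive exogenous dose; a stable partial branch at
intermediate doses (roughly 1.15&ndash;1.45&nbsp;ng/ml in the
calibrated model, with a long-lived partial plateau on the way to M at
1.5&nbsp;ng/ml, as in the reference core); a two-step
E&rarr;P&rarr;M transition at 10&nbsp;ng/ml
&mdash; and the stated concentration scales (*dlc1* and *snail1* below
0.1&nbsp;µM at rest). Exogenous dose (ng/ml) is converted to µM-scale
signal by the single constant `tgf_unit_scale` and added to the
autocrine pool before every Hill evaluation.

Two structural choices deserve emphasis because they deviate from the
"default n = 2 everywhere" convention:

* **DLC1 &rarr; snail1 uses n = 6.** The knockdown phenomenology
  requires strong ultrasensitivity in this lumped edge. With n = 2 a
  56% reduction of *dlc1* production can reduce the DLC1-routed
  *snail1* drive at most (0.44)&sup2; &asymp; 0.19-fold; that is not
  enough to trap knockdown cells in the epithelial state at
  10&nbsp;ng/ml while control cells still complete EMT and the partial
  state survives, and the tristability window in `k_knockdown` then
  cannot coexist with the reported `ks1` window. The edge lumps a
  multi-step signalling cascade (DLC1 &rarr; Rho &rarr; MAPK &rarr;
  transcription), for which high effective cooperativity is the
  standard reading.
* **TGF&beta; &rarr; dlc1 uses n = 4** with a threshold low enough
  that the *dlc1* promoter is near saturation at stimulating doses.
  This reconciles a steep knockdown response with the measured
  *dlc1*/*snail1* ratios (0.77 untreated, 0.99 treated), which demand
  a ~100-fold *dlc1* induction between rest and full stimulation.

A consequence of this reconstruction worth knowing: the knockdown
`ks1` diagram has **four** saddle-nodes and a **single** stable partial
branch, not five saddle-nodes with two distinct partial branches. A
second partial state would need an attractor with intermediate ZEB1,
which the sharp miR-200/ZEB1 switch of this core does not admit; probes
over the ZEB1&rarr;*dlc1* edge parameters did not produce one without
destroying the 1.5&nbsp;ng/ml partial state. Window edges are therefore
measured on the single partial branch.

## Calibration

The extension (12 kinetic parameters plus `k_knockdown`) is fitted on
log10 scale, bounds $[10^{-5}, 10^{2}]$, to a dataset assembled by
`build_dataset()`:

* CBS-core reference trajectories for all nine shared species at
  10 ng/ml (grid 0&ndash;1000 h by 25 h),
* *zeb1*/ZEB1 reference points at 1.5 ng/ml over the reference's
  partial plateau (0&ndash;600 h; at later times the reference itself
  leaves the plateau), which pin the location of the partial state,
* the printed *dlc1*/*snail1* ratios, entered as ratio observables
  (value 0.77 untreated at the pre-stimulation steady state, 0.99
  treated at the late steady points) so the constraint binds the
  model's own *dlc1*:*snail1* proportion rather than a value borrowed
  from the reference &mdash; tying the pseudo-observation to the
  reference *snail1* decouples the constraint from the model whenever
  its basal *snail1* drifts inside its loose sd,
* knockdown *dlc1* and *snail1* pseudo-observations: fold change times
  the control steady value, replicated at 14 fitting time points
  between 180 and 1000 h.

Observation noise is 5% of each species' dynamic range (the study does
not publish weights); the 14-point knockdown block's sd is shrunk by
$\sqrt{14/41}$ so that block carries weight comparable to one full
trajectory. The knockdown fold changes themselves are not printed as
numbers in the text available to us; the generator defaults are
`fc_dlc1 = 0.44` &mdash; chosen so the implied maximum-likelihood
knockdown fraction reproduces the reported ~56% &mdash; and
`fc_snail1 = 0.12`, encoding the reported near-complete suppression of
TGF&beta;-induced *snail1* upregulation under knockdown. qPCR replicate
noise is lognormal with CV 0.2, matching the visual spread of typical
fold-change replicates; these are assumptions, stated once here, not
measured facts.

The optimiser is a self-contained differential evolution (rand/1/bin,
F = 0.7, CR = 0.9, Latin-hypercube initial population) with a
gradient-free local polish, best of several starts; the interface
accepts the study-scale 15 starts &times; 100 particles unchanged.
The shipped calibration is deliberately two-staged. Unconstrained
likelihood optimisation over all 13 extension parameters repeatedly
found minima that trade away the attractor structure: the knockdown
fold-change block admits both a `ks1`-heavy and a DLC1-route-heavy
optimum, and the `ks1`-heavy one floors the epithelial drive above the
partial branch's collapse threshold, eliminating the upper edge of the
`k_knockdown` window &mdash; a steady-state property the finite
observation window cannot see. The final round therefore fixes the
drive architecture (the printed `ks1` = 0.0047 µM/h treated as an
input, thresholds and exponents from the structural stage, fast *dlc1*
turnover `kd_dm` = 0.4/h, `kD_tl` = 3/h, `kd_D` = 1.5/h, which removes
most of the DLC1 ramp lag) and fits the *dlc1* transcription rates and
the knockdown fraction; the result reaches a per-species NRMSE of at
most 4.1% against the 10&nbsp;ng/ml reference, ratios 0.74/0.99, and
an ML knockdown fraction of 0.540. The posterior is explored with an adaptive-Metropolis
sampler (Haario-style covariance adaptation beginning after 500
iterations), burn-in removed by the Geweke z-score (window fractions
0.1/0.5), effective sample size from the truncated autocorrelation sum.
Desk-scale chains are 2&times;10&#8308; iterations; extending to the
study's 10&#8310; is a single argument. The pairs `ks2:J2s` and
`kd2:J2d` come out rank-correlated above 0.99 &mdash; an expected
structural degeneracy, since each drive enters approximately as a power
law $k\,(x/J)^n$ in the relevant regime, leaving only $k/J^n$
identifiable &mdash; and `reduce_model()` fixes each pair's log-ratio
at the posterior mode. `ks1:J1s` is only moderately correlated here
(rank correlation &asymp; 0.4): in this calibration the knockdown
fold-change block pins the direct TGF&beta; route absolutely, which
breaks that pair's ridge.

## Deterministic protocol and classification

Every simulated experiment follows the equilibrate-then-stimulate
protocol: integrate from an entirely epithelial initial state (E-cad
and both microRNAs at their basal production/degradation ratios,
everything else zero) without exogenous TGF&beta; (default 100 time
units; the analysis scripts use longer equilibrations where a tight
steady state matters), then apply the dose. The integrator is `lsoda`
at rtol 1e-8 / atol 1e-10.

Phenotype thresholds on N-cadherin are data-derived, never hard-coded:
the control-condition TGF0 bifurcation is computed, the N-cad values of
its stable branches are pooled, and the two cuts are placed at the
midpoints of the two widest gaps. With the shipped parameters the cuts
land near 0.27 and 1.7 µM. One model time unit is nominally an hour;
the single conversion constant `time_units_per_day()` (= 100) maps
simulation time onto experimental days so that the 180&ndash;1000 h
calibration window spans roughly days 2&ndash;10. That mapping is a
modelling convention; no printed number fixes it.

## Bifurcation analysis

Continuation is pseudo-arclength (Euler predictor along the branch
tangent, Newton corrector on the bordered system) in coordinates scaled
per species and by the parameter-range width, so saddle-node turning
points are traversed rather than stalled at. Stability comes from the
eigenvalues of a central finite-difference Jacobian (relative step
1e-6). Folds are detected by sign changes of det(J) along the branch
and localised by step bisection to 1e-4 of the range width; the toy
normal forms $\dot x = r - x^2$ and $\dot x = r + x - x^3$ are used as
closed-form oracles in the test suite. `assemble_diagram()` harvests
fixed points at five anchor parameter values from relaxations of an
E/P/M-covering seed library, continues each in both directions, merges
duplicate branches by proximity in (parameter, N-cad) space, and pools
fold points. Anchor/seed coverage is established by our own convergence
checks, not by any published setting. Only codimension-1 folds are
detected; no oscillatory instabilities arise in this model.

## Stochastic simulation

The reaction network lists every elementary process separately (each
additive transcription source term, each translation, each
degradation: 32 reactions), and the exact direct-method sampler runs on
molecule counts with system size &Omega; (molecules per µM):
zeroth-order rates scale by &Omega;, first-order rates use counts
directly, Hill-modulated terms are evaluated at count/&Omega; and
scaled by &Omega;. A compiled kernel with a reaction dependency graph
(only propensities touched by the fired reaction are recomputed) makes
population runs practical; it consumes R's RNG in the same order as the
plain-R reference loop, so the two engines produce bit-identical
trajectories for the same seed.

&Omega; sets the intrinsic noise scale and is not printed in the study.
Following the calibration-input reading of that gap, the package
default (&Omega; = 1250) was fixed once so that the knockdown
population started mesenchymal reproduces the reported E/P split at the
10-day horizon; the stochastic analysis script reports the split's
&Omega;-sensitivity (at &Omega; = 800 the same run gives roughly
62%/38%, at 4000 roughly 3%/97%), which is strong &mdash; the split
should be read as &Omega;-conditional. Endpoint classification applies
the deterministic thresholds to the N-cad average over the last 5% of
the horizon to suppress shot noise. Per-cell seeds are `seed + i` and
are logged in the population summary.

## Heterogeneity ensembles

The RACIPE-style analysis draws each kinetic parameter independently
from a normal distribution centred on its ML value with standard
deviation 0.2 times the value ("variance of 20%" is read as a relative
standard deviation &mdash; a literal variance of 0.2&times;value has
inconsistent units), truncated to positive. Hill coefficients are held
fixed: they define the model structure rather than a cell-to-cell
kinetic quantity. By default all (non-Hill) parameters vary, with
`which =` to restrict to the extension only. Washout runs switch the
exogenous dose to zero at 7 experimental days, matching the
knockdown-after-EMT protocol, and are configurable.

## What the synthetic data do and do not show

The qPCR generator reproduces the *shape* of relative-quantification
data &mdash; multiplicative (lognormal) replicate noise around true
fold changes, an untreated control centred on 1, a time-stable
knockdown &mdash; but none of the Ct-level mechanics (primer
efficiencies, housekeeping normalisation). The phenotype-mixture
generator draws marker levels lognormally around the model's own
phenotype fixed points; real single-cell marker distributions are wider
and overlap more. Tests passing on these generators therefore validate
the pipeline's arithmetic and its statistical contracts, not the
biology of any real cell population: in particular the model starts
from an entirely epithelial population, whereas real populations are
heterogeneous mixtures even before stimulation.

## Numerical choices and degenerate inputs

* Integration failures name the species with the largest local rate
  and, in grid scans, mark the cell missing rather than aborting.
* States are clamped at zero after integrator micro-excursions; the
  rhs rejects states below &minus;1e-6 µM as genuine errors.
* Newton refinement of fixed points is damped (step halving on
  residual growth) and fails soft (dropped seed) rather than hard.
* Zero-width fit bounds short-circuit the optimiser and return the
  pinned value; all-zero propensities terminate an SSA run early with
  an `absorbed` flag.
* Fold bisection stops at 1e-4 of the parameter-range width; duplicate
  folds within 1% of the range and 5% in N-cad are pooled.

## Problem sizes used by the shipped analyses

Deterministic runs integrate to 1000&ndash;1500 time units
(10&ndash;15 experimental days). Populations use 200 cells (60 for the
&Omega;-sensitivity scan), diagrams use five anchors with adaptive
steps, the desk-scale MCMC uses 2&times;10&#8308; iterations over the
six ridge parameters, and the ensemble uses 300 parameter sets per
condition. Every stochastic entry point takes an explicit seed, and
identical seeds reproduce identical artifacts end to end.

## Known limitations

* The CBS core is a reconstruction; quantities that depend on the
  original parameter table (exact fold positions, exact ML estimates)
  should be compared at the structural level, not digit by digit.
* The ZEB1 amplitude of the partial plateau at 1.5 ng/ml is lower than
  the reference core's (the DLC1-routed drive cannot push SNAIL1 as
  close to the second switch's threshold without destabilising the
  partial state), so the 1.5 ng/ml block carries a visible residual in
  the fit.
* One stable partial branch, not two; four saddle-nodes in the
  knockdown `ks1` diagram rather than five (see above).
* The knockdown E/P split is &Omega;-conditional.
* No transient TGF&beta; inputs, no delay terms, no extrinsic noise or
  cell-division partitioning; *snail1*'s experimentally observed late
  decline is outside the model, which only activates *snail1* and
  *zeb1* under stimulation.
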