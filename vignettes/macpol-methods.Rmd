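---
title: "macpol: model, scoring, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{macpol: model, scoring, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the kinetic model and its assumptions, the scoring conventions, the
numerical machinery, and the places where the design was genuinely open and
a choice had to be made. It states no empirical result that the test suite
does not itself compute.

## 1. Model formulation

State variables are absolute copy numbers per cell (dimensionless counts);
extracellular ligands live in a nominal medium volume of `1e-6` mL per cell
(about 10^6 cells/mL of culture), which fixes the conversion from ng/mL
doses via `copies = dose[g/mL] / MW[g/mol] * N_A * V[mL]`. A 10 ng/mL dose
of a 17 kDa cytokine is therefore ~3.5e5 copies per cell.

Kinetics are restricted to six rate-law kinds: mass action over the
reactant multiset, constitutive synthesis, first-order decay, Hill
activation `k A^n/(K^n + A^n)`, Hill inhibition `k K^n/(K^n + A^n)`, and
Michaelis–Menten in a regulator (a superset of the Hill forms kept because
nothing in the modeled biology excludes it; Hill with `n = 1` coincides
with it analytically, which the tests exploit as an oracle). Two structural
conventions keep the ODEs well-posed:

* **Conversions are catalytic mass action.** An activation step
  `X → X*` driven by an upstream species `U` is written
  `X + U → X* + U`, so the flux vanishes as its substrate is depleted and
  no state can be driven negative by a regulator-only flux.
* **Regulator-only Hill terms appear exclusively in synthesis reactions**
  (no reactants), where a non-depleting flux is physically meaningful
  (transcription and translation channels). A gene with several inputs
  carries one synthesis reaction per input channel; activation channels
  add, repression gates a channel's basal flux through Hill inhibition.

Reversible steps are represented as explicit forward/backward reaction
pairs. Conserved moieties (receptor trafficking cycles without synthesis,
the NF-κB shuttling pool) are declared on the network and checked
symbolically by `validate_network()`: the declared weighted stoichiometric
sum must vanish for every reaction.

## 2. The reference network

`build_reference_network()` encodes the seven-pathway topology: six
receptor-mediated cytokine pathways and oxygen sensing. Every receptor
module has binding, unbinding, internalization and recycling; five cycles
are closed (declared conserved), while the IL-4 receptor is synthesized and
degraded because IL-10/STAT3 upregulates its production. VEGF is carried by
two isoforms competing for VEGFR1 — 165a signals, 165b occupies. IL-1Ra is
secreted into an extracellular pool that binds the IL-1 receptor into a
non-signaling complex, closing the sixth autocrine loop; with TNF-α,
IL-1β, IFN-γ, IL-10, VEGF165a, IL-12, CXCL9 and IL-1Ra the model carries
eight secreted markers.

The parameterization is **desk-calibrated**: rates were chosen by hand to
satisfy (i) the directional response catalogue (`directional_response_suite()`
— about forty induction/repression assertions under single stimuli,
hypoxia, and miR-93 overexpression), (ii) plausible timescales (receptor
events minutes, transcription-factor cycles 0.5–4 h, marker mRNA/protein
4–48 h), and (iii) the qualitative dynamic signatures: IFN-γ self-limits
through SOCS1, IFN-γ + IL-4 repolarizes from early M1 to late M2, the
hypoxic response induces both M1 and M2 arms nearly symmetrically, and
100×-diluted doses always elicit weaker polarization. No numerical identity
with any externally published parameter set is claimed; such a model can
be loaded through `read_sbml()` when available.

Six parameters keep their conventional intervention names so that the
standard repolarization experiments are expressible verbatim: `kf3` (STAT1
activation by receptor-associated JAK), `k26` (STAT6 dephosphorylation),
`k127` (STAT3 dephosphorylation), `k85` (IRF1 degradation), `k101` (SOCS1
degradation), `kf62`/`kf63` (PHD-mediated HIF1α/HIF2α hydroxylation).

**Oxygen convention.** O₂ enters only through PHD activity, scaled linearly
by `percent/21`; 21% is identity, 2% scales hydroxylation to 2/21. This is
the simplest monotone convention consistent with oxygen-dependent HIF
stabilization; a saturating (Michaelis–Menten in O₂) mapping can be
substituted by editing the two parameters directly.

## 3. Simulation engine

The right-hand side and an L-stable Rosenbrock(2,3) integrator (the
`ode23s` pair of Shampine & Reichelt) are implemented in C++; one
finite-difference Jacobian and one LU factorization per step. A stiff
method is non-negotiable here: copy numbers span below 10^0 (active
complexes at rest) to above 10^5 (ligand pools after dosing) with rates
from minutes to days. Because linear conserved sums annihilate both the RHS
and its finite-difference Jacobian exactly, the integrator preserves
declared moiety totals to rounding error, which the tests check at 1e-8
relative over 48 h.

Defaults: `rel_tol = 1e-6`, `abs_tol = 1e-9 × max initial amount`.
Event handling restarts the integration at every dose/intervention time;
simultaneous events apply doses first, then oxygen, then interventions. The
state recorded at an event time is post-event. Pre-equilibration
(`equilibrate()`: relative-derivative criterion 1e-6/h, 500 h horizon, with
autocrine secretion live) precedes every protocol unless a state is
supplied; keeping the autocrine loops live during equilibration was a
choice — the alternative (clamping secreted pools to zero at rest) would
make the untreated baseline depend on when feedback is switched on.

## 4. Scoring

Marker readouts follow the panel annotation: protein level, transcript
level, or production rate (the instantaneous flux of secretion-tagged
reactions — a production-rate readout responds faster than an accumulated
pool, which matters for the early M1 phase of combined stimuli). Fold
changes are taken against the untreated t = 0 baseline with the denominator
floored at `1e-6 ×` the trajectory maximum to keep near-zero baselines from
exploding the ratio.

There is no canonical closed-form definition of the composite score in
the experimental literature, so the score here is a declared choice: the geometric mean of panel fold changes, and the M1/M2
score their ratio. The geometric mean is the only simple mean that makes
the score invariant to marker re-ordering and to unit rescaling of any
single marker, and it makes panel-swap invert the score exactly — all three
properties are locked by tests. Classification thresholds are
`delta = 0.05` log10 units for trajectory classes (flat / self-promoting /
self-limiting / self-repolarizing) and `tau = 0.1` for cell labels
(M1-like / M2-like / M0\*); both are exposed as arguments.

## 5. Sensitivity analysis

`lhs_sample()` stratifies each parameter's log10 range (default ±10-fold
around nominal, a standard screening span) into n equal-probability bins with one draw per bin.
`prcc()` rank-transforms design and output and computes partial
correlations through the precision matrix of the joint rank-correlation
matrix; when the output is perfectly rank-correlated with one input (exact
monotone toy models) it falls back to explicit residual regressions,
treating zero-variance residuals as zero association. P-values use the
t transform with `n − 2 − (p − 1)` degrees of freedom, with
Benjamini–Hochberg adjusted values reported alongside; the influential set
follows the `|PRCC| > 0.1` convention, not p-values. An independent
lm-based oracle re-derives the coefficients in the tests to 1e-10.

## 6. Virtual populations

Cell-to-cell heterogeneity is modeled as independent log-normal multipliers
(log10-sd `sigma_log10 = 0.15` by default) on all kinetic parameters —
"same mechanisms, different innate rates". Initial-condition perturbation
is deliberately not the default; amounts follow from the rates at rest.

The t = 0 state of each cell required a real design decision. Fully
equilibrating every cell makes an unstimulated population trivially 100%
unpolarized (each cell is normalized to its own fixed point); starting all
cells at the shared reference state makes the majority spuriously
polarized by 24 h of free drift. The package therefore seeds every cell
from the shared reference resting state and lets it settle for
`preincubation_h = 24` h before the experiment — the in-silico analogue of
plating a common stock and resting it overnight. Most cells reach their
private attractor within the window; cells with slow drift modes retain a
residual offset, so an unstimulated population is mostly M0\* with a small
spontaneously polarized minority, which is the behavior single-cell
experiments report. Acceptance screening is unchanged: a cell is rejected
if its own resting state fails to converge (200 h horizon) or any species
with a reference baseline above one copy leaves `[1/20, 20]×` the reference
baseline.

## 7. Calibration machinery

The objective is a weighted sum of squared residuals between normalized
simulation and normalized data, with one shared pre-equilibrated baseline
per parameter vector and the five normalization modes used by experimental
time courses (t0, max, last timepoint, named reference timepoint, named
reference condition). Fitting runs multi-start `nlminb` in log10-parameter
space inside box bounds (positivity and scale spread for free);
`include_nominal_start = FALSE` switches to purely randomized starts, which
is how the bootstrap exposes flat directions: for a deliberately
non-identifiable synthesis pair only the product is pinned by steady-state
data, so replicates scatter along the ridge (high per-parameter CV, low
product CV). The bootstrap resamples whole datasets, not points — datasets
are the independent units of a literature corpus. Full-corpus recalibration
is out of scope by design; fitting is exercised on motifs.

`generate_synthetic_datasets()` is first-class, tested code: it simulates
conditions, samples a realistic 0–48 h grid, applies multiplicative
log-normal noise and a normalization mode, and is seed-deterministic. It
emulates sparse normalized time courses of single readouts; it does not
emulate inter-laboratory variability, systematic normalization
disagreements between studies, or measurement-model differences between
blot, qPCR and ELISA data — a green recovery test therefore establishes
that the optimizer and objective are sound, not that the reference model is
identifiable from literature-scale data.

## 8. Known limitations

* The reduced network is a topological, not numerical, stand-in for a
  fully calibrated large-scale model; no claim of matching any external
  parameterization's trajectories is made.
* Serum and proliferation effects are excluded; HSS is represented as 2%
  O₂, optionally with globally scaled-down synthesis
  (`hss_variant()`).
* Doses are instantaneous boluses; no washout, infusion or
  pharmacokinetics.
* Single well-mixed cell: autocrine and paracrine signaling coincide.
* The SBML subset excludes events, rules, function definitions and initial
  assignments; kinetic laws outside annotated/recognizable products raise
  explicit unsupported-feature errors rather than being evaluated
  generically.
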