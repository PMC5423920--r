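---
title: "Constraint-based model evaluation with gsmmtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based model evaluation with gsmmtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsmmtools)
```

## The model and its assumptions

gsmmtools analyses genome-scale metabolic models under the standard
constraint-based assumptions: the cell is at metabolic steady state
(`S v = 0`), fluxes are box-bounded (`lb ≤ v ≤ ub`, with the ±1000
mmol/gDCW/h sentinels kept literal rather than treated as infinities), and
the phenotype of interest is the optimum of a linear objective, almost
always the biomass reaction. Growth predictions therefore inherit the usual
caveats of flux balance analysis: no kinetics, no regulation, and a flux
vector that is generally non-unique at the optimum. The package treats only
the objective value `Z` as canonical from plain FBA; any downstream claim
about individual fluxes (flux correlations, predicted gas exchange rates)
goes through parsimonious FBA, which selects the minimum-total-flux vector
among the optima and in particular carries zero flux around closed internal
cycles.

Gene–protein–reaction rules are Boolean trees over gene ids with `and`
binding tighter than `or`; a deletion disables exactly the reactions whose
rule evaluates false with the deleted genes absent. Reactions without a
rule are spontaneous or orphan reactions and are never disabled — the
standard convention in published reconstructions. Essentiality is a pure
function of the knockout/wild-type growth pair: essential below
`eps_zero = 1e-6` 1/h (published definitions say growth "was 0", which is
numerically unusable, so a threshold is required), non-essential above
`(1 - delta)` of wild type with `delta = 1e-3`, partially essential in
between. Both thresholds are arguments.

## The LP core

No linear-programming package is assumed. The solver is a bounded-variable
primal simplex (two-phase, explicit artificial variables) using Bland's
rule in both phases. Bland's rule is deliberate: knockout models fix
`lb = ub = 0` on many columns and chemostat fitting pins exchange rates to
equalities, so the LPs are heavily degenerate, and anti-cycling correctness
matters more than pivot-count speed at the network sizes involved (tens of
reactions). Numerical choices: pivot rejection below 1e-11, ratio-test and
reduced-cost tolerance 1e-9, residual artificial mass above 1e-7 reported
as infeasible. Every optimal solution is certified post hoc:
`max |S v| ≤ 1e-7` and bound violations ≤ 1e-7, otherwise the solve errors
rather than returning a silently bad vertex. The independent check in the
test suite is a brute-force enumeration of basic solutions
(`fba_brute_force()`), a different algorithm entirely, exponential in the
reaction count and therefore restricted to networks of ≤ ~10 reactions.

pFBA fixes the first-stage optimum through the one-sided constraint
`cᵀv ≥ Z* − |Z*|·1e-9 − 1e-9` rather than an equality (robust to roundoff
in `Z*`), and splits each flux into non-negative forward/reverse parts so
the second stage is again a plain LP. The split formulation was chosen over
an absolute-value reformulation because it keeps every subproblem in the
same bounded-simplex form.

## Maintenance-energy fitting

For each chemostat observation the measured exchange rates and the growth
rate are pinned and the flux through the ATP maintenance reaction (`ATPM`,
ATP hydrolysis) is maximised; ordinary least squares of the resulting
`r_ATP` on μ gives the maintenance line `r_ATP = Y_xATP·μ + m_ATP` — slope
GAM (mmol ATP/gDCW), intercept NGAM (mmol ATP/gDCW/h). Two design points:

- `rate_tolerance` optionally relaxes each pinned rate to a ±fraction band,
  because exact equality can be infeasible with real measurement error. The
  default is 0 (exact): a one-sided band lets the LP take the most generous
  uptake in the band and would bias `r_ATP` upward, destroying exact
  recovery on clean data. Set it to ~0.02 for noisy laboratory tables.
- A negative fitted NGAM is physically impossible but statistically
  reachable; it is returned as-is with a warning rather than clipped, so
  the user sees the data problem.

## What the generators emulate — and what they do not

The synthetic-data module is first-class: every input the pipeline consumes
can be generated with known ground truth, and all generators are pure
functions of their spec and seed (the global RNG stream is saved and
restored).

- `make_toy_model()` builds chain / branched / parallel / cycle networks
  over a reduced element alphabet (C, H, O) in which every conversion is
  mass-balanced by construction — a yield-`y` step emits `2(1−y)` triose
  waste per hexose, so balance ground truth is hand-checkable. Planted
  defects (an orphan metabolite, an imbalanced reaction) are recorded in
  the emitted truth, as are the analytic FBA optimum
  (`uptake × best yield`) and per-gene essentiality classes.
- `make_random_model()` draws random sparse stoichiometries whose bounds
  always contain zero, so the LP is feasible and bounded by construction —
  the right property for stress-testing solver/oracle agreement, not a
  model of real network topology.
- `simulate_chemostat()` generates observations exactly on the maintenance
  line (GAM 20.4 mmol ATP/gDCW, NGAM 2.52 mmol ATP/gDCW/h by default, the
  fitted values reported for the *P. pastoris* reconstruction this workflow
  targets), with Gaussian noise on `r_ATP` mapped back into the glucose
  uptake through the companion `make_energy_model()` stoichiometry. In that
  model one glucose yields exactly `atp_yield` ATP and growth drains
  glucose without an ATP term, so the ATP-maximisation step returns the
  generating `r_ATP` identically.
- `make_physiology_model()` is a stylised aerobic network (glycolysis,
  pyruvate oxidation, P/O = 2 oxidative phosphorylation) with six
  macromolecule pools whose per-gram precursor/ATP costs are configurable;
  lipid is the ATP-expensive pool. Its default composition takes the
  midpoints of the scanned physiological ranges (protein 42%, lipid 11.2%,
  RNA 11.6%, DNA 0.55%, carbohydrate 31.9%, remainder in the small-molecule
  pool).

What passing tests on these fixtures demonstrate is that the *algorithms*
are correct: the LP core agrees with enumeration, the classifiers recover
planted truth, the fitting inverts its own forward model. They do not
demonstrate that a particular genome-scale reconstruction is accurate —
real networks bring compartmentalisation at scale, thousands of degenerate
optima, lumped biomass chemistry and measurement error that the toys
deliberately exclude. The genome-scale reproduction test therefore runs
only when the published supplementary tables are supplied.

## Other design decisions

- **Biomass renormalisation.** When a sensitivity scan varies one mass
  fraction, the remaining fractions are rescaled proportionally so the
  composition still sums to 1 g/gDCW. Proportional rescaling is the
  least-informative choice; absorbing the change into a single pool is
  possible by constructing the composition explicitly.
- **Infeasible scan points.** With NGAM > 0 and too little substrate the
  growth LP is infeasible (maintenance cannot be paid). Scans report such
  points with `status = "infeasible"` and μ = 0 — washout — which keeps
  monotonicity checks well-defined across the grid.
- **Expression support.** A reaction is "verified" when its GPR evaluates
  true with unexpressed genes absent (an intact isozyme or complete complex
  suffices). The laxer "any gene expressed" reading is available behind
  `criterion = "any"`; the GPR evaluation is the default because it is the
  reading consistent with knockout semantics.
- **Source screens.** Carbon candidates are opened at equal carbon supply
  (uptake scaled by 6/n_C relative to the glucose reference) rather than
  equal molarity, so a hexose and a triose are compared fairly; nitrogen
  candidates use the molar rate. Element membership comes from parsed
  formulas; unparseable or generic (R/X) formulas make a candidate
  "unscreenable" rather than guessed.
- **Dead-end definition.** The gap finder reports *root* dead ends — no
  producer or no consumer under admissible directions — matching the
  primary output of the classic gapFind approach; `transitive = TRUE`
  additionally freezes reactions touching blocked metabolites to a fixed
  point. Metabolites on exchange reactions are boundary species and are
  excluded. Published dead-end counts rarely state which mode they used, so
  both are provided and neither is asserted as canonical.
- **Metabolite counting.** `summarize_model()` reports both total
  compartmented entries and the unique count after stripping a trailing
  `_<compartment>` suffix, since published model statistics quote sometimes
  one, sometimes the other.
- **Serialisation.** Stoichiometric coefficients and bounds are written
  (TSV and SBML alike) with the shortest fixed-notation decimal that
  reparses to the identical double, so round-trips are bit-exact and never
  collide with the `+` separator of the equation grammar.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated
inputs: 100 random networks of ≤ ~16 reactions for the solver and gap
oracles, toy testbeds of ≤ 8 reactions for pFBA/essentiality, chemostat
series of 50 points × 200 noisy replicates for the maintenance fit, and a
5 × 9 NGAM-by-uptake grid for the sensitivity scan. These sizes keep the
enumeration oracle exact and the full suite in the tens of seconds on one
CPU; the package functions themselves accept larger models, with the pure-R
simplex as the practical ceiling (hundreds of reactions, not thousands).

## Known limitations

No flux-variability analysis, loopless-FBA MILPs, thermodynamic
constraints, or quadratic objectives; the SBML subset covers core + fbc
bounds/GPRs/objectives only and reports anything else as unsupported; gap
*filling* (as opposed to finding) is out of scope, as is computing ¹³C
fluxes — the package consumes them for comparison only.
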