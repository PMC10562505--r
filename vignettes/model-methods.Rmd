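---
title: "Model structure and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slncea)
```

`slncea` implements a cost-effectiveness comparison of two radiotracer
agents — technetium-99m tilmanocept and technetium-99m sulfur colloid — for
sentinel lymph node biopsy (SLNB) in early-stage (T1/T2, clinically
node-negative) oral cavity squamous cell carcinoma. This vignette documents
the model structure, the reward conventions, and the numerical choices; the
worked example in the README shows the headline results.

## Decision tree

Each strategy is a decision tree over the four diagnostic outcomes of SLNB
with occult nodal metastasis prevalence $p$ and the agent's sensitivity
$se$ and specificity $sp$:

| Branch | Probability | Up-front pathway |
|---|---|---|
| True positive  | $p \cdot se$ | resection + completion neck dissection + adjuvant mix |
| False negative | $p (1 - se)$ | resection only; worse disease-free transitions |
| False positive | $(1 - p)(1 - sp)$ | same unnecessary treatment bundle as a true positive |
| True negative  | $(1 - p) \, sp$ | resection only |

The positive pathway adds the neck-dissection cost and, with the observed
treatment mix (49% radiation, 15% chemoradiation), adjuvant therapy cost
and the corresponding one-time procedure disutilities. All four branches
then enter a Markov cohort model in the disease-free state; false negatives
use a distinct, worse disease-free transition row (about four times the
nodal-recurrence probability).

```{r tree}
cfg <- base_case_config()
branch_probabilities(cfg$prevalence, cfg$diag_tilmanocept)
```

## Markov cohort model

Five states — `NED` (no evidence of disease), `LR` (local recurrence), `NR`
(nodal recurrence), `DM` (distant metastasis), `Dead` — iterated over 30
one-year cycles at a 3% annual discount rate. Rewards are split into

* *membership* rewards: annual state cost and utility, accrued per year of
  state occupancy, and
* *entry* rewards: one-time costs and disutilities (salvage surgery plus
  adjuvant therapy entering `LR`/`NR`, palliative chemotherapy entering
  `DM`, end-of-life care entering `Dead`), charged on the off-diagonal
  probability flow into the state so self-transitions never re-charge them.

```{r markov}
tr <- run_cohort("NED", "standard", build_reward_spec(cfg),
                 cfg$transitions, cfg$horizon_years, cfg$discount_rate,
                 cfg$structural_variant)
tr
```

## Structural variants and calibration

Published cost-effectiveness tables rarely pin down every accrual
convention. The open choices are modeled explicitly as a
`structural_variant()` with five binary axes — annual-reward timing
(start/end of cycle), discount timing (first year discounted or not),
metastatic chemotherapy charged at entry vs annually, the adjuvant bundle
at recurrence (full radiation vs the 49%/15% mix), and one-time vs
persistent procedure disutilities — giving 32 combinations, plus an
optional half-cycle correction kept outside the calibration grid.

`calibrate_variant()` evaluates the base case under every combination and
ranks them by mean absolute relative error against the four published
primary outcomes (two expected costs, two expected QALY totals). The ICER
is deliberately excluded from the score: it is fully determined by those
four quantities, so including it would double-weight the increments, and as
a ratio of small differences it is numerically ill-conditioned as a
calibration anchor. The winning combination is frozen as
`calibrated_variant()` and is the default of `base_case_config()`.

```{r calibrate, eval = FALSE}
ranked <- calibrate_variant()
ranked[1:5, c("label", "qaly_til", "qaly_sul", "cost_til", "cost_sul",
              "score")]
```

The preference for tilmanocept at the $100,000/QALY threshold is not an
artifact of this selection: `evaluate_strategies()` prefers tilmanocept
under every one of the 32 variants (checked in the test suite).

## Cost-effectiveness arithmetic

`icer()` classifies the incremental comparison on the cost-effectiveness
plane (dominance, trade-off, equivalence) and reports
$\mathrm{ICER} = \Delta C / \Delta Q$ only in the trade-off quadrants.
Decisions use the net monetary benefit
$\mathrm{NMB} = \lambda Q - C$, which is continuous through the dominance
quadrants and identical to the ICER-threshold rule wherever the latter is
defined (a property-tested equivalence).

## Sensitivity analyses

`one_way()` and `two_way()` sweep parameters over the documented ranges
(`sensitivity_ranges()`), with swept transition cells proportionally
renormalized so each row stays stochastic. `find_threshold()` locates
decision thresholds by a dense sign scan of the NMB difference followed by
bisection, and is cross-checked in the tests against a much denser scan.
`dominance_region()` reports the contiguous sub-ranges where the
intervention is simultaneously cheaper and more effective.

## Microsimulation oracle

`simulate_patients()` runs individual patients through the identical tree
and chain with the same variant conventions, so its sample means are an
unbiased estimate of the cohort expectations. It uses a single uniform
stream with a fixed per-patient layout, making results seed-reproducible,
and serves as an independent stochastic oracle: the test suite requires
cohort–microsimulation agreement within Monte-Carlo error on randomly
generated parameter sets.

## Synthetic parameter sets

`random_config()` draws structurally valid configurations (Dirichlet-style
row sampling guarantees row-stochasticity; the false-negative disease-free
row is constructed stochastically worse than the standard row), and
`perturb()` jitters an existing configuration multiplicatively with
renormalization. Both are fuzzing surfaces for property tests, not
estimators of anything clinical.

## Numerical choices and limitations

* Transition rows are divided by their sums at matrix build, absorbing the
  printed rounding of the disease-free row (sum 1.001); the validator
  reports this as a `normalizable` finding rather than an error.
* Configurations serialize to YAML with enough precision that doubles
  round-trip bit-for-bit (`write_config()`/`read_config()`).
* The model is an annual-cycle cohort approximation: no within-year event
  ordering, no age- or time-dependent mortality, and recurrence states do
  not distinguish salvage outcomes beyond the published reward structure.
* The published input tables do not uniquely determine every published
  summary figure; where the model disagrees with a published number under
  all structural variants, the package reports its own computed value
  rather than adjusting inputs to match.
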