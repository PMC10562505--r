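# slncea

Cost-effectiveness model comparing two radiotracer agents for sentinel
lymph node biopsy (SLNB) in early-stage (T1/T2, clinically node-negative)
oral cavity squamous cell carcinoma: technetium-99m **tilmanocept** versus
technetium-99m **sulfur colloid**.

## The scientific problem

SLNB maps the draining sentinel nodes so that only patients with occult
nodal metastasis (prevalence $p = 0.28$) undergo completion neck dissection
and adjuvant therapy. The two tracer agents differ in diagnostic accuracy
(tilmanocept: sensitivity 0.979, specificity 0.990; sulfur colloid:
sensitivity 0.727, specificity 0.990) and in cost ($628 vs $105). A missed
metastasis (false negative) leaves disease untreated and raises the risk of
nodal recurrence and death; a false positive triggers an unnecessary
dissection and adjuvant therapy.

The model is a four-branch diagnostic decision tree (TP/FN/FP/TN) feeding a
five-state Markov cohort — `NED`, local recurrence `LR`, nodal recurrence
`NR`, distant metastasis `DM`, `Dead` — run for 30 annual cycles at a 3%
discount rate. Strategies are compared by the incremental
cost-effectiveness ratio $\mathrm{ICER} = \Delta C/\Delta Q$ and by net
monetary benefit $\mathrm{NMB} = \lambda Q - C$ at a willingness-to-pay of
$\lambda = \$100{,}000$ per QALY. See the vignette
(`vignettes/model-methods.Rmd`) for the full structure, the explicit
treatment of under-specified accrual conventions as `structural_variant()`
axes, and the calibration that selects the default variant.

## Worked example

```r
library(slncea)

run_base_case()
#> tilmanocept strategy: expected cost $84265, 7.0687 QALYs (discounted)
#> sulfur_colloid strategy: expected cost $82767, 6.9234 QALYs (discounted)
#> tilmanocept vs sulfur_colloid: delta cost $1497.84, delta QALY 0.1453
#>   ICER $10310 per QALY (WTP $100,000): prefer tilmanocept

# Decision threshold: how good would sulfur colloid's sensitivity have to
# get before it becomes the preferred strategy?
find_threshold(base_case_config(), "diag_sulfur.sensitivity",
               range = c(0.50, 1.00))
#> diag_sulfur.sensitivity: 1 decision threshold(s)
#>   0.9693: tilmanocept below, sulfur_colloid above

# Where is tilmanocept outright dominant (cheaper AND more effective)
# as sulfur colloid's specificity varies?
sw <- one_way(base_case_config(), "diag_sulfur.specificity",
              range = c(0.70, 1.00), n_points = 301)
dominance_region(sw)
#> # A tibble: 1 × 3
#>    from    to n_points
#>   <dbl> <dbl>    <int>
#> 1   0.7 0.869      170
```

Configurations are plain YAML (`write_config()` / `read_config()`, bundled
base case in `inst/extdata/base_case.yaml`), every parameter is addressable
by a dot-separated path (`set_parameter(cfg, "transitions.lr_row.LR->DM",
0.3)` with proportional row renormalization), and
`simulate_patients()` provides an individual-level microsimulation used as
an independent stochastic oracle for the cohort engine. A command-line
front end lives at `inst/cli/slncea.R` (subcommands: `validate`,
`base-case`, `one-way`, `two-way`, `threshold`, `dominance`, `microsim`,
`gen-config`).

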