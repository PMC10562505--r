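#' Probabilities of the four diagnostic branches
#'
#' Standard decomposition of a binary diagnostic test against true occult
#' nodal status: `p_tp = prevalence * sens`, `p_fn = prevalence * (1-sens)`,
#' `p_fp = (1-prevalence) * (1-spec)`, `p_tn = (1-prevalence) * spec`.
#'
#' @param prevalence Prevalence of occult nodal metastasis.
#' @param diag A [diagnostic_performance()] object.
#' @return An object of class `slncea_branches`: named numeric vector
#'   `c(TP, FN, FP, TN)` summing to 1.
#' @export
branch_probabilities <- function(prevalence, diag) {
  stopifnot(prevalence >= 0, prevalence <= 1,
            diag$sensitivity >= 0, diag$sensitivity <= 1,
            diag$specificity >= 0, diag$specificity <= 1)
  p <- c(TP = prevalence * diag$sensitivity,
         FN = prevalence * (1 - diag$sensitivity),
         FP = (1 - prevalence) * (1 - diag$specificity),
         TN = (1 - prevalence) * diag$specificity)
  structure(p, class = "slncea_branches")
}

agent_diag <- function(agent, cfg) {
  switch(agent,
         tilmanocept = cfg$diag_tilmanocept,
         sulfur_colloid = cfg$diag_sulfur,
         stop("unknown agent: ", agent))
}

agent_cost <- function(agent, cfg) {
  switch(agent,
         tilmanocept = cfg$costs$agent_cost_tilmanocept,
         sulfur_colloid = cfg$costs$agent_cost_sulfur_colloid,
         stop("unknown agent: ", agent))
}

# cost of the treatment bundle added for a positive biopsy, and the matching
# one-time QALY toll (a positive, non-negated magnitude)
positive_pathway <- function(cfg) {
  co <- cfg$costs
  ut <- cfg$utilities
  list(
    cost = co$concurrent_neck_dissection +
      cfg$p_rt_given_positive * co$radiation_therapy +
      cfg$p_chemo_given_positive * co$chemo_with_rt,
    disutility = -(ut$disutility_neck_dissection +
                     cfg$p_rt_given_positive * ut$disutility_rt +
                     cfg$p_chemo_given_positive * ut$disutility_chemo_rt)
  )
}

#' Upfront (cycle-0) outcome of one diagnostic branch
#'
#' Every patient pays the agent dose and the primary tumor resection. A
#' positive biopsy (TP or FP) additionally triggers completion neck
#' dissection and, per the assumed treatment mix, adjuvant radiation (49%)
#' and chemoradiation (15%) — false positives therefore incur unnecessary
#' treatment cost and disutility, which is what penalizes imperfect
#' specificity. Negative branches (FN, TN) move to surveillance with no
#' neck treatment. Under the default (one-time) disutility convention the
#' positive-pathway tolls are charged here as a cycle-0 QALY decrement;
#' under the `"persistent"` variant they instead lower the treated
#' patients' `NED` utility inside the Markov model and `upfront_qaly` is 0.
#'
#' @param branch One of `"TP"`, `"FN"`, `"FP"`, `"TN"`.
#' @param agent `"tilmanocept"` or `"sulfur_colloid"`.
#' @param cfg An `slncea_config`.
#' @return List of class `slncea_branch_outcome`: `branch`, `upfront_cost`,
#'   `upfront_qaly` (<= 0) and `markov_column` (`"fn"` iff `branch == "FN"`).
#' @export
branch_upfront_outcome <- function(branch, agent, cfg) {
  if (!branch %in% diagnostic_branches()) stop("unknown branch: ", branch)
  base_cost <- agent_cost(agent, cfg) + cfg$costs$primary_resection
  pos <- positive_pathway(cfg)
  positive <- branch %in% c("TP", "FP")
  once <- cfg$structural_variant$upfront_disutility == "once"
  structure(list(
    branch = branch,
    upfront_cost = base_cost + if (positive) pos$cost else 0,
    upfront_qaly = if (positive && once) -pos$disutility else 0,
    markov_column = if (branch == "FN") "fn" else "standard"
  ), class = "slncea_branch_outcome")
}

#' Expected lifetime outcome of one agent strategy
#'
#' Probability-weighted sum over the four diagnostic branches of the upfront
#' (cycle-0, undiscounted) outcome plus the discounted Markov continuation
#' from [run_cohort()], started in `NED` with the branch's transition
#' column.
#'
#' @inheritParams branch_upfront_outcome
#' @param keep_traces Keep the per-branch cohort traces in the result.
#' @return An object of class `slncea_outcome`: `agent`, `expected_cost`,
#'   `expected_qaly`, and optionally `trace_by_branch`.
#' @examples
#' til <- expected_strategy_outcome("tilmanocept", base_case_config())
#' c(til$expected_cost, til$expected_qaly)
#' @export
expected_strategy_outcome <- function(agent, cfg, keep_traces = FALSE) {
  p <- branch_probabilities(cfg$prevalence, agent_diag(agent, cfg))
  rewards <- build_reward_spec(cfg)
  v <- cfg$structural_variant
  rewards_pos <- rewards
  if (v$upfront_disutility == "persistent") {
    toll <- positive_pathway(cfg)$disutility
    rewards_pos$annual_utility["NED"] <-
      min(1, max(0, rewards$annual_utility["NED"] - toll))
  }
  traces <- list(
    standard_positive = run_cohort("NED", "standard", rewards_pos,
                                   cfg$transitions, cfg$horizon_years,
                                   cfg$discount_rate, v),
    standard_negative = run_cohort("NED", "standard", rewards,
                                   cfg$transitions, cfg$horizon_years,
                                   cfg$discount_rate, v),
    fn = run_cohort("NED", "fn", rewards, cfg$transitions,
                    cfg$horizon_years, cfg$discount_rate, v)
  )
  branch_trace <- c(TP = "standard_positive", FN = "fn",
                    FP = "standard_positive", TN = "standard_negative")
  cost <- qaly <- 0
  by_branch <- list()
  for (b in diagnostic_branches()) {
    up <- branch_upfront_outcome(b, agent, cfg)
    tr <- traces[[branch_trace[[b]]]]
    cost <- cost + p[[b]] * (up$upfront_cost + tr$total_cost)
    qaly <- qaly + p[[b]] * (up$upfront_qaly + tr$total_qaly)
    if (keep_traces) by_branch[[b]] <- tr
  }
  structure(list(agent = agent, expected_cost = cost, expected_qaly = qaly,
                 trace_by_branch = if (keep_traces) by_branch else NULL),
            class = "slncea_outcome")
}

#' @export
print.slncea_outcome <- function(x, ...) {
  cat(sprintf("%s strategy: expected cost $%.0f, %.4f QALYs (discounted)\n",
              x$agent, x$expected_cost, x$expected_qaly))
  invisible(x)
}
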