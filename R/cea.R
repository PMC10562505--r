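QALY_TOL <- 1e-9
COST_TOL <- 1e-6

#' Incremental cost-effectiveness of one strategy over another
#'
#' Computes the incremental cost and QALYs of `intervention` over
#' `comparator` and classifies the result on the cost-effectiveness plane:
#' * `"intervention_dominates"`: cheaper and at least as effective (or equal
#'   cost and more effective) — no finite ICER is reported;
#' * `"comparator_dominates"`: the mirror case;
#' * `"tradeoff"`: the deltas have the same decision-relevant structure
#'   (more costly and more effective, or cheaper and less effective) and
#'   `icer = delta_cost / delta_qaly`;
#' * `"equivalent"`: both deltas within tolerance of zero.
#'
#' @param intervention,comparator [expected_strategy_outcome()] results (any
#'   list with `expected_cost` and `expected_qaly` works).
#' @param wtp Willingness-to-pay threshold used to fill `preferred_at_wtp`.
#' @return An object of class `slncea_icer` with fields `delta_cost`,
#'   `delta_qaly`, `icer` (NA unless a tradeoff), `classification`,
#'   `preferred_at_wtp`, plus the strategy labels and `wtp`.
#' @examples
#' a <- list(agent = "tilmanocept", expected_cost = 84961, expected_qaly = 7.06)
#' b <- list(agent = "sulfur_colloid", expected_cost = 84264, expected_qaly = 6.94)
#' icer(a, b)$icer  # 5808.33: quotient of the rounded published outcomes
#' @export
icer <- function(intervention, comparator, wtp = 1e5) {
  dc <- intervention$expected_cost - comparator$expected_cost
  dq <- intervention$expected_qaly - comparator$expected_qaly
  cls <- if (abs(dq) <= QALY_TOL && abs(dc) <= COST_TOL) {
    "equivalent"
  } else if (dc <= COST_TOL && dq >= -QALY_TOL) {
    "intervention_dominates"
  } else if (dc >= -COST_TOL && dq <= QALY_TOL) {
    "comparator_dominates"
  } else {
    "tradeoff"
  }
  out <- structure(list(
    intervention = intervention$agent %||% "intervention",
    comparator = comparator$agent %||% "comparator",
    delta_cost = dc, delta_qaly = dq,
    icer = if (cls == "tradeoff") dc / dq else NA_real_,
    classification = cls, wtp = wtp,
    preferred_at_wtp = NA_character_
  ), class = "slncea_icer")
  out$preferred_at_wtp <- decide(out, wtp)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Preferred strategy at a willingness-to-pay threshold
#'
#' Dominance forces the decision; in the trade-off quadrants the decision is
#' the ICER-threshold rule (intervention iff `icer <= wtp` when it buys
#' QALYs; intervention iff `icer >= wtp` when it saves money at a QALY
#' loss), which is equivalent to picking the larger
#' [net_monetary_benefit()] — the form actually used, since it is continuous
#' through the dominance quadrants.
#'
#' @param result An [icer()] result.
#' @param wtp Willingness-to-pay in dollars per QALY (>= 0).
#' @return The label of the preferred strategy.
#' @export
decide <- function(result, wtp) {
  stopifnot(wtp >= 0)
  # exact ties break on the label so the decision is antisymmetric
  tie <- min(result$intervention, result$comparator)
  switch(result$classification,
    intervention_dominates = result$intervention,
    comparator_dominates = result$comparator,
    equivalent = tie,
    tradeoff = {
      nmb_diff <- wtp * result$delta_qaly - result$delta_cost
      if (nmb_diff > 0) result$intervention
      else if (nmb_diff < 0) result$comparator
      else tie
    }
  )
}

#' Net monetary benefit of a strategy
#'
#' `NMB = wtp * QALYs - cost`. Maximizing NMB across strategies reproduces
#' the ICER-threshold decision in every quadrant of the
#' cost-effectiveness plane.
#'
#' @param outcome An [expected_strategy_outcome()] result.
#' @param wtp Willingness-to-pay in dollars per QALY (>= 0).
#' @return NMB in dollars.
#' @export
net_monetary_benefit <- function(outcome, wtp) {
  stopifnot(wtp >= 0)
  wtp * outcome$expected_qaly - outcome$expected_cost
}

#' One-row summary record of an incremental comparison
#'
#' @param result An [icer()] result.
#' @return A one-row tibble: strategies, deltas, icer, classification,
#'   preferred strategy and the threshold used.
#' @export
icer_record <- function(result) {
  tibble::tibble(
    intervention = result$intervention,
    comparator = result$comparator,
    delta_cost = result$delta_cost,
    delta_qaly = result$delta_qaly,
    icer = result$icer,
    classification = result$classification,
    wtp = result$wtp,
    preferred = result$preferred_at_wtp
  )
}

#' @export
print.slncea_icer <- function(x, ...) {
  cat(sprintf("%s vs %s: delta cost $%.2f, delta QALY %.4f\n",
              x$intervention, x$comparator, x$delta_cost, x$delta_qaly))
  if (x$classification == "tradeoff") {
    cat(sprintf("  ICER $%.0f per QALY (WTP $%s): prefer %s\n", x$icer,
                format(x$wtp, big.mark = ",", scientific = FALSE),
                x$preferred_at_wtp))
  } else {
    cat(sprintf("  %s: prefer %s\n", x$classification, x$preferred_at_wtp))
  }
  invisible(x)
}

# NMB difference tilmanocept minus sulfur colloid for a configuration --
# the continuous decision function used by sweeps and threshold search
strategy_nmb_diff <- function(cfg, wtp = cfg$wtp_threshold) {
  til <- expected_strategy_outcome("tilmanocept", cfg)
  sul <- expected_strategy_outcome("sulfur_colloid", cfg)
  net_monetary_benefit(til, wtp) - net_monetary_benefit(sul, wtp)
}

#' Evaluate both strategies and their incremental comparison
#'
#' @param cfg An `slncea_config`.
#' @param wtp Willingness-to-pay; defaults to the configuration's threshold.
#' @return List with `tilmanocept`, `sulfur_colloid` (strategy outcomes) and
#'   `icer` (the [icer()] result of tilmanocept vs sulfur colloid).
#' @export
evaluate_strategies <- function(cfg, wtp = cfg$wtp_threshold) {
  til <- expected_strategy_outcome("tilmanocept", cfg)
  sul <- expected_strategy_outcome("sulfur_colloid", cfg)
  list(tilmanocept = til, sulfur_colloid = sul,
       icer = icer(til, sul, wtp = wtp))
}
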