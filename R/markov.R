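#' Build the 5x5 annual transition matrix
#'
#' Embeds the chosen NED row (`"standard"` for true-positive, false-positive
#' and true-negative patients; `"fn"` for false negatives, who face worse
#' progression while disease-free), the single set of recurrence-state rows,
#' and the absorbing death state. Every row is divided by its sum, which
#' absorbs the 1.001 rounding of the printed standard NED row. Structural
#' zeros everywhere else: there is no re-entry into `NED` and recurrence
#' states do not revert.
#'
#' @param column `"standard"` or `"fn"`.
#' @param transitions A [disease_transitions()] object.
#' @return A 5x5 row-stochastic matrix with dimnames [markov_states()].
#' @export
transition_matrix <- function(column = c("standard", "fn"), transitions) {
  column <- match.arg(column)
  st <- markov_states()
  P <- matrix(0, 5, 5, dimnames = list(st, st))
  dest <- function(row) sub("^.*->", "", names(row))
  ned <- if (column == "fn") transitions$ned_row_fn else
    transitions$ned_row_standard
  P["NED", dest(ned)] <- ned
  P["LR", dest(transitions$lr_row)] <- transitions$lr_row
  P["NR", dest(transitions$nr_row)] <- transitions$nr_row
  P["DM", dest(transitions$dm_row)] <- transitions$dm_row
  P["Dead", "Dead"] <- 1
  sweep(P, 1, rowSums(P), "/")
}

#' Per-state reward structure of the cohort model
#'
#' Annual (state-membership) and one-time (state-entry) costs and utilities
#' for each health state, assembled from a configuration:
#' * `NED` accrues the disease-free annual surveillance cost and the
#'   post-resection utility.
#' * `LR`, `NR` and `DM` accrue the other-remission annual cost and the
#'   post-resection utility composed with the recurrent/metastatic
#'   disutility (clamped to \[0, 1\]).
#' * Entry into `LR` or `NR` charges salvage neck dissection plus adjuvant
#'   therapy and the one-time salvage disutility; entry into `DM` charges
#'   palliative chemotherapy (unless the variant charges it annually); entry
#'   into `Dead` charges end-of-life care.
#' * `Dead` has zero annual cost and utility.
#' Entry rewards are charged on probability flow into the state and never on
#' self-transitions, so salvage surgery is not re-charged for every year
#' spent in a recurrence state.
#'
#' @param cfg An `slncea_config`.
#' @return An object of class `slncea_rewards`: list of four named length-5
#'   vectors `annual_cost`, `annual_utility`, `entry_cost`,
#'   `entry_disutility`.
#' @export
build_reward_spec <- function(cfg) {
  st <- markov_states()
  v <- cfg$structural_variant
  co <- cfg$costs
  ut <- cfg$utilities
  adjuvant <- switch(v$recurrence_adjuvant,
    rt = co$radiation_therapy,
    mix = cfg$p_rt_given_positive * co$radiation_therapy +
      cfg$p_chemo_given_positive * co$chemo_with_rt
  )
  clamp01 <- function(x) pmin(1, pmax(0, x))
  u_rec <- clamp01(ut$utility_post_resection + ut$disutility_recurrent_metastatic)
  annual_cost <- c(NED = co$annual_cost_ned,
                   LR = co$annual_cost_other_remission,
                   NR = co$annual_cost_other_remission,
                   DM = co$annual_cost_other_remission +
                     if (v$dm_cost == "annual") co$chemo_metastatic else 0,
                   Dead = 0)
  entry_cost <- c(NED = 0,
                  LR = co$salvage_neck_dissection + adjuvant,
                  NR = co$salvage_neck_dissection + adjuvant,
                  DM = if (v$dm_cost == "entry") co$chemo_metastatic else 0,
                  Dead = co$eol_care)
  annual_utility <- c(NED = clamp01(ut$utility_post_resection),
                      LR = u_rec, NR = u_rec, DM = u_rec, Dead = 0)
  entry_disutility <- c(NED = 0, LR = ut$disutility_salvage,
                        NR = ut$disutility_salvage, DM = 0, Dead = 0)
  structure(list(annual_cost = annual_cost[st],
                 annual_utility = annual_utility[st],
                 entry_cost = entry_cost[st],
                 entry_disutility = entry_disutility[st]),
            class = "slncea_rewards")
}

discount_factors <- function(horizon, rate, discount_timing) {
  t <- seq_len(horizon)
  if (discount_timing == "delayed") (1 + rate)^-(t - 1) else (1 + rate)^-t
}

#' Iterate the cohort over the model horizon
#'
#' Deterministic cohort iteration: `occ[0]` puts unit mass on `start_state`
#' and `occ[t] = occ[t-1] %*% P`. Cycle `t` (for `t = 1..horizon`) accrues
#' * annual rewards on the occupancy chosen by the variant's
#'   `reward_timing` (end- or start-of-cycle, or their mean under the
#'   half-cycle correction), and
#' * entry rewards on the off-diagonal probability flow
#'   `occ[t-1, s] * P[s, s']` into each entry-rewarded state,
#' both multiplied by that cycle's discount factor. A cohort that starts in
#' an entry-rewarded state is not charged its entry reward.
#'
#' @param start_state State name, default `"NED"`.
#' @param column NED transition column, `"standard"` or `"fn"`.
#' @param rewards A [build_reward_spec()] object.
#' @param transitions A [disease_transitions()] object.
#' @param horizon Number of one-year cycles (>= 1).
#' @param rate Annual discount rate.
#' @param variant A [structural_variant()]; only `reward_timing`,
#'   `discount_timing` and `half_cycle` are used here (the cost axes act
#'   through `rewards`).
#' @return An object of class `slncea_trace`: list with `occupancy`
#'   (`(horizon+1) x 5` matrix, rows cycle 0..horizon), `cycle_costs`,
#'   `cycle_qalys` (discounted, length `horizon`), `total_cost`,
#'   `total_qaly`.
#' @examples
#' cfg <- base_case_config()
#' tr <- run_cohort("NED", "standard", build_reward_spec(cfg),
#'                  cfg$transitions, 30, 0.03, cfg$structural_variant)
#' tr$total_qaly
#' @export
run_cohort <- function(start_state = "NED", column = c("standard", "fn"),
                       rewards, transitions, horizon, rate,
                       variant = structural_variant()) {
  column <- match.arg(column)
  st <- markov_states()
  stopifnot(start_state %in% st)
  if (horizon < 1) stop("horizon must be >= 1 cycle, got ", horizon)
  P <- transition_matrix(column, transitions)
  if (max(abs(rowSums(P) - 1)) > 1e-9) stop("unnormalized transition rows")
  h <- as.integer(horizon)
  occ <- matrix(0, h + 1, 5, dimnames = list(0:h, st))
  occ[1, start_state] <- 1
  disc <- discount_factors(h, rate, variant$discount_timing)
  cycle_costs <- cycle_qalys <- numeric(h)
  for (t in seq_len(h)) {
    prev <- occ[t, ]
    flow <- prev * P  # flow[s, s'] = occ[t-1, s] * P[s, s']
    cur <- colSums(flow)
    occ[t + 1, ] <- cur
    off <- flow
    diag(off) <- 0
    entries <- colSums(off)
    basis <- if (variant$half_cycle) {
      (prev + cur) / 2
    } else if (variant$reward_timing == "start") {
      prev
    } else {
      cur
    }
    cycle_costs[t] <- disc[t] * (sum(basis * rewards$annual_cost) +
                                   sum(entries * rewards$entry_cost))
    cycle_qalys[t] <- disc[t] * (sum(basis * rewards$annual_utility) +
                                   sum(entries * rewards$entry_disutility))
  }
  structure(list(occupancy = occ, cycle_costs = cycle_costs,
                 cycle_qalys = cycle_qalys, total_cost = sum(cycle_costs),
                 total_qaly = sum(cycle_qalys)),
            class = "slncea_trace")
}

#' Tidy export of a cohort trace
#'
#' @param trace An `slncea_trace`.
#' @return A tibble in long format: `cycle`, `state`, `occupancy`, plus the
#'   per-cycle discounted `cost` and `qaly` (repeated across states of a
#'   cycle; zero at cycle 0, where nothing accrues).
#' @export
trace_to_tidy <- function(trace) {
  occ <- trace$occupancy
  h <- nrow(occ) - 1
  cyc <- as.integer(rownames(occ))
  tibble::tibble(
    cycle = rep(cyc, times = ncol(occ)),
    state = rep(colnames(occ), each = nrow(occ)),
    occupancy = as.vector(occ),
    cost = rep(c(0, trace$cycle_costs), times = ncol(occ)),
    qaly = rep(c(0, trace$cycle_qalys), times = ncol(occ))
  )
}

#' Write a cohort trace as CSV
#'
#' @param trace An `slncea_trace`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_trace_csv <- function(trace, file) {
  utils::write.csv(trace_to_tidy(trace), file, row.names = FALSE)
  invisible(file)
}

#' @export
print.slncea_trace <- function(x, ...) {
  h <- nrow(x$occupancy) - 1
  cat(sprintf(
    "cohort trace: %d cycles; total discounted cost $%.0f, %.4f QALYs\n",
    h, x$total_cost, x$total_qaly))
  cat(sprintf("  final occupancy: %s\n",
              paste(sprintf("%s %.3f", colnames(x$occupancy),
                            x$occupancy[h + 1, ]), collapse = ", ")))
  invisible(x)
}
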