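#' Individual-level Monte-Carlo simulation of one strategy
#'
#' Simulates `n` patients through the identical model as the cohort engine:
#' each patient draws a diagnostic branch, accrues the branch's upfront
#' rewards, then walks the Markov chain cycle by cycle, accruing discounted
#' annual and entry rewards under the same structural-variant conventions
#' as [run_cohort()]. The sample means are an unbiased stochastic estimate
#' of [expected_strategy_outcome()], which makes the simulator an
#' independent oracle for the deterministic engine.
#'
#' Randomness is a single uniform stream laid out patient-by-patient
#' (`horizon + 1` draws per patient), so growing `n` with the same seed
#' extends the sample without reshuffling earlier patients.
#'
#' @param agent `"tilmanocept"` or `"sulfur_colloid"`.
#' @param cfg An `slncea_config`.
#' @param n Number of simulated patients (>= 1).
#' @param seed Integer seed; identical seeds reproduce identical results.
#' @return An object of class `slncea_simresult`: `n`, `mean_cost`,
#'   `mean_qaly`, `se_cost`, `se_qaly`, `seed`.
#' @export
simulate_patients <- function(agent, cfg, n, seed) {
  stopifnot(n >= 1)
  h <- cfg$horizon_years
  v <- cfg$structural_variant
  rewards <- build_reward_spec(cfg)
  p <- branch_probabilities(cfg$prevalence, agent_diag(agent, cfg))
  up <- lapply(diagnostic_branches(), branch_upfront_outcome, agent = agent,
               cfg = cfg)
  up_cost <- vapply(up, `[[`, numeric(1), "upfront_cost")
  up_qaly <- vapply(up, `[[`, numeric(1), "upfront_qaly")

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  U <- matrix(stats::runif(as.numeric(n) * (h + 1)), nrow = h + 1)

  cum_branch <- cumsum(unclass(p))
  branch <- findInterval(U[1, ], c(0, cum_branch[-4]))  # 1 TP, 2 FN, 3 FP, 4 TN
  positive <- branch %in% c(1, 3)

  cumP_std <- t(apply(transition_matrix("standard", cfg$transitions), 1, cumsum))
  cumP_fn <- t(apply(transition_matrix("fn", cfg$transitions), 1, cumsum))

  ann_cost <- rewards$annual_cost
  ann_util <- rewards$annual_utility
  u_ned_pos <- ann_util[["NED"]]
  if (v$upfront_disutility == "persistent") {
    u_ned_pos <- min(1, max(0, u_ned_pos - positive_pathway(cfg)$disutility))
  }
  util_of <- function(state) {
    u <- ann_util[state]
    u[state == 1 & positive] <- u_ned_pos
    u
  }
  disc <- discount_factors(h, cfg$discount_rate, v$discount_timing)

  cost <- up_cost[branch]
  qaly <- up_qaly[branch]
  state <- rep.int(1L, n)  # everyone enters the Markov model in NED
  fn <- branch == 2
  for (t in seq_len(h)) {
    u <- U[t + 1, ]
    nxt <- integer(n)
    for (s in 1:4) {
      idx <- state == s
      if (!any(idx)) next
      if (s == 1) {
        i1 <- idx & fn
        if (any(i1)) nxt[i1] <- 1L + findInterval(u[i1], cumP_fn[1, -5])
        i2 <- idx & !fn
        if (any(i2)) nxt[i2] <- 1L + findInterval(u[i2], cumP_std[1, -5])
      } else {
        # full cumulative row; ties at zero-probability states resolve to
        # the next reachable state because findInterval counts all <= u
        nxt[idx] <- 1L + findInterval(u[idx], cumP_std[s, -5])
      }
    }
    nxt[state == 5L] <- 5L
    moved <- nxt != state
    a_cost <- if (v$half_cycle) {
      (ann_cost[state] + ann_cost[nxt]) / 2
    } else if (v$reward_timing == "start") ann_cost[state] else ann_cost[nxt]
    a_util <- if (v$half_cycle) {
      (util_of(state) + util_of(nxt)) / 2
    } else if (v$reward_timing == "start") util_of(state) else util_of(nxt)
    cost <- cost + disc[t] * (a_cost + ifelse(moved, rewards$entry_cost[nxt], 0))
    qaly <- qaly + disc[t] * (a_util + ifelse(moved, rewards$entry_disutility[nxt], 0))
    state <- nxt
  }
  structure(list(
    agent = agent, n = n,
    mean_cost = mean(cost), mean_qaly = mean(qaly),
    se_cost = stats::sd(cost) / sqrt(n), se_qaly = stats::sd(qaly) / sqrt(n),
    seed = seed
  ), class = "slncea_simresult")
}

#' @export
print.slncea_simresult <- function(x, ...) {
  cat(sprintf(
    "microsim (%s, n = %d, seed %d): cost $%.0f (se %.1f), QALY %.4f (se %.5f)\n",
    x$agent, x$n, x$seed, x$mean_cost, x$se_cost, x$mean_qaly, x$se_qaly))
  invisible(x)
}
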