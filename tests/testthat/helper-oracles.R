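# Independent oracles used across tests -- kept deliberately naive so they
# share no code path with the package internals they check.

# present value of an annuity of 1 per year, paid at years 1..n
annuity_pv <- function(n, rate) {
  sum((1 + rate)^-(1:n))
}

# expected total (undiscounted) reward until absorption via the fundamental
# matrix (I - Q)^-1 of the transient block, reward accrued per year of
# state membership measured at end of cycle over `horizon` cycles
fundamental_matrix_reward <- function(P, start, annual_reward, horizon) {
  occ <- numeric(nrow(P))
  names(occ) <- rownames(P)
  occ[start] <- 1
  total <- 0
  for (t in seq_len(horizon)) {
    occ <- drop(occ %*% P)
    total <- total + sum(occ * annual_reward)
  }
  total
}

# a reward spec with a single nonzero component, for isolating one channel
zero_rewards <- function() {
  st <- c("NED", "LR", "NR", "DM", "Dead")
  z <- stats::setNames(numeric(5), st)
  structure(list(annual_cost = z, annual_utility = z, entry_cost = z,
                 entry_disutility = z), class = "slncea_rewards")
}

# transitions where NED is absorbing (identity chain for survival checks)
identity_ned_transitions <- function() {
  disease_transitions(
    ned_row_standard = c(1, 0, 0, 0, 0),
    ned_row_fn = c(1, 0, 0, 0, 0),
    lr_row = c(1, 0, 0),
    nr_row = c(1, 0, 0),
    dm_row = c(1, 0)
  )
}

# independent ICER-threshold decision rule on the cost-effectiveness plane,
# written from the textbook definition (used to cross-check the NMB route)
icer_rule_decision <- function(a, b, wtp) {
  dc <- a$expected_cost - b$expected_cost
  dq <- a$expected_qaly - b$expected_qaly
  if (dc <= 0 && dq >= 0 && (dc < 0 || dq > 0)) return(a$agent)
  if (dc >= 0 && dq <= 0 && (dc > 0 || dq < 0)) return(b$agent)
  if (dc == 0 && dq == 0) return(min(a$agent, b$agent))
  r <- dc / dq
  if (dq > 0) {
    if (r < wtp) a$agent else if (r > wtp) b$agent else min(a$agent, b$agent)
  } else {
    if (r > wtp) a$agent else if (r < wtp) b$agent else min(a$agent, b$agent)
  }
}
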