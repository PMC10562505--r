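#' Health states of the natural-history model
#'
#' The cohort model tracks five mutually exclusive health states: no evidence
#' of disease (`NED`), local recurrence (`LR`), nodal recurrence (`NR`),
#' distant metastasis (`DM`) and `Dead`. `Dead` is absorbing; there are no
#' re-entry edges into `NED`.
#'
#' @return Character vector of state names, in model order.
#' @export
markov_states <- function() {
  c("NED", "LR", "NR", "DM", "Dead")
}

#' Diagnostic branches of the decision tree
#'
#' @return Character vector `c("TP", "FN", "FP", "TN")`.
#' @export
diagnostic_branches <- function() {
  c("TP", "FN", "FP", "TN")
}

#' Tracer agent strategy labels
#'
#' @return Character vector `c("tilmanocept", "sulfur_colloid")`.
#' @export
agent_labels <- function() {
  c("tilmanocept", "sulfur_colloid")
}

# row-sum tolerance below which a transition row is "normalizable" rather
# than invalid (Table rounding leaves the standard NED row at 1.001)
ROW_SUM_TOL <- 2e-3
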