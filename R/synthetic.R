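#' Generate a structurally valid random parameter set
#'
#' Draws a complete configuration that respects every container invariant:
#' probabilities in \[0, 1\], Dirichlet-style row-stochastic transition rows
#' (positives sampled and normalized, so stochasticity holds by
#' construction), non-negative costs, a base utility in \[0, 1\] and
#' non-positive disutilities. The false-negative NED row is built
#' stochastically worse than the standard row — more mass on nodal
#' recurrence and death, less on remaining disease-free — preserving the
#' qualitative structure of the published model. Intended as the fuzzing
#' surface for property tests; not an estimate of anything.
#'
#' @param seed Integer seed; equal seeds give identical configurations.
#' @param structural_variant Variant attached to the configuration.
#' @return An `slncea_config` with no `"invalid"` validation findings.
#' @export
random_config <- function(seed, structural_variant = calibrated_variant()) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  dirichlet <- function(alpha) {
    g <- stats::rgamma(length(alpha), shape = alpha)
    g / sum(g)
  }
  # standard NED row: mostly disease-free, modest exits
  std <- dirichlet(c(30, 1.2, 1.3, 0.3, 2.2))
  # FN row: inflate nodal recurrence and death, shrink the others, renormalize
  fn_raw <- std * c(1, stats::runif(1, 0.2, 0.8), stats::runif(1, 2.5, 5),
                    stats::runif(1, 0.3, 0.9), stats::runif(1, 1.5, 2.5))
  fn_raw[1] <- std[1]  # placeholder; NED mass absorbs the remainder
  fn <- fn_raw
  fn[1] <- max(0.05, 1 - sum(fn_raw[-1]))
  fn <- fn / sum(fn)
  if (fn[3] <= std[3] || fn[5] <= std[5]) {
    # enforce the orderings the construction targets
    fn[3] <- std[3] * 2.5
    fn[5] <- std[5] * 1.5
    fn[1] <- max(0.05, 1 - sum(fn[-1]))
    fn <- fn / sum(fn)
  }
  rcost <- function(lo, hi) stats::runif(1, lo, hi)
  base_util <- stats::runif(1, 0.6, 1)
  cfg <- model_config(
    diag_tilmanocept = diagnostic_performance(stats::runif(1, 0.6, 1),
                                              stats::runif(1, 0.6, 1)),
    diag_sulfur = diagnostic_performance(stats::runif(1, 0.4, 1),
                                         stats::runif(1, 0.6, 1)),
    prevalence = stats::runif(1, 0.1, 0.5),
    transitions = disease_transitions(
      ned_row_standard = std,
      ned_row_fn = fn,
      lr_row = dirichlet(c(6, 3, 1.5)),
      nr_row = dirichlet(c(6, 3, 1.5)),
      dm_row = dirichlet(c(8, 2))
    ),
    costs = cost_inputs(
      agent_cost_tilmanocept = rcost(200, 2000),
      agent_cost_sulfur_colloid = rcost(10, 400),
      primary_resection = rcost(10000, 50000),
      concurrent_neck_dissection = rcost(1000, 10000),
      salvage_neck_dissection = rcost(15000, 40000),
      radiation_therapy = rcost(10000, 40000),
      chemo_with_rt = rcost(3000, 15000),
      chemo_metastatic = rcost(15000, 60000),
      annual_cost_ned = rcost(500, 3000),
      annual_cost_other_remission = rcost(300, 2000),
      eol_care = rcost(5000, 20000)
    ),
    utilities = utility_inputs(
      utility_post_resection = base_util,
      disutility_neck_dissection = -stats::runif(1, 0.01, 0.15),
      disutility_salvage = -stats::runif(1, 0.01, 0.3),
      disutility_rt = -stats::runif(1, 0.01, 0.15),
      disutility_chemo_rt = -stats::runif(1, 0.01, 0.3),
      disutility_recurrent_metastatic = -stats::runif(1, 0.05, 0.5)
    ),
    p_rt_given_positive = stats::runif(1),
    p_chemo_given_positive = stats::runif(1),
    discount_rate = stats::runif(1, 0, 0.06),
    horizon_years = sample(10:40, 1),
    cycle_length_years = 1,
    wtp_threshold = stats::runif(1, 5e4, 1.5e5),
    structural_variant = structural_variant
  )
  cfg
}

#' Jitter a configuration multiplicatively
#'
#' Each numeric parameter is multiplied by an independent factor drawn
#' uniformly from `1 +/- relative_scale`; probabilities are clamped back to
#' \[0, 1\] and every transition row renormalized, so the result is always a
#' valid configuration. Used for robustness sweeps around a base case.
#'
#' @param cfg An `slncea_config`.
#' @param relative_scale Fraction in (0, 0.5].
#' @param seed Integer seed.
#' @return A new `slncea_config`; the input is unchanged.
#' @export
perturb <- function(cfg, relative_scale, seed) {
  stopifnot(relative_scale > 0, relative_scale <= 0.5)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  jit <- function(x) x * stats::runif(length(x), 1 - relative_scale,
                                      1 + relative_scale)
  # x first in pmax/pmin so names survive (pmax takes the first argument's
  # attributes; transition-row names are load-bearing downstream)
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  for (d in c("diag_tilmanocept", "diag_sulfur")) {
    cfg[[d]]$sensitivity <- clamp01(jit(cfg[[d]]$sensitivity))
    cfg[[d]]$specificity <- clamp01(jit(cfg[[d]]$specificity))
  }
  cfg$prevalence <- clamp01(jit(cfg$prevalence))
  for (row_name in names(cfg$transitions)) {
    row <- clamp01(jit(cfg$transitions[[row_name]]))
    cfg$transitions[[row_name]] <- row / sum(row)
  }
  for (nm in names(cfg$costs)) cfg$costs[[nm]] <- jit(cfg$costs[[nm]])
  cfg$utilities$utility_post_resection <-
    clamp01(jit(cfg$utilities$utility_post_resection))
  for (nm in setdiff(names(cfg$utilities), "utility_post_resection")) {
    cfg$utilities[[nm]] <- -abs(jit(cfg$utilities[[nm]]))
  }
  cfg$p_rt_given_positive <- clamp01(jit(cfg$p_rt_given_positive))
  cfg$p_chemo_given_positive <- clamp01(jit(cfg$p_chemo_given_positive))
  cfg$discount_rate <- abs(jit(cfg$discount_rate))
  cfg
}
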