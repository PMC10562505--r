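#' Diagnostic performance of a tracer agent
#'
#' @param sensitivity Probability that a patient with occult nodal metastasis
#'   has a positive sentinel lymph node biopsy.
#' @param specificity Probability that a patient without occult metastasis
#'   has a negative biopsy.
#' @return An object of class `slncea_diag`.
#' @export
diagnostic_performance <- function(sensitivity, specificity) {
  structure(list(sensitivity = sensitivity, specificity = specificity),
            class = "slncea_diag")
}

#' Annual disease-progression transition rows
#'
#' Rows are stored as printed (pre-normalization); [transition_matrix()]
#' divides each row by its sum when the chain is built. Entries are named by
#' full transition label (`"NED->LR"` etc.), which is also how they are
#' addressed by [set_parameter()] paths such as
#' `"transitions.lr_row.LR->DM"`.
#'
#' @param ned_row_standard Length-5 row `NED -> {NED, LR, NR, DM, Dead}` for
#'   patients with a true-positive, false-positive or true-negative biopsy.
#' @param ned_row_fn Length-5 row for false-negative patients, who face a
#'   roughly fourfold `NED->NR` probability and about twice the `NED->Dead`
#'   probability while disease-free.
#' @param lr_row Length-3 row `LR -> {LR, DM, Dead}`.
#' @param nr_row Length-3 row `NR -> {NR, DM, Dead}`.
#' @param dm_row Length-2 row `DM -> {DM, Dead}`.
#' @return An object of class `slncea_transitions`.
#' @export
disease_transitions <- function(ned_row_standard, ned_row_fn, lr_row, nr_row,
                                dm_row) {
  lab <- function(from, to) paste0(from, "->", to)
  x <- list(
    ned_row_standard = stats::setNames(as.numeric(ned_row_standard),
                                       lab("NED", markov_states())),
    ned_row_fn = stats::setNames(as.numeric(ned_row_fn),
                                 lab("NED", markov_states())),
    lr_row = stats::setNames(as.numeric(lr_row), lab("LR", c("LR", "DM", "Dead"))),
    nr_row = stats::setNames(as.numeric(nr_row), lab("NR", c("NR", "DM", "Dead"))),
    dm_row = stats::setNames(as.numeric(dm_row), lab("DM", c("DM", "Dead")))
  )
  structure(x, class = "slncea_transitions")
}

#' Cost inputs (2020 US dollars)
#'
#' One-time procedure costs, annual state costs (`annual_cost_*`) and the
#' end-of-life care cost charged once on the transition into `Dead`.
#'
#' @param agent_cost_tilmanocept,agent_cost_sulfur_colloid Hospital
#'   acquisition cost of the radiotracer dose.
#' @param primary_resection Resection of the primary oral tumor, performed at
#'   the time of the biopsy for every patient.
#' @param concurrent_neck_dissection Completion neck dissection performed when
#'   the biopsy is positive.
#' @param salvage_neck_dissection Stand-alone salvage neck dissection at
#'   recurrence.
#' @param radiation_therapy,chemo_with_rt,chemo_metastatic Adjuvant radiation,
#'   cisplatin chemoradiation, and palliative chemotherapy for metastatic
#'   disease.
#' @param annual_cost_ned,annual_cost_other_remission Annual surveillance
#'   costs while in `NED` and while in the other alive states.
#' @param eol_care End-of-life care, charged once at death.
#' @return An object of class `slncea_costs`.
#' @export
cost_inputs <- function(agent_cost_tilmanocept, agent_cost_sulfur_colloid,
                        primary_resection, concurrent_neck_dissection,
                        salvage_neck_dissection, radiation_therapy,
                        chemo_with_rt, chemo_metastatic, annual_cost_ned,
                        annual_cost_other_remission, eol_care) {
  structure(list(
    agent_cost_tilmanocept = agent_cost_tilmanocept,
    agent_cost_sulfur_colloid = agent_cost_sulfur_colloid,
    primary_resection = primary_resection,
    concurrent_neck_dissection = concurrent_neck_dissection,
    salvage_neck_dissection = salvage_neck_dissection,
    radiation_therapy = radiation_therapy,
    chemo_with_rt = chemo_with_rt,
    chemo_metastatic = chemo_metastatic,
    annual_cost_ned = annual_cost_ned,
    annual_cost_other_remission = annual_cost_other_remission,
    eol_care = eol_care
  ), class = "slncea_costs")
}

#' Utility inputs
#'
#' `utility_post_resection` is the annual utility of the disease-free state
#' after resection of the primary tumor; the `disutility_*` values are
#' non-positive decrements, applied either once (procedure tolls) or annually
#' (`disutility_recurrent_metastatic`, which composes with the base utility
#' for the recurrent states). Composed annual utilities are clamped to
#' \[0, 1\].
#'
#' @param utility_post_resection Annual utility of `NED` after resection.
#' @param disutility_neck_dissection One-time toll for completion neck
#'   dissection.
#' @param disutility_salvage One-time toll for salvage treatment, applied on
#'   entry into `LR` or `NR`.
#' @param disutility_rt,disutility_chemo_rt One-time tolls for adjuvant
#'   radiation and chemoradiation.
#' @param disutility_recurrent_metastatic Annual decrement while in `LR`,
#'   `NR` or `DM`.
#' @return An object of class `slncea_utilities`.
#' @export
utility_inputs <- function(utility_post_resection, disutility_neck_dissection,
                           disutility_salvage, disutility_rt,
                           disutility_chemo_rt,
                           disutility_recurrent_metastatic) {
  structure(list(
    utility_post_resection = utility_post_resection,
    disutility_neck_dissection = disutility_neck_dissection,
    disutility_salvage = disutility_salvage,
    disutility_rt = disutility_rt,
    disutility_chemo_rt = disutility_chemo_rt,
    disutility_recurrent_metastatic = disutility_recurrent_metastatic
  ), class = "slncea_utilities")
}

#' Assemble a complete model configuration
#'
#' @param diag_tilmanocept,diag_sulfur [diagnostic_performance()] objects.
#' @param prevalence Prevalence of occult nodal metastasis in the cN0 neck.
#' @param transitions A [disease_transitions()] object.
#' @param costs A [cost_inputs()] object.
#' @param utilities A [utility_inputs()] object.
#' @param p_rt_given_positive,p_chemo_given_positive Fractions of
#'   test-positive patients receiving adjuvant radiation and chemoradiation.
#' @param discount_rate Annual discount rate applied to costs and QALYs.
#' @param horizon_years Number of one-year Markov cycles.
#' @param cycle_length_years Cycle length; the model is annual.
#' @param wtp_threshold Willingness-to-pay threshold in dollars per QALY.
#' @param structural_variant A [structural_variant()] describing modeling
#'   conventions the source tables leave open; defaults to the calibrated
#'   convention, see [calibrated_variant()].
#' @return An object of class `slncea_config`.
#' @export
model_config <- function(diag_tilmanocept, diag_sulfur, prevalence,
                         transitions, costs, utilities,
                         p_rt_given_positive, p_chemo_given_positive,
                         discount_rate = 0.03, horizon_years = 30L,
                         cycle_length_years = 1, wtp_threshold = 1e5,
                         structural_variant = calibrated_variant()) {
  structure(list(
    diag_tilmanocept = diag_tilmanocept,
    diag_sulfur = diag_sulfur,
    prevalence = prevalence,
    transitions = transitions,
    costs = costs,
    utilities = utilities,
    p_rt_given_positive = p_rt_given_positive,
    p_chemo_given_positive = p_chemo_given_positive,
    discount_rate = discount_rate,
    horizon_years = as.integer(horizon_years),
    cycle_length_years = cycle_length_years,
    wtp_threshold = wtp_threshold,
    structural_variant = structural_variant
  ), class = "slncea_config")
}

#' Published base-case parameter set
#'
#' Returns the base-case configuration exactly as printed in the source
#' tables: diagnostic performance and prevalence, annual disease-progression
#' rows (the standard NED row sums to 1.001 because of rounding and is
#' normalized only when the transition matrix is built), 2020-USD costs,
#' utilities, the 49%/15% adjuvant-treatment fractions among test-positives,
#' a 3% annual discount rate, a 30-year horizon and a $100,000/QALY
#' willingness-to-pay threshold.
#'
#' @param structural_variant Modeling conventions; defaults to the calibrated
#'   variant.
#' @return An `slncea_config`.
#' @examples
#' cfg <- base_case_config()
#' cfg$diag_tilmanocept$sensitivity  # 0.979
#' @export
base_case_config <- function(structural_variant = calibrated_variant()) {
  model_config(
    diag_tilmanocept = diagnostic_performance(0.979, 0.990),
    diag_sulfur = diagnostic_performance(0.727, 0.990),
    prevalence = 0.280,
    transitions = disease_transitions(
      ned_row_standard = c(0.869, 0.032, 0.035, 0.004, 0.061),
      ned_row_fn = c(0.749, 0.007, 0.137, 0.003, 0.104),
      lr_row = c(0.614, 0.286, 0.100),
      nr_row = c(0.589, 0.286, 0.125),
      dm_row = c(0.837, 0.163)
    ),
    costs = cost_inputs(
      agent_cost_tilmanocept = 628,
      agent_cost_sulfur_colloid = 105,
      primary_resection = 28512,
      concurrent_neck_dissection = 3946,
      salvage_neck_dissection = 29366,
      radiation_therapy = 24693,
      chemo_with_rt = 7684,
      chemo_metastatic = 36619,
      annual_cost_ned = 1579,
      annual_cost_other_remission = 1071,
      eol_care = 11101
    ),
    utilities = utility_inputs(
      utility_post_resection = 0.913,
      disutility_neck_dissection = -0.072,
      disutility_salvage = -0.238,
      disutility_rt = -0.060,
      disutility_chemo_rt = -0.090,
      disutility_recurrent_metastatic = -0.343
    ),
    p_rt_given_positive = 0.49,
    p_chemo_given_positive = 0.15,
    discount_rate = 0.03,
    horizon_years = 30L,
    cycle_length_years = 1,
    wtp_threshold = 1e5,
    structural_variant = structural_variant
  )
}

#' Sensitivity-analysis ranges for every ranged parameter
#'
#' One entry per parameter carrying a plausible range in the source tables,
#' keyed by the same dot-separated path accepted by [set_parameter()]. The
#' NED transition ranges are shared between the standard and false-negative
#' columns, so both paths appear. Ranges are stored orientation-normalized as
#' `c(low, high)` with `low <= high`; for the disutilities this means the
#' more negative bound comes first. Note that the salvage-treatment
#' disutility base value (-0.238) lies outside its printed range
#' (-0.093 to -0.034); [validate_config()] flags this as a note.
#'
#' @return Named list of numeric `c(low, high)` vectors.
#' @export
sensitivity_ranges <- function() {
  ned <- list(
    "NED->NED" = c(0.500, 0.990),
    "NED->LR" = c(0.001, 0.100),
    "NED->NR" = c(0.010, 0.250),
    "NED->DM" = c(0.001, 0.050),
    "NED->Dead" = c(0.010, 0.250)
  )
  r <- c(
    list(
      "diag_tilmanocept.specificity" = c(0.700, 1.000),
      "diag_sulfur.specificity" = c(0.700, 1.000),
      "diag_tilmanocept.sensitivity" = c(0.750, 1.000),
      "diag_sulfur.sensitivity" = c(0.500, 1.000),
      "prevalence" = c(0.200, 0.400)
    ),
    stats::setNames(ned, paste0("transitions.ned_row_standard.", names(ned))),
    stats::setNames(ned, paste0("transitions.ned_row_fn.", names(ned))),
    list(
      "transitions.lr_row.LR->LR" = c(0.500, 0.750),
      "transitions.lr_row.LR->DM" = c(0.100, 0.500),
      "transitions.lr_row.LR->Dead" = c(0.010, 0.250),
      "transitions.nr_row.NR->NR" = c(0.400, 0.750),
      "transitions.nr_row.NR->DM" = c(0.150, 0.500),
      "transitions.nr_row.NR->Dead" = c(0.050, 0.250),
      "transitions.dm_row.DM->DM" = c(0.750, 0.950),
      "transitions.dm_row.DM->Dead" = c(0.050, 0.250),
      "costs.agent_cost_tilmanocept" = c(400, 1500),
      "costs.agent_cost_sulfur_colloid" = c(10, 200),
      "costs.primary_resection" = c(18466, 40992),
      "costs.concurrent_neck_dissection" = c(1326, 7970),
      "costs.salvage_neck_dissection" = c(26078, 32973),
      "costs.radiation_therapy" = c(16099, 35708),
      "costs.chemo_with_rt" = c(4926, 11018),
      "costs.chemo_metastatic" = c(23478, 52476),
      "costs.annual_cost_ned" = c(1017, 2257),
      "costs.annual_cost_other_remission" = c(690, 1531),
      "costs.eol_care" = c(7154, 15852),
      "utilities.utility_post_resection" = c(0.301, 1),
      "utilities.disutility_neck_dissection" = c(-0.116, -0.038),
      "utilities.disutility_salvage" = c(-0.093, -0.034),
      "utilities.disutility_rt" = c(-0.133, -0.055),
      "utilities.disutility_chemo_rt" = c(-0.336, -0.149),
      "utilities.disutility_recurrent_metastatic" = c(-0.414, -0.273)
    )
  )
  lapply(r, function(v) sort(unname(v)))
}

# ---- path addressing --------------------------------------------------------

normalize_path <- function(path) {
  gsub("→", "->", path, fixed = TRUE)
}

#' Enumerate the numeric parameter paths of a configuration
#'
#' @param cfg An `slncea_config`.
#' @return Character vector of dot-separated paths addressing every numeric
#'   leaf (the structural variant is not numeric and is excluded).
#' @export
parameter_paths <- function(cfg) {
  leaf_paths <- function(x, prefix) {
    if (is.list(x)) {
      unlist(lapply(names(x), function(nm) {
        leaf_paths(x[[nm]], c(prefix, nm))
      }), use.names = FALSE)
    } else if (is.numeric(x) && !is.null(names(x))) {
      paste(c(paste(prefix, collapse = "."), names(x)), collapse = ".")
    } else if (is.numeric(x)) {
      paste(prefix, collapse = ".")
    } else {
      character(0)
    }
  }
  fields <- setdiff(names(cfg), "structural_variant")
  unlist(lapply(fields, function(nm) leaf_paths(cfg[[nm]], nm)),
         use.names = FALSE)
}

split_path <- function(cfg, path) {
  path <- normalize_path(path)
  segs <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- cfg
  walk <- list()
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    if (is.list(node) && s %in% names(node)) {
      walk[[i]] <- s
      node <- node[[s]]
    } else if (is.numeric(node) && s %in% names(node)) {
      if (i != length(segs)) stop("path continues past a leaf: ", path)
      walk[[i]] <- s
      node <- node[[s]]
    } else {
      valid <- parameter_paths(cfg)
      d <- utils::adist(path, valid, partial = FALSE)
      stop(sprintf("unknown parameter path '%s'; did you mean '%s'?",
                   path, valid[which.min(d)]), call. = FALSE)
    }
  }
  list(segments = segs, value = node)
}

#' Read a single parameter by path
#'
#' @param cfg An `slncea_config`.
#' @param path Dot-separated path, e.g. `"diag_sulfur.sensitivity"` or
#'   `"transitions.lr_row.LR->DM"` (a unicode arrow is also accepted).
#' @return The numeric value at `path`.
#' @export
get_parameter <- function(cfg, path) {
  unname(split_path(cfg, path)$value)
}

#' Replace a single parameter, renormalizing transition rows
#'
#' Returns a modified copy; the input configuration is never changed. When
#' `path` addresses a cell of a transition row, the remaining cells of that
#' row are rescaled proportionally so the row still sums to 1 — the
#' convention used by every sensitivity sweep in the package.
#'
#' @inheritParams get_parameter
#' @param value New numeric value.
#' @return A new `slncea_config`.
#' @export
set_parameter <- function(cfg, path, value) {
  sp <- split_path(cfg, path)
  segs <- sp$segments
  n <- length(segs)
  is_transition_cell <- n == 3 && segs[[1]] == "transitions"
  if (is_transition_cell) {
    row <- cfg$transitions[[segs[[2]]]]
    if (value < 0 || value > 1) {
      stop("transition probability must lie in [0, 1], got ", value)
    }
    others <- setdiff(names(row), segs[[3]])
    old_sum <- sum(row[others])
    row[segs[[3]]] <- value
    if (old_sum > 0) {
      row[others] <- row[others] * (1 - value) / old_sum
    } else {
      row[others] <- (1 - value) / length(others)
    }
    cfg$transitions[[segs[[2]]]] <- row
  } else if (n == 1) {
    cfg[[segs[[1]]]] <- value
  } else if (n == 2) {
    cfg[[segs[[1]]]][[segs[[2]]]] <- value
  } else {
    cfg[[segs[[1]]]][[segs[[2]]]][[segs[[3]]]] <- value
  }
  cfg
}

# ---- validation -------------------------------------------------------------

#' Validate a model configuration
#'
#' Collects every violated invariant into a report instead of throwing.
#' Severities: `"invalid"` (probability out of \[0,1\], negative cost,
#' positive disutility, row sum off by more than the normalization
#' tolerance, horizon below 1, negative discount rate), `"normalizable"`
#' (transition row sum within 2e-3 of 1, fixed automatically when the chain
#' is built) and `"note"` (informational, e.g. a base value outside its
#' printed sensitivity range).
#'
#' @param cfg An `slncea_config`.
#' @return A tibble of class `slncea_validation` with columns `path`,
#'   `severity`, `message`. Zero `"invalid"` rows means the configuration is
#'   usable; see [is_valid()].
#' @export
validate_config <- function(cfg) {
  rows <- list()
  add <- function(path, severity, message) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      path = path, severity = severity, message = message)
  }
  prob <- function(path) {
    v <- get_parameter(cfg, path)
    if (!is.finite(v) || v < 0 || v > 1) {
      add(path, "invalid", sprintf("probability out of range: %g", v))
    }
  }
  for (p in c("diag_tilmanocept.sensitivity", "diag_tilmanocept.specificity",
              "diag_sulfur.sensitivity", "diag_sulfur.specificity",
              "prevalence", "p_rt_given_positive", "p_chemo_given_positive")) {
    prob(p)
  }
  for (row_name in names(cfg$transitions)) {
    row <- cfg$transitions[[row_name]]
    if (is.null(names(row)) || !all(grepl("->", names(row), fixed = TRUE))) {
      add(paste0("transitions.", row_name), "invalid",
          "transition cells must be named 'from->to'")
      next
    }
    for (cell in names(row)) {
      v <- row[[cell]]
      if (!is.finite(v) || v < 0 || v > 1) {
        add(paste("transitions", row_name, cell, sep = "."), "invalid",
            sprintf("probability out of range: %g", v))
      }
    }
    s <- sum(row)
    if (abs(s - 1) > ROW_SUM_TOL) {
      add(paste0("transitions.", row_name), "invalid",
          sprintf("row sum %g", s))
    } else if (s != 1) {
      add(paste0("transitions.", row_name), "normalizable",
          sprintf("row sum %g; normalized at model build", s))
    }
  }
  for (nm in names(cfg$costs)) {
    v <- cfg$costs[[nm]]
    if (!is.finite(v) || v < 0) {
      add(paste0("costs.", nm), "invalid", sprintf("negative cost: %g", v))
    }
  }
  u <- cfg$utilities$utility_post_resection
  if (!is.finite(u) || u < 0 || u > 1) {
    add("utilities.utility_post_resection", "invalid",
        sprintf("utility out of range: %g", u))
  }
  for (nm in setdiff(names(cfg$utilities), "utility_post_resection")) {
    v <- cfg$utilities[[nm]]
    if (!is.finite(v) || v > 0) {
      add(paste0("utilities.", nm), "invalid",
          sprintf("disutility must be <= 0: %g", v))
    }
  }
  if (cfg$horizon_years < 1) {
    add("horizon_years", "invalid",
        sprintf("horizon must be >= 1 year: %d", cfg$horizon_years))
  }
  if (cfg$discount_rate < 0) {
    add("discount_rate", "invalid",
        sprintf("discount rate must be >= 0: %g", cfg$discount_rate))
  }
  rng <- sensitivity_ranges()
  for (p in names(rng)) {
    v <- tryCatch(get_parameter(cfg, p), error = function(e) NULL)
    if (!is.null(v) && is.finite(v) && (v < rng[[p]][1] || v > rng[[p]][2])) {
      add(p, "note", sprintf(
        "range excludes base case: value %g outside sensitivity range [%g, %g]",
        v, rng[[p]][1], rng[[p]][2]))
    }
  }
  out <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    tibble::tibble(path = character(), severity = character(),
                   message = character())
  }
  class(out) <- c("slncea_validation", class(out))
  out
}

#' Is a validation report (or configuration) free of invalid findings?
#'
#' @param x An `slncea_config` or the report returned by [validate_config()].
#' @return `TRUE` when no finding has severity `"invalid"`.
#' @export
is_valid <- function(x) {
  report <- if (inherits(x, "slncea_config")) validate_config(x) else x
  !any(report$severity == "invalid")
}

#' @export
print.slncea_validation <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("configuration valid: no findings\n")
  } else {
    cat(sprintf("%d finding(s): %d invalid, %d normalizable, %d note\n",
                nrow(x), sum(x$severity == "invalid"),
                sum(x$severity == "normalizable"),
                sum(x$severity == "note")))
    for (i in seq_len(nrow(x))) {
      cat(sprintf("  [%s] %s: %s\n", x$severity[i], x$path[i], x$message[i]))
    }
  }
  invisible(x)
}

# ---- serialization ----------------------------------------------------------

config_to_list <- function(cfg) {
  out <- lapply(cfg, function(x) {
    if (is.list(x)) {
      lapply(x, function(v) if (length(v) > 1) as.list(v) else unname(v))
    } else {
      x
    }
  })
  out$structural_variant <- unclass(cfg$structural_variant)
  out
}

#' Write a configuration to a YAML file
#'
#' The file mirrors the configuration field names exactly; a bundled copy of
#' the base case ships with the package
#' (`system.file("extdata", "base_case.yaml", package = "slncea")`).
#'
#' @param cfg An `slncea_config`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_config <- function(cfg, file) {
  yaml::write_yaml(config_to_list(cfg), file, precision = 22)
  invisible(file)
}

#' Read a configuration from a YAML file
#'
#' @param file Path to a file produced by [write_config()] (or written by
#'   hand with the same field names).
#' @return An `slncea_config`.
#' @export
read_config <- function(file) {
  if (!file.exists(file)) stop("config file not found: ", file)
  x <- yaml::read_yaml(file)
  row <- function(r) unlist(r)
  model_config(
    diag_tilmanocept = do.call(diagnostic_performance, x$diag_tilmanocept),
    diag_sulfur = do.call(diagnostic_performance, x$diag_sulfur),
    prevalence = x$prevalence,
    transitions = disease_transitions(
      ned_row_standard = row(x$transitions$ned_row_standard),
      ned_row_fn = row(x$transitions$ned_row_fn),
      lr_row = row(x$transitions$lr_row),
      nr_row = row(x$transitions$nr_row),
      dm_row = row(x$transitions$dm_row)
    ),
    costs = do.call(cost_inputs, x$costs),
    utilities = do.call(utility_inputs, x$utilities),
    p_rt_given_positive = x$p_rt_given_positive,
    p_chemo_given_positive = x$p_chemo_given_positive,
    discount_rate = x$discount_rate,
    horizon_years = x$horizon_years,
    cycle_length_years = x$cycle_length_years,
    wtp_threshold = x$wtp_threshold,
    structural_variant = do.call(structural_variant, x$structural_variant)
  )
}

#' @export
print.slncea_config <- function(x, ...) {
  cat("slncea model configuration\n")
  cat(sprintf("  tilmanocept: sens %.3f spec %.3f, agent cost $%s\n",
              x$diag_tilmanocept$sensitivity, x$diag_tilmanocept$specificity,
              format(x$costs$agent_cost_tilmanocept, big.mark = ",")))
  cat(sprintf("  sulfur colloid: sens %.3f spec %.3f, agent cost $%s\n",
              x$diag_sulfur$sensitivity, x$diag_sulfur$specificity,
              format(x$costs$agent_cost_sulfur_colloid, big.mark = ",")))
  cat(sprintf("  prevalence %.3f; horizon %d y; discount %.1f%%; WTP $%s/QALY\n",
              x$prevalence, x$horizon_years, 100 * x$discount_rate,
              format(x$wtp_threshold, big.mark = ",")))
  cat("  variant:", format(x$structural_variant), "\n")
  invisible(x)
}
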