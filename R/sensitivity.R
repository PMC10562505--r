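#' One-way deterministic sensitivity sweep
#'
#' Rebuilds both strategies at each grid value of a single parameter (all
#' other parameters at their configured values; swept transition cells are
#' proportionally renormalized by [set_parameter()]) and records the
#' incremental comparison and the preferred strategy at the configuration's
#' willingness-to-pay threshold.
#'
#' @param cfg An `slncea_config` (left untouched).
#' @param path Parameter path, see [set_parameter()].
#' @param range Numeric `c(low, high)`; defaults to the parameter's entry in
#'   [sensitivity_ranges()]. A collapsed range (`low == high`) yields a
#'   single repeated point.
#' @param n_points Grid size (>= 2).
#' @return A tibble of class `slncea_sweep`: `value`, the four strategy
#'   outcomes, `delta_cost`, `delta_qaly`, `icer` (NA off the trade-off
#'   quadrants), `classification`, `preferred`. The swept path and WTP are
#'   attached as attributes.
#' @export
one_way <- function(cfg, path, range = NULL, n_points = 101) {
  stopifnot(n_points >= 2)
  path <- normalize_path(path)
  if (is.null(range)) {
    range <- sensitivity_ranges()[[path]]
    if (is.null(range)) stop("no default sensitivity range for path: ", path)
  }
  grid <- seq(range[1], range[2], length.out = n_points)
  rows <- lapply(grid, function(v) {
    res <- evaluate_strategies(set_parameter(cfg, path, v))
    tibble::tibble(
      value = v,
      cost_tilmanocept = res$tilmanocept$expected_cost,
      qaly_tilmanocept = res$tilmanocept$expected_qaly,
      cost_sulfur_colloid = res$sulfur_colloid$expected_cost,
      qaly_sulfur_colloid = res$sulfur_colloid$expected_qaly,
      delta_cost = res$icer$delta_cost,
      delta_qaly = res$icer$delta_qaly,
      icer = res$icer$icer,
      classification = res$icer$classification,
      preferred = res$icer$preferred_at_wtp
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "path") <- path
  attr(out, "wtp") <- cfg$wtp_threshold
  class(out) <- c("slncea_sweep", class(out))
  out
}

#' Locate decision thresholds of a parameter by bisection
#'
#' Scans the decision function — the sign of the net-monetary-benefit
#' difference between the tilmanocept and sulfur colloid strategies at
#' `wtp`, which is continuous through the dominance quadrants where a raw
#' ICER is not — on a dense grid, then refines every sign change by
#' bisection. All thresholds found are returned; none are silently dropped.
#'
#' @inheritParams one_way
#' @param wtp Willingness-to-pay; defaults to the configuration's threshold.
#' @param n_scan Pre-scan grid size (>= 200 by default).
#' @param tol Bracket width at which bisection stops.
#' @return An object of class `slncea_threshold`: list with `path`,
#'   `thresholds` (a tibble with `threshold_value`, `bracket_low`,
#'   `bracket_high`, `decision_below`, `decision_above`; zero rows when the
#'   decision never changes) and `decision_at_low`/`decision_at_high`.
#' @export
find_threshold <- function(cfg, path, range = NULL, wtp = cfg$wtp_threshold,
                           n_scan = 201, tol = 1e-4) {
  path <- normalize_path(path)
  if (is.null(range)) {
    range <- sensitivity_ranges()[[path]]
    if (is.null(range)) stop("no default sensitivity range for path: ", path)
  }
  f <- function(v) strategy_nmb_diff(set_parameter(cfg, path, v), wtp)
  label <- function(fv) if (fv >= 0) "tilmanocept" else "sulfur_colloid"
  grid <- seq(range[1], range[2], length.out = max(2, n_scan))
  fv <- vapply(grid, f, numeric(1))
  sgn <- ifelse(fv >= 0, 1, -1)
  change <- which(diff(sgn) != 0)
  rows <- lapply(change, function(i) {
    lo <- grid[i]; hi <- grid[i + 1]
    flo <- fv[i]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if ((fm >= 0) == (flo >= 0)) {
        lo <- mid; flo <- fm
      } else {
        hi <- mid
      }
    }
    tibble::tibble(threshold_value = (lo + hi) / 2, bracket_low = lo,
                   bracket_high = hi, decision_below = label(fv[i]),
                   decision_above = label(fv[i + 1]))
  })
  thr <- if (length(rows)) do.call(rbind, rows) else {
    tibble::tibble(threshold_value = numeric(), bracket_low = numeric(),
                   bracket_high = numeric(), decision_below = character(),
                   decision_above = character())
  }
  structure(list(path = path, thresholds = thr,
                 decision_at_low = label(fv[1]),
                 decision_at_high = label(fv[length(fv)])),
            class = "slncea_threshold")
}

#' @export
print.slncea_threshold <- function(x, ...) {
  if (nrow(x$thresholds) == 0) {
    cat(sprintf("%s: no decision change over the range (always %s)\n",
                x$path, x$decision_at_low))
  } else {
    cat(sprintf("%s: %d decision threshold(s)\n", x$path, nrow(x$thresholds)))
    for (i in seq_len(nrow(x$thresholds))) {
      cat(sprintf("  %.4f: %s below, %s above\n",
                  x$thresholds$threshold_value[i],
                  x$thresholds$decision_below[i],
                  x$thresholds$decision_above[i]))
    }
  }
  invisible(x)
}

#' Two-way preference grid
#'
#' Evaluates the preferred strategy on an `n x n` grid of two parameters.
#'
#' @inheritParams one_way
#' @param path_a,path_b Parameter paths for the two axes.
#' @param range_a,range_b Numeric `c(low, high)` per axis; default from
#'   [sensitivity_ranges()].
#' @param n Grid points per axis (>= 2).
#' @return A long-format tibble of class `slncea_grid`: `value_a`,
#'   `value_b`, `nmb_diff` (tilmanocept minus sulfur colloid), `preferred`.
#' @export
two_way <- function(cfg, path_a, range_a = NULL, path_b, range_b = NULL,
                    n = 41) {
  stopifnot(n >= 2)
  path_a <- normalize_path(path_a); path_b <- normalize_path(path_b)
  if (is.null(range_a)) range_a <- sensitivity_ranges()[[path_a]]
  if (is.null(range_b)) range_b <- sensitivity_ranges()[[path_b]]
  if (is.null(range_a) || is.null(range_b)) {
    stop("no default sensitivity range for one of the paths")
  }
  ga <- seq(range_a[1], range_a[2], length.out = n)
  gb <- seq(range_b[1], range_b[2], length.out = n)
  grid <- expand.grid(value_a = ga, value_b = gb, KEEP.OUT.ATTRS = FALSE)
  nmb <- vapply(seq_len(nrow(grid)), function(i) {
    cfg2 <- set_parameter(cfg, path_a, grid$value_a[i])
    cfg2 <- set_parameter(cfg2, path_b, grid$value_b[i])
    strategy_nmb_diff(cfg2)
  }, numeric(1))
  out <- tibble::tibble(
    value_a = grid$value_a, value_b = grid$value_b, nmb_diff = nmb,
    preferred = ifelse(nmb >= 0, "tilmanocept", "sulfur_colloid")
  )
  attr(out, "path_a") <- path_a
  attr(out, "path_b") <- path_b
  class(out) <- c("slncea_grid", class(out))
  out
}

#' Sub-ranges of a sweep where the intervention dominates
#'
#' @param sweep A [one_way()] result.
#' @return A tibble with one row per maximal contiguous run of grid points
#'   classified `intervention_dominates`: `from`, `to` (grid values) and
#'   `n_points`. Zero rows when the intervention never dominates.
#' @export
dominance_region <- function(sweep) {
  dom <- sweep$classification == "intervention_dominates"
  r <- rle(dom)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  tibble::tibble(
    from = sweep$value[starts[keep]],
    to = sweep$value[ends[keep]],
    n_points = r$lengths[keep]
  )
}
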