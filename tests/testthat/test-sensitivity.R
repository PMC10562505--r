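test_that("a collapsed sweep at the base value reproduces the base case", {
  cfg <- base_case_config()
  base <- evaluate_strategies(cfg)
  sw <- one_way(cfg, "costs.agent_cost_tilmanocept", range = c(628, 628),
                n_points = 2)
  expect_equal(nrow(sw), 2L)
  expect_equal(sw$icer[1], base$icer$icer)
  expect_equal(sw$icer[2], base$icer$icer)
  expect_equal(sw$cost_tilmanocept[1], base$tilmanocept$expected_cost)
  expect_equal(sw$qaly_sulfur_colloid[1], base$sulfur_colloid$expected_qaly)
  expect_equal(attr(sw, "path"), "costs.agent_cost_tilmanocept")
})

test_that("one-way sweeps cover their grid and flag decision changes", {
  cfg <- base_case_config()
  sw <- one_way(cfg, "diag_sulfur.sensitivity", range = c(0.70, 1.00),
                n_points = 31)
  expect_equal(nrow(sw), 31L)
  expect_equal(sw$value, seq(0.70, 1.00, length.out = 31))
  expect_true(all(sw$preferred %in% c("tilmanocept", "sulfur_colloid")))
  # tilmanocept's own arm never moves when the comparator's test is swept
  expect_equal(diff(range(sw$cost_tilmanocept)), 0)
  expect_equal(diff(range(sw$qaly_tilmanocept)), 0)
  expect_error(one_way(cfg, "costs.no_such", range = c(0, 1)),
               "costs")
  expect_error(one_way(cfg, "prevalence", n_points = 1))
})

test_that("bisection thresholds agree with a much denser scan", {
  cfg <- base_case_config()
  thr <- find_threshold(cfg, "diag_sulfur.sensitivity", range = c(0.70, 1.00))
  expect_s3_class(thr, "slncea_threshold")
  expect_gte(nrow(thr$thresholds), 1L)
  dense <- find_threshold(cfg, "diag_sulfur.sensitivity",
                          range = c(0.70, 1.00), n_scan = 2001, tol = 1e-5)
  expect_equal(nrow(thr$thresholds), nrow(dense$thresholds))
  expect_equal(thr$thresholds$threshold_value,
               dense$thresholds$threshold_value, tolerance = 2e-4)
  expect_identical(thr$decision_at_low, dense$decision_at_low)
  expect_identical(thr$decision_at_high, dense$decision_at_high)
  # the reported crossing really separates the two decisions
  x <- thr$thresholds$threshold_value[1]
  below <- strategy_nmb_diff(set_parameter(cfg, "diag_sulfur.sensitivity",
                                           x - 0.01))
  above <- strategy_nmb_diff(set_parameter(cfg, "diag_sulfur.sensitivity",
                                           x + 0.01))
  expect_true(sign(below) != sign(above))
})

test_that("a range with no decision change reports zero thresholds", {
  cfg <- base_case_config()
  thr <- find_threshold(cfg, "costs.agent_cost_tilmanocept",
                        range = c(400, 1500))
  expect_equal(nrow(thr$thresholds), 0L)
  expect_equal(thr$decision_at_low, "tilmanocept")
  expect_identical(thr$decision_at_low, thr$decision_at_high)
})

test_that("dominance regions are the maximal runs of dominating points", {
  fake <- tibble::tibble(
    value = 1:8,
    classification = c("tradeoff", "intervention_dominates",
                       "intervention_dominates", "tradeoff",
                       "comparator_dominates", "intervention_dominates",
                       "tradeoff", "tradeoff")
  )
  reg <- dominance_region(fake)
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$from, c(2, 6))
  expect_equal(reg$to, c(3, 6))
  expect_equal(reg$n_points, c(2L, 1L))
  none <- dominance_region(tibble::tibble(value = 1:3,
                                          classification = rep("tradeoff", 3)))
  expect_equal(nrow(none), 0L)
})

test_that("two-way grids are complete and consistent with the NMB sign", {
  cfg <- base_case_config()
  gr <- two_way(cfg, "diag_tilmanocept.specificity", c(0.9, 1.0),
                "diag_sulfur.specificity", c(0.9, 1.0), n = 3)
  expect_equal(nrow(gr), 9L)
  expect_setequal(unique(gr$value_a), seq(0.9, 1.0, length.out = 3))
  expect_identical(gr$preferred,
                   ifelse(gr$nmb_diff >= 0, "tilmanocept", "sulfur_colloid"))
  # a grid point equals the direct evaluation at those parameter values
  cfg2 <- set_parameter(cfg, "diag_tilmanocept.specificity", 0.95)
  cfg2 <- set_parameter(cfg2, "diag_sulfur.specificity", 1.0)
  i <- which(gr$value_a == 0.95 & gr$value_b == 1.0)
  expect_equal(gr$nmb_diff[i], strategy_nmb_diff(cfg2))
})
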