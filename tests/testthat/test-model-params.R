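test_that("base case reproduces the printed parameter tables", {
  cfg <- base_case_config()
  expect_equal(cfg$diag_tilmanocept$sensitivity, 0.979)
  expect_equal(cfg$diag_tilmanocept$specificity, 0.990)
  expect_equal(cfg$diag_sulfur$sensitivity, 0.727)
  expect_equal(cfg$prevalence, 0.280)
  expect_equal(unname(cfg$transitions$dm_row), c(0.837, 0.163))
  expect_equal(unname(cfg$transitions$ned_row_fn),
               c(0.749, 0.007, 0.137, 0.003, 0.104))
  expect_equal(cfg$costs$agent_cost_sulfur_colloid, 105)
  expect_equal(cfg$costs$eol_care, 11101)
  expect_equal(cfg$utilities$utility_post_resection, 0.913)
  expect_equal(cfg$p_rt_given_positive, 0.49)
  expect_equal(cfg$horizon_years, 30L)
  expect_equal(cfg$discount_rate, 0.03)
  expect_equal(cfg$wtp_threshold, 1e5)
})

test_that("sensitivity ranges cover every ranged parameter and resolve", {
  cfg <- base_case_config()
  rng <- sensitivity_ranges()
  # every path addressable and oriented low <= high
  for (p in names(rng)) {
    expect_no_error(get_parameter(cfg, p))
    expect_lte(rng[[p]][1], rng[[p]][2])
  }
  expect_equal(rng[["diag_tilmanocept.sensitivity"]], c(0.750, 1.000))
  expect_equal(rng[["costs.agent_cost_tilmanocept"]], c(400, 1500))
  expect_equal(rng[["transitions.lr_row.LR->DM"]], c(0.100, 0.500))
  # disutility ranges orientation-normalized (more negative bound first)
  expect_equal(rng[["utilities.disutility_salvage"]], c(-0.093, -0.034))
  # one entry per ranged row cell: 5 diagnostics/prevalence, 18 transition
  # cells (NED rows appear for both columns), 11 costs, 6 utilities
  expect_length(rng, 5 + 18 + 11 + 6)
})

test_that("validation flags exactly the known base-case findings", {
  report <- validate_config(base_case_config())
  expect_true(is_valid(report))
  norm <- report[report$severity == "normalizable", ]
  expect_equal(nrow(norm), 1L)
  expect_equal(norm$path, "transitions.ned_row_standard")
  # the salvage disutility base value lies outside its printed range
  notes <- report[report$severity == "note", ]
  expect_true("utilities.disutility_salvage" %in% notes$path)
})

test_that("validation reports invariant violations without throwing", {
  cfg <- base_case_config()
  cfg$diag_tilmanocept$sensitivity <- 1.2
  r1 <- validate_config(cfg)
  expect_false(is_valid(r1))
  expect_match(r1$message[r1$path == "diag_tilmanocept.sensitivity" &
                            r1$severity == "invalid"],
               "probability out of range")

  cfg2 <- base_case_config()
  cfg2$transitions$lr_row[] <- c(0.5, 0.5, 0.5)
  r2 <- validate_config(cfg2)
  expect_false(is_valid(r2))
  expect_match(r2$message[r2$path == "transitions.lr_row"], "row sum 1.5")

  cfg3 <- base_case_config()
  cfg3$costs$eol_care <- -5
  expect_false(is_valid(validate_config(cfg3)))
})

test_that("set_parameter is copy-on-write and rescales transition rows", {
  cfg <- base_case_config()
  cfg2 <- set_parameter(cfg, "diag_sulfur.sensitivity", 0.9)
  expect_equal(get_parameter(cfg2, "diag_sulfur.sensitivity"), 0.9)
  expect_equal(get_parameter(cfg, "diag_sulfur.sensitivity"), 0.727)
  # only that leaf differs
  cfg2$diag_sulfur$sensitivity <- 0.727
  expect_identical(cfg, cfg2)

  # proportional rescale: others multiplied by (1 - new) / (their old sum)
  cfg3 <- set_parameter(cfg, "transitions.ned_row_standard.NED->NED", 0.9)
  row <- cfg3$transitions$ned_row_standard
  old <- c(0.032, 0.035, 0.004, 0.061)
  expect_equal(unname(row),
               c(0.9, old * (1 - 0.9) / sum(old)))
  expect_equal(sum(row), 1)
  # the unicode arrow form is accepted too
  cfg4 <- set_parameter(cfg, "transitions.ned_row_standard.NED→NED", 0.9)
  expect_identical(cfg3, cfg4)
})

test_that("unknown paths error with the nearest valid suggestion", {
  cfg <- base_case_config()
  expect_error(set_parameter(cfg, "diag_sulfur.sensibility", 0.9),
               "diag_sulfur.sensitivity")
  expect_error(get_parameter(cfg, "costs.eol"), "costs.eol_care")
})

test_that("configs round-trip through YAML bit-for-bit", {
  cfg <- base_case_config()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, f)
  expect_identical(read_config(f), cfg)
  # full-precision doubles from the generator survive as well
  rc <- random_config(11)
  write_config(rc, f)
  expect_identical(read_config(f), rc)
  # the bundled base case equals the built-in one
  bundled <- system.file("extdata", "base_case.yaml", package = "slncea")
  expect_identical(read_config(bundled), cfg)
  expect_error(read_config("no/such/file.yaml"), "not found")
})
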