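test_that("scenario runs are pure and the empty scenario is the identity", {
  p <- fixture_params()
  before <- serialize(p, NULL)
  base <- run_model(p)
  res <- run_scenario(p, scenario_spec("noop", list()))
  expect_identical(serialize(p, NULL), before) # base untouched, bit for bit
  expect_equal(res$arms, base$arms)
  expect_equal(res$ratio, base$ratio)
})

test_that("unknown override paths raise a configuration error", {
  p <- fixture_params()
  expect_error(apply_overrides(p, list("config.not_a_field" = 1)), "not_a_field")
  expect_error(apply_overrides(p, list("arms.bevacizumab.injections_per_year" = 1)), "bevacizumab")
  expect_error(apply_overrides(p, list(1, 2)), "named")
  # an override producing an invalid configuration fails validation
  expect_error(
    apply_overrides(p, list("config.starting_distribution" = c(1, 1, 0, 0, 0))),
    "summing to 1"
  )
})

test_that("swapping the utility elicitation method changes QALYs but never costs", {
  p <- fixture_params()
  tto <- run_model(p)
  sg <- run_scenario(p, scenario_spec("sg", list("config.utility_method" = "sg")))
  expect_equal(sg$arms$cost, tto$arms$cost, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(sg$arms$qaly, tto$arms$qaly)))
})

test_that("extrapolation approaches behave as defined after year one", {
  p <- fixture_params()

  # continuous: the same matrix persists at every cycle
  tr <- run_cohort(p, "dexamethasone")
  mats <- attr(tr, "cycle_matrices")
  expect_equal(mats[[20]][1:5, 1:5] / (1 - mats[[20]][1, 6]),
    unclass(p$arms$dexamethasone$transition),
    ignore_attr = TRUE, tolerance = 1e-12
  )

  # one-time benefit: both arms share one visual-acuity matrix beyond year 1
  m_ref <- post_year1_matrix(p, "aflibercept", "one_time_benefit")
  m_int <- post_year1_matrix(p, "dexamethasone", "one_time_benefit")
  expect_equal(unclass(m_ref), unclass(m_int), ignore_attr = TRUE)
  # and that matrix has no improvement transitions
  expect_true(all(unclass(m_ref)[lower.tri(unclass(m_ref))] == 0))
  p_otb <- apply_overrides(p, list("config.extrapolation" = "one_time_benefit"))
  tr_a <- run_cohort(p_otb, "aflibercept")
  tr_d <- run_cohort(p_otb, "dexamethasone")
  k <- 10 # cycle beyond the first treatment year
  expect_equal(attr(tr_a, "cycle_matrices")[[k]], attr(tr_d, "cycle_matrices")[[k]],
    tolerance = 1e-12
  )

  # treatment costs stop after year 1 under one-time benefit
  expect_lt(tr_d$cost_rate[10], tr_d$cost_rate[1])
  expect_equal(
    tr_d$cost_rate[10],
    annual_cost_components(p, "dexamethasone")$ongoing * 0.25,
    tolerance = 1e-12
  )

  expect_error(
    apply_overrides(p, list("config.extrapolation" = "beyond_belief")),
    "should be one of"
  )
})

test_that("rebound erodes the treatment benefit towards the reference trajectory", {
  p <- fixture_params()
  cont <- run_model(apply_overrides(p, list("config.extrapolation" = "continuous")))
  otb <- run_model(apply_overrides(p, list("config.extrapolation" = "one_time_benefit")))
  reb <- run_model(apply_overrides(p, list("config.extrapolation" = "rebound")))
  # catch-up can only shrink the QALY gain relative to one-time benefit,
  # and never reverses the better arm's advantage
  expect_gt(reb$delta_qaly, 0)
  expect_lt(reb$delta_qaly, otb$delta_qaly)
  expect_lt(otb$delta_qaly, cont$delta_qaly)
  # the reference arm is unaffected by which of the two modes is chosen
  expect_equal(reb$arms$qaly[1], otb$arms$qaly[1], tolerance = 1e-12)
})

test_that("a one-year cycle with re-aggregated probabilities reproduces quarterly results within 5%", {
  p <- fixture_params()
  base <- run_model(p)
  annual <- run_scenario(p, scenario_spec("annual", list("config.cycle_length_years" = 1)))
  expect_equal(annual$delta_cost, base$delta_cost, tolerance = 0.05)
  expect_equal(annual$delta_qaly, base$delta_qaly, tolerance = 0.05)
})

test_that("the default scenario suite runs and responds in the expected directions", {
  p <- fixture_params()
  scen <- run_scenario_suite(p)
  expect_identical(anyDuplicated(scen$scenario), 0L)
  ref <- scen[scen$scenario == "reference", ]
  # shorter horizons shrink both increments towards the first-year gap
  two <- scen[scen$scenario == "two_year_horizon", ]
  expect_lt(abs(two$delta_cost), abs(ref$delta_cost))
  expect_lt(two$delta_qaly, ref$delta_qaly)
  # removing discounting inflates both increments
  d0 <- scen[scen$scenario == "discount_0pct", ]
  expect_gt(abs(d0$delta_cost), abs(ref$delta_cost))
  expect_gt(d0$delta_qaly, ref$delta_qaly)
  d5 <- scen[scen$scenario == "discount_5pct", ]
  expect_lt(abs(d5$delta_cost), abs(ref$delta_cost))
  # fewer injections narrow the drug-cost gap between the arms
  pr <- scen[scen$scenario == "pronto_injections", ]
  expect_lt(abs(pr$delta_cost), abs(ref$delta_cost))
  expect_equal(pr$delta_qaly, ref$delta_qaly, tolerance = 1e-12)
  # indirect costs hit both arms equally: increments unchanged
  ind <- scen[scen$scenario == "indirect_costs", ]
  expect_equal(ind$delta_cost, ref$delta_cost, tolerance = 1e-9)
  expect_gt(ind$cost_ref, ref$cost_ref)
  # single-state starting cohorts exercise every state
  expect_true(all(paste0("start_state_", 1:5) %in% scen$scenario))
})

test_that("tornado entries are sorted by width and the horizon dominates", {
  p <- fixture_params()
  torn <- tornado(p)
  expect_true(all(diff(torn$width) <= 1e-9)) # descending
  expect_identical(torn$parameter[1], "time_horizon")
  expect_setequal(
    torn$parameter,
    vapply(default_tornado_pairs(p), `[[`, character(1), "name")
  )
  # a pair with identical sides has zero width
  noop <- tornado_pair("noop", scenario_spec("a", list()), scenario_spec("b", list()))
  expect_equal(tornado(p, list(noop))$width, 0)
})
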