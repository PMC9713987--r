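test_that("annual-to-cycle probability conversion matches the rate formula", {
  expect_equal(annual_prob_to_cycle_prob(0, 0.25), 0)
  for (p in c(0.01, 0.3, 0.77)) {
    expect_equal(annual_prob_to_cycle_prob(p, 1), p) # identity at a full year
    # agreement with the exponential-rate formulation 1 - e^(-rt)
    r <- -log(1 - p)
    expect_equal(annual_prob_to_cycle_prob(p, 0.25), 1 - exp(-r * 0.25), tolerance = 1e-15)
  }
  expect_equal(annual_prob_to_cycle_prob(0.3, 0.25), 0.0853088, tolerance = 1e-6)
  expect_equal(annual_prob_to_cycle_prob(1, 0.25), 1) # documented edge
  expect_error(annual_prob_to_cycle_prob(1.2, 0.25), "\\[0, 1\\]")
  expect_error(annual_prob_to_cycle_prob(0.5, 0), "positive")
})

test_that("four quarter-cycles compose back to the annual probability exactly", {
  for (p in c(0.001, 0.08, 0.3, 0.62, 0.95)) {
    pc <- annual_prob_to_cycle_prob(p, 0.25)
    expect_equal(1 - (1 - pc)^4, p, tolerance = 1e-12)
    expect_equal(cycle_prob_to_annual_prob(pc, 0.25), p, tolerance = 1e-12)
  }
})

test_that("discount factor follows annual-equivalent compounding", {
  expect_equal(discount_factor(5, 0), 1)
  expect_equal(discount_factor(0, 0.035), 1)
  expect_equal(discount_factor(1, 0.035), 0.96618, tolerance = 1e-5)
  expect_equal(discount_factor(2, 0.035), 1 / 1.035^2)
  expect_error(discount_factor(-1, 0.035), "nonnegative")
})

test_that("mortality embedding scales rows by survival and keeps death absorbing", {
  p <- fixture_params()
  m <- p$arms$dexamethasone$transition

  m0 <- embed_mortality(m, 0)
  expect_equal(m0[1:5, 1:5], unclass(m), ignore_attr = TRUE)
  expect_equal(m0[1:5, 6], rep(0, 5))
  expect_equal(m0[6, ], c(0, 0, 0, 0, 0, 1))

  m1 <- embed_mortality(m, 1)
  expect_equal(m1[, 6], rep(1, 6))

  mq <- embed_mortality(m, 0.01)
  expect_equal(
    unname(mq[1, ]),
    c(0.976437, 0.010593, 0.002970, 0, 0, 0.01) # printed row scaled by 0.99
  )
  expect_true(all(abs(rowSums(mq) - 1) < 1e-12))

  bad <- diag(5)
  bad[3, 3] <- 0.7
  expect_error(embed_mortality(bad, 0.1), "row 3")
})

test_that("degenerate single-state cohorts reproduce closed-form QALYs", {
  # stay in the best state, no death, utility 0.85, one undiscounted year
  p <- degenerate_params(u = 0.85, q = 0, horizon_years = 1, d = 0)
  res <- accumulate_trace(run_cohort(p, "aflibercept"))
  expect_equal(res$qaly, 0.85, tolerance = 1e-12)
  expect_equal(res$cost, 0, tolerance = 1e-6)

  # forty years of full health-state occupancy: Q = u * T
  p40 <- degenerate_params(u = 0.85, q = 0, horizon_years = 40, d = 0)
  expect_equal(accumulate_trace(run_cohort(p40, "aflibercept"))$qaly, 34, tolerance = 1e-9)

  # certain death within the first year: immediate absorption afterwards
  pdie <- degenerate_params(u = 0.85, q = 1, horizon_years = 2, d = 0)
  tr <- run_cohort(pdie, "aflibercept")
  expect_equal(sum(tr$qaly), 0.85 * 0.25, tolerance = 1e-12)
  expect_equal(tr$occ_death[2], 1)
})

test_that("occupancy is conserved and death is monotone on randomised models", {
  set.seed(101)
  for (rep in 1:8) {
    p <- make_synthetic_model(decline_gap = stats::runif(1, 0, 0.1))
    for (arm in names(p$arms)) {
      tr <- run_cohort(p, arm)
      occ <- as.matrix(tr[, c(paste0("occ", 1:5), "occ_death")])
      expect_true(all(abs(rowSums(occ) - 1) < 1e-9))
      expect_true(all(diff(tr$occ_death) >= -1e-12))
      res <- accumulate_trace(tr)
      expect_gte(res$cost, 0)
      expect_gte(res$qaly, 0)
      horizon_years <- nrow(tr) * p$config$cycle_length_years
      expect_lte(res$qaly, horizon_years * max(p$utilities$mean) + 1e-9)
    }
  }
})

test_that("discounted life-years converge to the continuous annuity as t shrinks", {
  # constant annual mortality q, no VA dynamics, utility 1:
  # integral of e^(-(mu+delta)s) ds over the horizon, mu = -log(1-q),
  # delta = log(1+d)
  q <- 0.03
  d <- 0.035
  horizon <- 40
  a <- -log(1 - q) + log(1 + d)
  analytic <- (1 - exp(-horizon * a)) / a
  err <- sapply(c(0.25, 1 / 12), function(t) {
    p <- degenerate_params(u = 1, q = q, horizon_years = horizon, d = d, cycle_length = t)
    engine <- accumulate_trace(run_cohort(p, "aflibercept"))$qaly
    abs(engine - analytic) / analytic
  })
  expect_lt(err[1], 0.01) # within 1% at quarterly cycles
  expect_lt(err[2], err[1]) # and converging as the cycle shrinks
})

test_that("half-cycle correction averages adjacent occupancies", {
  q <- 0.03
  t <- 0.25
  surv <- (1 - q)^(t * (0:4)) # engine survival at cycle starts
  expected_plain <- t * sum(surv[1:4])
  expected_hcc <- t * sum((surv[1:4] + surv[2:5]) / 2)
  p <- degenerate_params(u = 1, q = q, horizon_years = 1, d = 0)
  expect_equal(accumulate_trace(run_cohort(p, "aflibercept"))$qaly,
    expected_plain,
    tolerance = 1e-12
  )
  p_hcc <- degenerate_params(u = 1, q = q, horizon_years = 1, d = 0, half_cycle_correction = TRUE)
  expect_equal(accumulate_trace(run_cohort(p_hcc, "aflibercept"))$qaly,
    expected_hcc,
    tolerance = 1e-12
  )
  expect_lt(expected_hcc, expected_plain) # declining cohorts accrue less
})

test_that("zero discounting makes discounted and undiscounted totals agree", {
  p <- apply_overrides(fixture_params(), list("config.discount_rate_per_year" = 0))
  tr <- run_cohort(p, "dexamethasone")
  res <- accumulate_trace(tr)
  expect_equal(res$cost, res$undiscounted_cost, tolerance = 1e-12)
  expect_equal(res$qaly, res$undiscounted_qaly, tolerance = 1e-12)
})

test_that("the ICER reproduces the published worked example and dominance rules", {
  # printed per-arm totals: cost 92,340 / 169,689, QALYs 4.134 / 6.80
  res <- compute_icer(92340, 4.134, 169689, 6.80)
  expect_equal(res$delta_cost, 77349)
  expect_equal(res$icer, 29002, tolerance = 20 / 29002) # printed rounding slack
  # printed increments: +77,349 EUR and +2.667 QALYs
  res2 <- compute_icer(0, 0, 77349, 2.667)
  expect_equal(round(res2$icer), 29002)

  expect_identical(compute_icer(100, 1, 90, 2)$dominance, "dominant")
  expect_true(is.na(compute_icer(100, 1, 90, 2)$icer))
  expect_identical(compute_icer(100, 2, 150, 1)$dominance, "dominated")
  und <- compute_icer(100, 1, 150, 1)
  expect_true(is.na(und$icer) && is.na(und$dominance))
  expect_equal(und$delta_cost, 50)
  # both-negative increments sit in quadrant III with a defined ICER
  expect_equal(compute_icer(100, 2, 50, 1)$icer, 50)
})

test_that("trace export writes state-labelled columns", {
  p <- degenerate_params(horizon_years = 1)
  tr <- run_cohort(p, "aflibercept")
  f <- tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  got <- utils::read.csv(f, check.names = FALSE)
  expect_true(all(va_states() %in% names(got)))
  expect_equal(nrow(got), nrow(tr))
})
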