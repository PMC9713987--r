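test_that("bundled fixture transcribes the published inputs", {
  p <- fixture_params()

  expect_identical(names(p$arms), c("aflibercept", "dexamethasone"))
  expect_equal(
    unname(unclass(p$arms$dexamethasone$transition)[1, ]),
    c(0.9863, 0.0107, 0.0030, 0, 0)
  )
  expect_equal(
    unname(unclass(p$arms$aflibercept$transition)[1, ]),
    c(0.9199, 0.0542, 0.0259, 0, 0)
  )
  u <- p$utilities
  expect_equal(u$mean[u$method == "tto" & u$state == ">20/40"], 0.85)
  expect_equal(u$low[u$method == "tto" & u$state == ">20/40"], 0.75)
  expect_equal(u$high[u$method == "tto" & u$state == ">20/40"], 0.95)
  expect_equal(u$high[u$method == "sg" & u$state == "<=20/400"], 1.11)
  expect_equal(p$arms$aflibercept$injections_per_year, 9.8)
  expect_equal(p$arms$dexamethasone$injections_per_year, 3.1)
  expect_equal(p$config$starting_age_years, 68.1)
  expect_equal(p$config$discount_rate_per_year, 0.035)
})

test_that("both full transition matrices and every printed row validate as stochastic", {
  p <- fixture_params()
  for (nm in names(p$arms)) {
    m <- p$arms[[nm]]$transition
    expect_length(validate_transition_matrix(m), 0)
    # each printed row sums to 1 exactly at double precision
    expect_true(all(abs(rowSums(unclass(m)) - 1) < 1e-12))
    # banded structure: improvement only one step, worsening at most two
    for (i in 1:5) {
      for (j in 1:5) {
        if (j < i - 1 || j > i + 2) expect_identical(unclass(m)[i, j], 0)
      }
    }
  }
})

test_that("validate_transition_matrix reports range and row-sum violations", {
  expect_length(validate_transition_matrix(diag(5)), 0)
  m <- diag(5)
  m[2, ] <- c(0.5, 0.5, 0.5, 0, 0)
  v <- validate_transition_matrix(m)
  expect_length(v, 1)
  expect_match(v, "row 2")
  m2 <- diag(5)
  m2[1, 1] <- -0.1
  m2[1, 2] <- 1.1
  expect_match(validate_transition_matrix(m2), "outside", all = FALSE)
  expect_error(transition_matrix(m), "row 2")
})

test_that("schema violations are reported with the offending field", {
  raw <- yaml::read_yaml(fixture_yaml_path())
  raw$arms$aflibercept$drug$injections_per_year <- NULL
  bad <- tempfile(fileext = ".yaml")
  yaml::write_yaml(raw, bad)
  expect_error(load_parameters(bad, quiet = TRUE), "injections_per_year")

  txt <- readLines(fixture_yaml_path())
  txt <- sub("0.9199", "0.8199", txt, fixed = TRUE)
  bad2 <- tempfile(fileext = ".yaml")
  writeLines(txt, bad2)
  expect_error(load_parameters(bad2, quiet = TRUE), "row 1")

  expect_error(load_parameters(tempfile(), quiet = TRUE), "not found")
})

test_that("write_parameters round-trips every field and is byte-stable", {
  p <- fixture_params()
  f1 <- tempfile(fileext = ".yaml")
  f2 <- tempfile(fileext = ".yaml")
  write_parameters(p, f1)
  p2 <- load_parameters(f1, quiet = TRUE)
  expect_equal(p2, p, tolerance = 1e-12)
  write_parameters(p2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("every published table number appears at its documented fixture field", {
  manifest <- utils::read.csv(test_path("fixture-manifest.csv"))
  raw <- yaml::read_yaml(fixture_yaml_path())
  for (i in seq_len(nrow(manifest))) {
    got <- yaml_path_get(raw, manifest$path[i])
    expect_equal(got, manifest$value[i],
      info = paste("fixture field", manifest$path[i])
    )
  }
})

test_that("life table I/O validates its contract", {
  lt <- make_life_table()
  f <- tempfile(fileext = ".csv")
  write_life_table(lt, f)
  lt2 <- read_life_table(f)
  expect_equal(lt2$qx, lt$qx, tolerance = 1e-12)
  expect_equal(qx_at(lt, 68.9), lt$qx[lt$age == 68])
  expect_equal(qx_at(lt, 150), 1) # beyond the table: certain death
  expect_error(qx_at(lt, 20), "below")
  bad <- data.frame(age = 60:70, qx = 0.01)
  expect_error(dmecea:::as_life_table(bad), "qx = 1")
})

test_that("utility tables enforce their invariants", {
  df <- data.frame(state = va_states(), mean = 0.9, low = 0.0, high = 0.8)
  expect_error(utility_table(df, df), "outside its range")
  u6 <- state_utilities(fixture_params(), "tto", include_death = TRUE)
  expect_length(u6, 6)
  expect_identical(unname(u6[6]), 0) # death utility exactly zero
  expect_equal(unname(state_utilities(fixture_params(), "sg")[1]), 0.90)
})

test_that("annual cost components split treatment from ongoing costs", {
  p <- fixture_params()
  cc <- annual_cost_components(p, "aflibercept")
  expect_equal(cc$treatment,
    588.8 * 9.8 + (112 * 12 + 20 * 12 + 149 * 6 + 42 * 2) +
      (3156 * 0.006 + 1600 * 0.004 + 3702 * 0.004)
  )
  expect_equal(cc$ongoing, 69 + 211 + 771 + 1577)
  # per-arm interpretation of the two published annual figures
  p$shared$other_cost_interpretation <- "arm"
  cc_arm <- annual_cost_components(p, "dexamethasone")
  expect_equal(cc_arm$ongoing, 69 + 211 + 1577)
  # indirect costs are added to ongoing when enabled
  p2 <- apply_overrides(fixture_params(), list("config.include_indirect_costs" = TRUE))
  expect_equal(
    annual_cost_components(p2, "aflibercept")$ongoing,
    69 + 211 + 771 + 1577 + p2$config$indirect_annual_cost
  )
})

test_that("model_config rejects invalid settings", {
  expect_error(model_config(cycle_length_years = 0), "cycle_length")
  expect_error(model_config(starting_distribution = c(0.5, 0.5, 0.5, 0, 0)), "summing to 1")
  expect_error(model_config(horizon = "fixed"), "horizon_years")
  expect_error(model_config(discount_rate_per_year = -0.01), ">= 0")
})
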