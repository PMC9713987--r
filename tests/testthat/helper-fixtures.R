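# shared fixtures built in code; nothing here touches the network or disk
# beyond tempdir()

fixture_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- default_parameters(quiet = TRUE)
    cache
  }
})

# constant-hazard life table (same annual death probability at every age)
const_life_table <- function(q, min_age = 0, max_age = 120) {
  df <- data.frame(age = min_age:max_age, qx = q)
  df$qx[nrow(df)] <- 1
  structure(df, class = c("life_table", "data.frame"), source = "test constant hazard")
}

# flat utility table: the same utility u in every living state, both methods
flat_utilities <- function(u) {
  df <- data.frame(state = va_states(), mean = u, low = 0, high = 1)
  utility_table(tto = df, sg = df)
}

# degenerate single-state world: identity transitions, utility u everywhere,
# constant annual mortality q, all costs zero unless kept
degenerate_params <- function(u = 0.85, q = 0, horizon_years = 1, d = 0,
                              cycle_length = 0.25, zero_costs = TRUE,
                              half_cycle_correction = FALSE) {
  p <- fixture_params()
  for (nm in names(p$arms)) {
    p$arms[[nm]]$transition <- transition_matrix(diag(5), arm_label = nm)
    if (zero_costs) {
      p$arms[[nm]]$drug_unit_cost <- 1e-9 # positivity required; negligible
      p$arms[[nm]]$injections_per_year <- 1e-9
      p$arms[[nm]]$resource_use$unit_cost[] <- 1e-9
      p$arms[[nm]]$resource_use$per_year_mean[] <- 0
      p$arms[[nm]]$adverse_events$annual_rate[] <- 0
      p$arms[[nm]]$rehabilitation_cost_per_year <- 0
      p$arms[[nm]]$equipment_cost_per_year <- 0
      p$arms[[nm]]$other_annual_cost <- 0
    }
  }
  if (zero_costs) {
    p$shared$comorbidity_annual_cost <- 0
    p$shared$nonmedical_annual_cost <- 0
  }
  p$utilities <- flat_utilities(u)
  p$life_table <- const_life_table(q)
  p$config <- model_config(
    cycle_length_years = cycle_length,
    discount_rate_per_year = d,
    starting_age_years = 68.1,
    horizon = "fixed",
    horizon_years = horizon_years,
    starting_distribution = c(1, 0, 0, 0, 0),
    starting_distribution_source = "test",
    half_cycle_correction = half_cycle_correction
  )
  p
}

# walk a parsed YAML structure along a dot-separated path; integer-looking
# keys index into unnamed lists
yaml_path_get <- function(x, path) {
  for (key in strsplit(path, ".", fixed = TRUE)[[1]]) {
    x <- if (grepl("^[0-9]+$", key)) x[[as.integer(key)]] else x[[key]]
    if (is.null(x)) stop("path not found: ", path)
  }
  x
}

fixture_yaml_path <- function() {
  system.file("extdata", "dme_parameters.yaml", package = "dmecea", mustWork = TRUE)
}
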