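#' Common natural-decline matrix
#'
#' After treatment stops, vision is assumed to decline at a common rate for
#' both arms: improvement entries (below the diagonal) are zeroed and the
#' diagonal absorbs the freed mass, keeping the reported worsening
#' probabilities. The default donor of the decline entries is the reference
#' arm's matrix; any valid matrix may be supplied instead.
#'
#' @param m a [transition_matrix()] donating the decline (worsening) entries.
#' @return A `transition_matrix` with no improvement transitions.
#' @export
common_decline_matrix <- function(m) {
  out <- unclass(m)
  for (i in seq_len(N_VA_STATES)) {
    worse <- seq_len(N_VA_STATES) > i
    out[i, !worse] <- 0
    out[i, i] <- 1 - sum(out[i, worse])
  }
  transition_matrix(out,
    arm_label = paste0(attr(m, "arm_label") %||% "", " (natural decline)"),
    cycle_length_years = attr(m, "cycle_length_years") %||% 0.25
  )
}

# multiply decline probabilities by `mult`, diagonal takes the complement
accelerate_decline <- function(m, mult) {
  out <- unclass(m)
  for (i in seq_len(N_VA_STATES)) {
    worse <- seq_len(N_VA_STATES) > i
    out[i, worse] <- pmin(out[i, worse] * mult, 1)
    d <- 1 - sum(out[i, worse])
    if (d < 0) {
      out[i, worse] <- out[i, worse] / sum(out[i, worse])
      d <- 0
    }
    out[i, i] <- d
    out[i, seq_len(N_VA_STATES) < i] <- 0
  }
  transition_matrix(out,
    arm_label = paste0(attr(m, "arm_label") %||% "", " (accelerated decline)"),
    cycle_length_years = attr(m, "cycle_length_years") %||% 0.25
  )
}

#' Visual-acuity matrix in force after the first treatment year
#'
#' Implements the three extrapolation approaches for projecting one-year
#' trial effects over a lifetime horizon:
#' * `"continuous"` (and `"none"`): the arm's own first-year matrix, and
#'   full treatment costs, persist for the whole horizon;
#' * `"one_time_benefit"`: treatment stops after one year; both arms then
#'   follow a single [common_decline_matrix()] (improvements zeroed, decline
#'   entries from the reference arm by default) and treatment-specific costs
#'   stop;
#' * `"rebound"`: as one-time benefit, but the better-responding arm's
#'   decline probabilities are multiplied by
#'   `config$rebound_decline_multiplier` until its visual-acuity mix matches
#'   the reference arm's within `config$rebound_tv_tolerance`
#'   (total-variation distance, conditional on being alive), after which it
#'   follows the common decline. The catch-up matrix itself is built inside
#'   [run_cohort()]; this helper returns the common-decline destination.
#'
#' @param params a `dme_params` parameter set.
#' @param arm arm name or `dme_arm` (used for `"continuous"`).
#' @param mode extrapolation mode.
#' @param config a `model_config`.
#' @return A `transition_matrix` at the configured cycle length.
#' @export
post_year1_matrix <- function(params, arm,
                              mode = c("continuous", "one_time_benefit", "rebound", "none"),
                              config = params$config) {
  mode <- match.arg(mode)
  if (is.character(arm)) arm <- params$arms[[arm]]
  t <- config$cycle_length_years
  at_t <- function(m) {
    if (isTRUE(all.equal(params$transition_cycle_length_years, t))) {
      m
    } else {
      rescale_transition_matrix(m, params$transition_cycle_length_years, t)
    }
  }
  if (mode %in% c("continuous", "none")) {
    return(at_t(arm$transition))
  }
  common_decline_matrix(at_t(params$arms[[1]]$transition))
}

#' Define a named scenario
#'
#' A scenario is a named set of overrides applied on top of a base parameter
#' set. Override names are dot-separated paths into the `dme_params`
#' structure (e.g. `"config.discount_rate_per_year"`,
#' `"arms.aflibercept.injections_per_year"`); unknown paths raise an error.
#'
#' @param name scenario name.
#' @param overrides named list of `path = value` overrides.
#' @param description free-text description.
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(name, overrides = list(), description = "") {
  structure(
    list(name = name, overrides = overrides, description = description),
    class = "scenario_spec"
  )
}

set_path <- function(x, keys, value, full) {
  key <- keys[[1]]
  if (!(key %in% names(x))) {
    stop("unknown parameter path '", full, "' (no field '", key, "')", call. = FALSE)
  }
  if (length(keys) == 1) {
    x[[key]] <- value
  } else {
    x[[key]] <- set_path(x[[key]], keys[-1], value, full)
  }
  x
}

#' Apply scenario overrides to a parameter set
#'
#' Pure: returns a modified copy, never mutates `params`. After applying the
#' overrides the configuration is re-validated through [model_config()], so
#' an override producing an invalid configuration fails loudly.
#'
#' @param params a `dme_params` parameter set.
#' @param overrides named list of `path = value` pairs (see [scenario_spec()]).
#' @return A new `dme_params`.
#' @export
apply_overrides <- function(params, overrides) {
  if (!length(overrides)) {
    return(params)
  }
  if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
    stop("overrides must be a named list", call. = FALSE)
  }
  out <- params
  for (path in names(overrides)) {
    out <- set_path(out, strsplit(path, ".", fixed = TRUE)[[1]], overrides[[path]], path)
  }
  cfg <- out$config
  out$config <- model_config(
    cycle_length_years = cfg$cycle_length_years,
    discount_rate_per_year = cfg$discount_rate_per_year,
    starting_age_years = cfg$starting_age_years,
    horizon = cfg$horizon,
    horizon_years = cfg$horizon_years,
    starting_distribution = cfg$starting_distribution,
    starting_distribution_source = cfg$starting_distribution_source,
    utility_method = cfg$utility_method,
    extrapolation = cfg$extrapolation,
    half_cycle_correction = cfg$half_cycle_correction,
    include_indirect_costs = cfg$include_indirect_costs,
    indirect_annual_cost = cfg$indirect_annual_cost,
    rebound_decline_multiplier = cfg$rebound_decline_multiplier,
    rebound_tv_tolerance = cfg$rebound_tv_tolerance
  )
  out
}

#' Run one scenario
#'
#' @param params base `dme_params` (left untouched).
#' @param spec a [scenario_spec()].
#' @return The scenario's `ce_result`.
#' @export
run_scenario <- function(params, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  run_model(apply_overrides(params, spec$overrides))
}

#' Default deterministic scenario suite
#'
#' One-way and structural scenarios mirroring the published sensitivity
#' analysis: time horizons, extrapolation approaches, dosing taken from a
#' PRN loading-phase schedule (3 aflibercept / 2 dexamethasone injections),
#' starting ages, cohorts starting entirely in each single visual-acuity
#' state, the standard-gamble utility set, 0%/5% discounting, a one-year
#' cycle length (matrices re-aggregated with the rate transformation), and
#' inclusion of indirect informal-care costs.
#'
#' @param params base `dme_params`; arm names are read from it.
#' @return Named list of [scenario_spec()]s (first entry = reference case).
#' @export
default_scenario_suite <- function(params = default_parameters()) {
  arms <- names(params$arms)
  one_hot <- function(i) replace(rep(0, N_VA_STATES), i, 1)
  specs <- list(
    scenario_spec("reference", list(), "reference case"),
    scenario_spec("one_year_horizon", list(
      "config.horizon" = "fixed", "config.horizon_years" = 1,
      "config.extrapolation" = "none"
    ), "trial duration only"),
    scenario_spec("two_year_horizon", list(
      "config.horizon" = "fixed", "config.horizon_years" = 2,
      "config.extrapolation" = "none"
    ), "no extrapolation beyond two years"),
    scenario_spec("one_time_benefit", list("config.extrapolation" = "one_time_benefit"),
      "treatment stops after one year, common decline thereafter"
    ),
    scenario_spec("rebound", list("config.extrapolation" = "rebound"),
      "benefit erodes until catch-up with the reference trajectory"
    ),
    scenario_spec("pronto_injections", stats::setNames(
      list(3, 2),
      paste0("arms.", arms, ".injections_per_year")
    ), "loading-phase dosing: 3 reference-arm and 2 intervention-arm injections/yr"),
    scenario_spec("starting_age_58", list("config.starting_age_years" = 58)),
    scenario_spec("starting_age_90", list("config.starting_age_years" = 90)),
    scenario_spec("utilities_standard_gamble", list("config.utility_method" = "sg")),
    scenario_spec("discount_0pct", list("config.discount_rate_per_year" = 0)),
    scenario_spec("discount_5pct", list("config.discount_rate_per_year" = 0.05)),
    scenario_spec("one_year_cycle", list("config.cycle_length_years" = 1),
      "annual cycles; per-cycle probabilities re-aggregated"
    ),
    scenario_spec("indirect_costs", list("config.include_indirect_costs" = TRUE),
      "adds annual informal-care cost to both arms"
    )
  )
  start_specs <- lapply(seq_len(N_VA_STATES), function(i) {
    scenario_spec(
      paste0("start_state_", i),
      list("config.starting_distribution" = one_hot(i)),
      paste("whole cohort starts in state", va_states()[i])
    )
  })
  specs <- c(specs, start_specs)
  stats::setNames(specs, vapply(specs, `[[`, character(1), "name"))
}

#' Run a scenario suite
#'
#' @param params base `dme_params`.
#' @param suite list of [scenario_spec()]s.
#' @return Data frame with one row per scenario: per-arm discounted totals,
#'   increments, `icer` (NA under dominance), signed `ratio`, and the
#'   dominance label.
#' @export
run_scenario_suite <- function(params, suite = default_scenario_suite(params)) {
  rows <- lapply(suite, function(spec) {
    res <- run_scenario(params, spec)
    data.frame(
      scenario = spec$name,
      cost_ref = res$arms$cost[1], qaly_ref = res$arms$qaly[1],
      cost_int = res$arms$cost[2], qaly_int = res$arms$qaly[2],
      delta_cost = res$delta_cost, delta_qaly = res$delta_qaly,
      icer = res$icer, ratio = res$ratio,
      dominance = ifelse(is.na(res$dominance), "", res$dominance)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired low/high scenarios for a tornado analysis
#'
#' @param name parameter name shared by the pair.
#' @param low,high [scenario_spec()]s for the two settings.
#' @return A `tornado_pair`.
#' @export
tornado_pair <- function(name, low, high) {
  structure(list(name = name, low = low, high = high), class = "tornado_pair")
}

#' One-way tornado analysis
#'
#' Runs each pair's low and high scenario and reports the signed
#' cost-per-QALY ratio on each side together with the spread
#' `width = |high - low|`, sorted by descending width. The signed ratio is
#' used (rather than the ICER, which is suppressed under dominance) so that
#' widths remain defined whichever quadrant a side lands in.
#'
#' @param params base `dme_params`.
#' @param pairs list of [tornado_pair()]s.
#' @return Data frame `parameter`, `ratio_low`, `ratio_high`, `width`,
#'   sorted by descending `width`.
#' @export
tornado <- function(params, pairs = default_tornado_pairs(params)) {
  rows <- lapply(pairs, function(p) {
    stopifnot(inherits(p, "tornado_pair"))
    lo <- run_scenario(params, p$low)
    hi <- run_scenario(params, p$high)
    data.frame(
      parameter = p$name,
      ratio_low = lo$ratio, ratio_high = hi$ratio,
      width = abs(hi$ratio - lo$ratio)
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  out
}

#' Default tornado pairs
#'
#' The drivers examined one at a time: time horizon (2 years vs lifetime),
#' extrapolation approach (one-time benefit vs continuous), per-year
#' injections of each drug (loading-phase count vs reference count),
#' discount rate (0% vs 5%), utility elicitation method, and starting age.
#'
#' @param params base `dme_params`.
#' @return Named list of [tornado_pair()]s.
#' @export
default_tornado_pairs <- function(params = default_parameters()) {
  arms <- names(params$arms)
  base <- function(name) scenario_spec(paste0(name, "_base"), list())
  list(
    horizon = tornado_pair(
      "time_horizon",
      scenario_spec("horizon_2y", list(
        "config.horizon" = "fixed", "config.horizon_years" = 2,
        "config.extrapolation" = "none"
      )),
      base("horizon_lifetime")
    ),
    extrapolation = tornado_pair(
      "extrapolation",
      scenario_spec("one_time_benefit", list("config.extrapolation" = "one_time_benefit")),
      base("continuous")
    ),
    ref_injections = tornado_pair(
      paste0(arms[1], "_injections_per_year"),
      scenario_spec("ref_inj_low", stats::setNames(list(3), paste0("arms.", arms[1], ".injections_per_year"))),
      base("ref_inj")
    ),
    int_injections = tornado_pair(
      paste0(arms[2], "_injections_per_year"),
      scenario_spec("int_inj_low", stats::setNames(list(2), paste0("arms.", arms[2], ".injections_per_year"))),
      base("int_inj")
    ),
    discount = tornado_pair(
      "discount_rate",
      scenario_spec("discount_0", list("config.discount_rate_per_year" = 0)),
      scenario_spec("discount_5", list("config.discount_rate_per_year" = 0.05))
    ),
    utility_method = tornado_pair(
      "utility_method",
      base("tto"),
      scenario_spec("sg", list("config.utility_method" = "sg"))
    ),
    starting_age = tornado_pair(
      "starting_age",
      scenario_spec("age_58", list("config.starting_age_years" = 58)),
      scenario_spec("age_90", list("config.starting_age_years" = 90))
    )
  )
}
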