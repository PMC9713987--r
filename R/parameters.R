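#' Construct a per-cycle visual-acuity transition matrix
#'
#' A 5x5 row-stochastic matrix of per-cycle probabilities over the five
#' visual-acuity states (death is handled separately by
#' [embed_mortality()]). Structurally, movement is restricted to a band:
#' one-step improvement, staying put, and one- or two-step worsening, which
#' is the pattern reported for both drugs.
#'
#' @param entries 5x5 numeric matrix (or coercible), rows = current state,
#'   columns = next state, ordered as [va_states()].
#' @param arm_label optional text label for the treatment arm.
#' @param cycle_length_years period the probabilities refer to (default 0.25,
#'   i.e. 3 months).
#' @return A `transition_matrix` object (a matrix with attributes).
#' @seealso [validate_transition_matrix()], [rescale_transition_matrix()]
#' @export
transition_matrix <- function(entries, arm_label = "", cycle_length_years = 0.25) {
  m <- as.matrix(entries)
  if (!is.numeric(m) || !all(dim(m) == c(N_VA_STATES, N_VA_STATES))) {
    stop("transition matrix must be a numeric 5x5 matrix", call. = FALSE)
  }
  dimnames(m) <- list(va_states(), va_states())
  attr(m, "arm_label") <- arm_label
  attr(m, "cycle_length_years") <- cycle_length_years
  class(m) <- c("transition_matrix", class(m))
  violations <- validate_transition_matrix(m)
  if (length(violations)) {
    stop("invalid transition matrix", if (nzchar(arm_label)) paste0(" (", arm_label, ")"),
      ":\n  - ", paste(violations, collapse = "\n  - "),
      call. = FALSE
    )
  }
  m
}

#' Validate a transition matrix
#'
#' Checks that every entry lies in \[0, 1\] and that every row sums to 1
#' within `tol`. Returns a character vector of human-readable violations
#' (empty when the matrix is valid) rather than raising an error, so callers
#' can aggregate messages.
#'
#' @param m numeric 5x5 matrix.
#' @param tol row-sum tolerance (default `1e-9`).
#' @return Character vector of violations; `character(0)` if valid.
#' @examples
#' m <- diag(5)
#' validate_transition_matrix(m) # character(0): an absorbing chain is valid
#' @export
validate_transition_matrix <- function(m, tol = 1e-9) {
  out <- character(0)
  if (!is.numeric(m) || is.null(dim(m)) || !all(dim(m) == c(N_VA_STATES, N_VA_STATES))) {
    return("matrix must be numeric 5x5")
  }
  bad <- which(m < 0 | m > 1, arr.ind = TRUE)
  if (nrow(bad)) {
    out <- c(out, sprintf(
      "entry [%d,%d] = %g outside [0, 1]", bad[, 1], bad[, 2], m[bad]
    ))
  }
  sums <- rowSums(m)
  off <- which(abs(sums - 1) > tol)
  if (length(off)) {
    out <- c(out, sprintf(
      "row %d ('%s') sums to %.10f, not 1", off,
      va_states()[off], sums[off]
    ))
  }
  out
}

#' Rescale a transition matrix to a different cycle length
#'
#' Converts each off-diagonal per-cycle probability to the new period via the
#' constant-rate transformation `1 - (1 - p)^(t_to/t_from)` and sets the
#' diagonal to the row complement. This is an approximation (the exact
#' conversion is a matrix root/power), adequate for the sparse banded
#' matrices used here; if a diagonal would go negative the row is
#' renormalised with a warning.
#'
#' @param m a [transition_matrix()].
#' @param t_from,t_to cycle lengths in years.
#' @return A `transition_matrix` at cycle length `t_to`.
#' @export
rescale_transition_matrix <- function(m, t_from, t_to) {
  stopifnot(t_from > 0, t_to > 0)
  if (t_from == t_to) {
    return(m)
  }
  expo <- t_to / t_from
  out <- unclass(m)
  for (i in seq_len(N_VA_STATES)) {
    off <- setdiff(seq_len(N_VA_STATES), i)
    out[i, off] <- 1 - (1 - out[i, off])^expo
    d <- 1 - sum(out[i, off])
    if (d < 0) {
      warning(sprintf("row %d renormalised while rescaling cycle length", i))
      out[i, i] <- 0
      out[i, ] <- out[i, ] / sum(out[i, ])
    } else {
      out[i, i] <- d
    }
  }
  transition_matrix(out,
    arm_label = attr(m, "arm_label") %||% "",
    cycle_length_years = t_to
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Utility weights by visual-acuity state
#'
#' Builds the preference-weight table used to convert time in each
#' visual-acuity state into QALYs. Two elicitation methods are carried
#' side by side: time trade-off (`"tto"`) and standard gamble (`"sg"`).
#' Death has utility exactly 0. Means must lie within their reported ranges;
#' the standard-gamble upper range for the worst state exceeds 1 as reported,
#' but probabilistic draws are clipped at 1 (utilities above perfect health
#' are not meaningful in QALY arithmetic).
#'
#' @param tto,sg data frames with columns `state`, `mean`, `low`, `high`
#'   (five rows each, ordered as [va_states()]).
#' @return A `utility_table` data frame with columns
#'   `method`, `state`, `mean`, `low`, `high`.
#' @export
utility_table <- function(tto, sg) {
  build <- function(df, method) {
    df <- as.data.frame(df)
    need <- c("state", "mean", "low", "high")
    if (!all(need %in% names(df)) || nrow(df) != N_VA_STATES) {
      stop("utility table for '", method, "' needs columns ",
        paste(need, collapse = ", "), " and one row per visual-acuity state",
        call. = FALSE
      )
    }
    if (!identical(as.character(df$state), va_states())) {
      stop("utility table for '", method, "' must list states in the fixed order: ",
        paste(va_states(), collapse = ", "),
        call. = FALSE
      )
    }
    bad <- df$mean < df$low | df$mean > df$high
    if (any(bad)) {
      stop("utility mean outside its range for state(s): ",
        paste(df$state[bad], collapse = ", "),
        call. = FALSE
      )
    }
    if (any(df$mean < 0 | df$mean > 1)) {
      stop("utility means must lie in [0, 1]", call. = FALSE)
    }
    cbind(method = method, df[need])
  }
  out <- rbind(build(tto, "tto"), build(sg, "sg"))
  class(out) <- c("utility_table", class(out))
  out
}

#' Extract the utility vector for one elicitation method
#'
#' @param params a `dme_params` parameter set (or a `utility_table`).
#' @param method `"tto"` or `"sg"`.
#' @param include_death append the death utility (exactly 0).
#' @return Named numeric vector of state utilities.
#' @export
state_utilities <- function(params, method = c("tto", "sg"), include_death = FALSE) {
  method <- match.arg(method)
  ut <- if (inherits(params, "utility_table")) params else params$utilities
  u <- ut$mean[ut$method == method]
  names(u) <- ut$state[ut$method == method]
  if (include_death) u <- c(u, death = 0)
  u
}

# ---- arm parameters ------------------------------------------------------

new_arm <- function(name, transition, drug_name, drug_unit_cost, drug_unit_cost_sd,
                    injections_per_year, resource_use, adverse_events,
                    rehabilitation_cost_per_year, equipment_cost_per_year,
                    other_annual_cost) {
  stopifnot(injections_per_year > 0, drug_unit_cost > 0)
  ru <- as.data.frame(resource_use)
  if (any(ru$unit_cost <= 0)) stop("resource-use unit costs must be positive", call. = FALSE)
  if (any(ru$per_year_low > ru$per_year_mean | ru$per_year_mean > ru$per_year_high)) {
    stop("resource-use ranges must satisfy low <= mean <= high for arm '", name, "'",
      call. = FALSE
    )
  }
  ae <- as.data.frame(adverse_events)
  if (any(ae$annual_rate < 0 | ae$annual_rate > 1)) {
    stop("adverse-event annual rates must lie in [0, 1] for arm '", name, "'", call. = FALSE)
  }
  structure(
    list(
      name = name,
      transition = transition,
      drug_name = drug_name,
      drug_unit_cost = drug_unit_cost,
      drug_unit_cost_sd = drug_unit_cost_sd,
      injections_per_year = injections_per_year,
      resource_use = ru,
      adverse_events = ae,
      rehabilitation_cost_per_year = rehabilitation_cost_per_year,
      equipment_cost_per_year = equipment_cost_per_year,
      other_annual_cost = other_annual_cost
    ),
    class = "dme_arm"
  )
}

# ---- model configuration -------------------------------------------------

#' Model configuration
#'
#' Run-level settings for the cohort engine. Defaults correspond to the
#' reference case: 3-month cycles, 3.5%/year discounting of both costs and
#' QALYs, cohort starting age 68.1 years, lifetime horizon, time-trade-off
#' utilities, continuous-treatment-effect extrapolation, no half-cycle
#' correction, indirect costs excluded.
#'
#' @param cycle_length_years cycle length t in years (0 < t <= 1).
#' @param discount_rate_per_year annual discount rate d (>= 0), applied as
#'   `(1 + d)^(-t_k)` at cycle start times.
#' @param starting_age_years cohort age at model start.
#' @param horizon `"lifetime"` or `"fixed"`.
#' @param horizon_years horizon length in years when `horizon = "fixed"`.
#' @param starting_distribution probability 5-vector over the visual-acuity
#'   states at treatment initiation (sums to 1).
#' @param starting_distribution_source free-text provenance note; the
#'   bundled value is a synthetic placeholder, not a published distribution.
#' @param utility_method `"tto"` or `"sg"`.
#' @param extrapolation post-first-year treatment-effect assumption:
#'   `"continuous"`, `"one_time_benefit"`, `"rebound"`, or `"none"`
#'   (`"none"` keeps first-year dynamics and is meant for short fixed
#'   horizons; it behaves like `"continuous"`).
#' @param half_cycle_correction average adjacent-cycle occupancies when
#'   accruing costs/QALYs (trapezoid rule).
#' @param include_indirect_costs add `indirect_annual_cost` (informal-care
#'   time) to both arms.
#' @param indirect_annual_cost annual indirect cost in 2020 euros.
#' @param rebound_decline_multiplier decline-probability multiplier applied
#'   to the better arm after year 1 under `"rebound"` until catch-up.
#' @param rebound_tv_tolerance total-variation distance (on the
#'   conditional-on-alive state distribution) below which the rebound arm is
#'   considered caught up.
#' @return A `model_config` list.
#' @export
model_config <- function(cycle_length_years = 0.25,
                         discount_rate_per_year = 0.035,
                         starting_age_years = 68.1,
                         horizon = c("lifetime", "fixed"),
                         horizon_years = NULL,
                         starting_distribution = c(0.25, 0.35, 0.25, 0.10, 0.05),
                         starting_distribution_source = "synthetic placeholder",
                         utility_method = c("tto", "sg"),
                         extrapolation = c("continuous", "one_time_benefit", "rebound", "none"),
                         half_cycle_correction = FALSE,
                         include_indirect_costs = FALSE,
                         indirect_annual_cost = 2000,
                         rebound_decline_multiplier = 2,
                         rebound_tv_tolerance = 0.01) {
  horizon <- match.arg(horizon)
  utility_method <- match.arg(utility_method)
  extrapolation <- match.arg(extrapolation)
  if (!(cycle_length_years > 0 && cycle_length_years <= 1)) {
    stop("cycle_length_years must lie in (0, 1]", call. = FALSE)
  }
  if (discount_rate_per_year < 0) stop("discount rate must be >= 0", call. = FALSE)
  sd0 <- as.numeric(starting_distribution)
  if (length(sd0) != N_VA_STATES || any(sd0 < 0) || abs(sum(sd0) - 1) > 1e-9) {
    stop("starting_distribution must be 5 nonnegative values summing to 1 (within 1e-9)",
      call. = FALSE
    )
  }
  if (horizon == "fixed" && (is.null(horizon_years) || horizon_years <= 0)) {
    stop("horizon_years must be a positive number when horizon = 'fixed'", call. = FALSE)
  }
  structure(
    list(
      cycle_length_years = cycle_length_years,
      discount_rate_per_year = discount_rate_per_year,
      starting_age_years = starting_age_years,
      horizon = horizon,
      horizon_years = if (horizon == "fixed") horizon_years else NULL,
      starting_distribution = sd0,
      starting_distribution_source = starting_distribution_source,
      utility_method = utility_method,
      extrapolation = extrapolation,
      half_cycle_correction = isTRUE(half_cycle_correction),
      include_indirect_costs = isTRUE(include_indirect_costs),
      indirect_annual_cost = indirect_annual_cost,
      rebound_decline_multiplier = rebound_decline_multiplier,
      rebound_tv_tolerance = rebound_tv_tolerance
    ),
    class = "model_config"
  )
}

# ---- life tables ---------------------------------------------------------

#' Read / write an annual life table
#'
#' A life table maps integer age to the annual probability of death `qx`.
#' The file format is a two-column CSV with header `age,qx`. Ages must be
#' consecutive integers and the final age must have `qx = 1` (the engine
#' treats ages beyond the table as certain death within the year).
#'
#' @param path CSV file path.
#' @return A `life_table` data frame with columns `age` and `qx`.
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("age", "qx") %in% names(df))) {
    stop("life table CSV must have columns 'age' and 'qx': ", path, call. = FALSE)
  }
  as_life_table(df, source = path)
}

#' @rdname read_life_table
#' @param life a `life_table`.
#' @export
write_life_table <- function(life, path) {
  utils::write.csv(data.frame(age = life$age, qx = life$qx), path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

as_life_table <- function(df, source = "user") {
  df <- as.data.frame(df)[c("age", "qx")]
  if (any(df$qx < 0 | df$qx > 1)) stop("life-table qx values must lie in [0, 1]", call. = FALSE)
  if (any(diff(df$age) != 1)) stop("life-table ages must be consecutive integers", call. = FALSE)
  if (df$qx[nrow(df)] != 1) {
    stop("life table must end with qx = 1 at its maximum age", call. = FALSE)
  }
  structure(df, class = c("life_table", "data.frame"), source = source)
}

#' Annual death probability at a given age
#'
#' Looks up `qx` at `floor(age)`; ages beyond the table's last age return 1.
#'
#' @param life a `life_table`.
#' @param age age in years (possibly fractional).
#' @return Annual death probability in \[0, 1\].
#' @export
qx_at <- function(life, age) {
  a <- floor(age)
  out <- life$qx[match(a, life$age)]
  out[a > max(life$age)] <- 1
  if (anyNA(out)) {
    stop("age ", paste(a[is.na(out)], collapse = ", "),
      " below the life table's first age (", min(life$age), ")",
      call. = FALSE
    )
  }
  out
}

# ---- parameter-set assembly and file I/O ---------------------------------

need_field <- function(x, field, where) {
  if (is.null(x[[field]])) {
    stop("parameter file is missing field '", field, "' in ", where, call. = FALSE)
  }
  x[[field]]
}

parse_arm <- function(raw, name, cycle_length) {
  tm <- need_field(raw, "transition_matrix", paste0("arms.", name))
  m <- do.call(rbind, tm)
  ru <- do.call(rbind, lapply(need_field(raw, "resource_use", paste0("arms.", name)), function(r) {
    data.frame(
      name = need_field(r, "name", "resource_use"),
      unit_cost = need_field(r, "unit_cost_euros_2020", r$name),
      unit_cost_sd = need_field(r, "unit_cost_sd", r$name),
      per_year_mean = need_field(r, "per_year_mean", r$name),
      per_year_low = need_field(r, "per_year_low", r$name),
      per_year_high = need_field(r, "per_year_high", r$name)
    )
  }))
  ae <- do.call(rbind, lapply(need_field(raw, "adverse_events", paste0("arms.", name)), function(r) {
    data.frame(
      name = need_field(r, "name", "adverse_events"),
      annual_rate = need_field(r, "annual_rate", r$name),
      unit_cost = need_field(r, "unit_cost_euros_2020", r$name),
      unit_cost_sd = need_field(r, "unit_cost_sd", r$name)
    )
  }))
  drug <- need_field(raw, "drug", paste0("arms.", name))
  new_arm(
    name = name,
    transition = transition_matrix(m, arm_label = name, cycle_length_years = cycle_length),
    drug_name = need_field(drug, "name", "drug"),
    drug_unit_cost = need_field(drug, "unit_cost_euros_2020", "drug"),
    drug_unit_cost_sd = need_field(drug, "unit_cost_sd", "drug"),
    injections_per_year = need_field(drug, "injections_per_year", "drug"),
    resource_use = ru,
    adverse_events = ae,
    rehabilitation_cost_per_year = need_field(raw, "rehabilitation_cost_per_year", name),
    equipment_cost_per_year = need_field(raw, "equipment_cost_per_year", name),
    other_annual_cost = need_field(raw, "other_annual_cost_euros_2020", name)
  )
}

parse_utilities <- function(raw) {
  one <- function(rows) {
    do.call(rbind, lapply(rows, function(r) {
      data.frame(
        state = need_field(r, "state", "utilities"),
        mean = need_field(r, "mean", r$state),
        low = need_field(r, "low", r$state),
        high = need_field(r, "high", r$state)
      )
    }))
  }
  utility_table(
    tto = one(need_field(raw, "time_trade_off", "utilities")),
    sg = one(need_field(raw, "standard_gamble", "utilities"))
  )
}

parse_life_table <- function(raw, base_dir) {
  src <- need_field(raw, "source", "life_table")
  if (src == "synthetic_gompertz_makeham") {
    lt <- make_life_table(
      a = need_field(raw, "gompertz_a_per_year", "life_table"),
      b = need_field(raw, "gompertz_b_per_year_age", "life_table"),
      c = raw$makeham_c_per_year %||% 0,
      min_age = raw$min_age_years %||% 40,
      max_age = raw$max_age_years %||% 100
    )
    attr(lt, "spec") <- raw
    lt
  } else if (src == "csv") {
    lt <- read_life_table(file.path(base_dir, need_field(raw, "file", "life_table")))
    attr(lt, "spec") <- raw
    lt
  } else if (src == "inline") {
    lt <- as_life_table(
      data.frame(
        age = vapply(raw$table, `[[`, numeric(1), "age"),
        qx = vapply(raw$table, `[[`, numeric(1), "qx")
      ),
      source = "inline"
    )
    attr(lt, "spec") <- raw
    lt
  } else {
    stop("unknown life_table source '", src, "'", call. = FALSE)
  }
}

#' Load a full model parameter set
#'
#' Reads a structured-text (YAML) parameter file and returns a fully
#' validated parameter set: two treatment arms (transition matrix, drug and
#' monitoring costs, adverse events), the utility table, shared cost figures,
#' a life table (synthetic Gompertz-Makeham spec, external CSV reference, or
#' inline), and the run configuration. Any schema violation raises an error
#' naming the offending field; an invalid transition matrix raises an error
#' naming the row.
#'
#' The first arm listed in the file is treated as the reference strategy
#' (comparator) throughout the package; the second is the intervention.
#'
#' @param path parameter file path.
#' @param quiet suppress provenance notes about synthetic placeholder inputs.
#' @return A `dme_params` list with elements `arms`, `utilities`, `shared`,
#'   `life_table`, `config`.
#' @seealso [default_parameters()], [write_parameters()]
#' @export
load_parameters <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  tcl <- raw$transition_cycle_length_years %||% 0.25
  arms_raw <- need_field(raw, "arms", "top level")
  if (length(arms_raw) != 2) stop("exactly two treatment arms are required", call. = FALSE)
  arms <- lapply(names(arms_raw), function(nm) parse_arm(arms_raw[[nm]], nm, tcl))
  names(arms) <- names(arms_raw)

  shared_raw <- need_field(raw, "shared_costs", "top level")
  shared <- list(
    comorbidity_annual_cost = need_field(shared_raw, "comorbidity_annual_cost_euros_2020", "shared_costs"),
    nonmedical_annual_cost = need_field(shared_raw, "nonmedical_annual_cost_euros_2020", "shared_costs"),
    other_cost_interpretation = match.arg(
      need_field(shared_raw, "other_cost_interpretation", "shared_costs"),
      c("category", "arm")
    )
  )

  cfg_raw <- need_field(raw, "config", "top level")
  sd_raw <- need_field(cfg_raw, "starting_distribution", "config")
  config <- model_config(
    cycle_length_years = need_field(cfg_raw, "cycle_length_years", "config"),
    discount_rate_per_year = need_field(cfg_raw, "discount_rate_per_year", "config"),
    starting_age_years = need_field(cfg_raw, "starting_age_years", "config"),
    horizon = need_field(cfg_raw, "horizon", "config"),
    horizon_years = cfg_raw$horizon_years,
    starting_distribution = unlist(need_field(sd_raw, "values", "starting_distribution")),
    starting_distribution_source = need_field(sd_raw, "source", "starting_distribution"),
    utility_method = need_field(cfg_raw, "utility_method", "config"),
    extrapolation = need_field(cfg_raw, "extrapolation", "config"),
    half_cycle_correction = cfg_raw$half_cycle_correction %||% FALSE,
    include_indirect_costs = cfg_raw$include_indirect_costs %||% FALSE,
    indirect_annual_cost = cfg_raw$indirect_annual_cost_euros_2020 %||% 0,
    rebound_decline_multiplier = cfg_raw$rebound_decline_multiplier %||% 2,
    rebound_tv_tolerance = cfg_raw$rebound_tv_tolerance %||% 0.01
  )

  life <- parse_life_table(need_field(raw, "life_table", "top level"), dirname(path))

  params <- structure(
    list(
      arms = arms,
      utilities = parse_utilities(need_field(raw, "utilities", "top level")),
      shared = shared,
      life_table = life,
      config = config,
      transition_cycle_length_years = tcl
    ),
    class = "dme_params"
  )
  if (!quiet) {
    if (grepl("synthetic", config$starting_distribution_source)) {
      message(
        "Note: starting visual-acuity distribution is a synthetic placeholder (",
        paste(format(config$starting_distribution), collapse = ", "),
        "); supply your own for real analyses."
      )
    }
    if (identical(attr(life, "spec")$source, "synthetic_gompertz_makeham")) {
      message("Note: background mortality uses a synthetic Gompertz-Makeham life table, not national data.")
    }
  }
  params
}

#' Bundled reference parameter set
#'
#' Loads the parameter file shipped with the package, which transcribes the
#' published model inputs (per-arm 3-month transition matrices, utilities by
#' elicitation method, unit costs and resource use, adverse-event rates,
#' shared annual comorbidity and non-medical costs) together with clearly
#' labelled synthetic stand-ins for the two inputs that were never published:
#' the starting visual-acuity distribution and the national life table.
#'
#' @inheritParams load_parameters
#' @return A `dme_params` parameter set.
#' @export
default_parameters <- function(quiet = TRUE) {
  load_parameters(
    system.file("extdata", "dme_parameters.yaml", package = "dmecea", mustWork = TRUE),
    quiet = quiet
  )
}

matrix_to_rows <- function(m) {
  lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
}

arm_to_raw <- function(arm) {
  list(
    drug = list(
      name = arm$drug_name,
      unit_cost_euros_2020 = arm$drug_unit_cost,
      unit_cost_sd = arm$drug_unit_cost_sd,
      injections_per_year = arm$injections_per_year
    ),
    transition_matrix = matrix_to_rows(arm$transition),
    resource_use = lapply(seq_len(nrow(arm$resource_use)), function(i) {
      r <- arm$resource_use[i, ]
      list(
        name = r$name, unit_cost_euros_2020 = r$unit_cost, unit_cost_sd = r$unit_cost_sd,
        per_year_mean = r$per_year_mean, per_year_low = r$per_year_low,
        per_year_high = r$per_year_high
      )
    }),
    adverse_events = lapply(seq_len(nrow(arm$adverse_events)), function(i) {
      r <- arm$adverse_events[i, ]
      list(
        name = r$name, annual_rate = r$annual_rate,
        unit_cost_euros_2020 = r$unit_cost, unit_cost_sd = r$unit_cost_sd
      )
    }),
    rehabilitation_cost_per_year = arm$rehabilitation_cost_per_year,
    equipment_cost_per_year = arm$equipment_cost_per_year,
    other_annual_cost_euros_2020 = arm$other_annual_cost
  )
}

#' Write a parameter set back to file
#'
#' Emits the same structured-text dialect read by [load_parameters()], with
#' a fixed field order and numeric precision so output is byte-stable and
#' `write_parameters()` then [load_parameters()] round-trips every field.
#' A life table loaded from a generator spec or CSV reference is written
#' back as that spec; otherwise it is inlined.
#'
#' @param params a `dme_params` parameter set.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  ut <- params$utilities
  ut_rows <- function(method) {
    sub <- ut[ut$method == method, ]
    lapply(seq_len(nrow(sub)), function(i) {
      list(state = sub$state[i], mean = sub$mean[i], low = sub$low[i], high = sub$high[i])
    })
  }
  life_spec <- attr(params$life_table, "spec")
  if (is.null(life_spec)) {
    life_spec <- list(
      source = "inline",
      table = lapply(seq_len(nrow(params$life_table)), function(i) {
        list(age = params$life_table$age[i], qx = params$life_table$qx[i])
      })
    )
  }
  cfg <- params$config
  raw <- list(
    currency = "euros_2020",
    transition_cycle_length_years = params$transition_cycle_length_years,
    arms = lapply(params$arms, arm_to_raw),
    utilities = list(
      death_utility = 0,
      time_trade_off = ut_rows("tto"),
      standard_gamble = ut_rows("sg")
    ),
    shared_costs = list(
      comorbidity_annual_cost_euros_2020 = params$shared$comorbidity_annual_cost,
      nonmedical_annual_cost_euros_2020 = params$shared$nonmedical_annual_cost,
      other_cost_interpretation = params$shared$other_cost_interpretation
    ),
    life_table = life_spec,
    config = list(
      cycle_length_years = cfg$cycle_length_years,
      discount_rate_per_year = cfg$discount_rate_per_year,
      starting_age_years = cfg$starting_age_years,
      horizon = cfg$horizon,
      horizon_years = cfg$horizon_years,
      utility_method = cfg$utility_method,
      extrapolation = cfg$extrapolation,
      half_cycle_correction = cfg$half_cycle_correction,
      include_indirect_costs = cfg$include_indirect_costs,
      indirect_annual_cost_euros_2020 = cfg$indirect_annual_cost,
      rebound_decline_multiplier = cfg$rebound_decline_multiplier,
      rebound_tv_tolerance = cfg$rebound_tv_tolerance,
      starting_distribution = list(
        source = cfg$starting_distribution_source,
        values = as.numeric(cfg$starting_distribution)
      )
    )
  )
  raw$config <- Filter(Negate(is.null), raw$config)
  writeLines(yaml::as.yaml(raw, precision = 12), path)
  invisible(path)
}

#' Annual cost components for one arm
#'
#' Splits an arm's annual per-patient cost (2020 euros) into the
#' treatment-dependent part (drug acquisition = unit cost x injections/year,
#' monitoring visits and imaging, expected adverse-event cost = rate x unit
#' cost) and the ongoing part that continues while the patient is alive
#' regardless of treatment (vision rehabilitation, vision-enhancing
#' equipment, comorbidity + non-medical annual costs, and - when enabled -
#' indirect informal-care costs).
#'
#' How the two published "other annual cost" figures enter depends on
#' `params$shared$other_cost_interpretation`:
#' `"category"` (default) reads them as comorbidity vs non-medical totals and
#' applies their sum to both arms; `"arm"` reads them as per-arm totals and
#' applies each arm's own figure.
#'
#' @param params a `dme_params` parameter set.
#' @param arm arm name or `dme_arm` object.
#' @param config a `model_config` (defaults to `params$config`).
#' @return List with `treatment`, `ongoing`, and `total` annual euro amounts.
#' @export
annual_cost_components <- function(params, arm, config = params$config) {
  if (is.character(arm)) arm <- params$arms[[arm]]
  drug <- arm$drug_unit_cost * arm$injections_per_year
  monitoring <- sum(arm$resource_use$unit_cost * arm$resource_use$per_year_mean)
  ae <- sum(arm$adverse_events$annual_rate * arm$adverse_events$unit_cost)
  other <- if (params$shared$other_cost_interpretation == "category") {
    params$shared$comorbidity_annual_cost + params$shared$nonmedical_annual_cost
  } else {
    arm$other_annual_cost
  }
  ongoing <- arm$rehabilitation_cost_per_year + arm$equipment_cost_per_year + other +
    if (config$include_indirect_costs) config$indirect_annual_cost else 0
  list(treatment = drug + monitoring + ae, ongoing = ongoing, total = drug + monitoring + ae + ongoing)
}

#' @export
print.dme_params <- function(x, ...) {
  cat("<dme_params> cost-utility model parameter set\n")
  cat("  arms:", paste(names(x$arms), collapse = " vs "),
    "(reference =", names(x$arms)[1], ")\n"
  )
  for (nm in names(x$arms)) {
    cc <- annual_cost_components(x, nm)
    cat(sprintf(
      "    %-14s %4.1f injections/yr, annual cost %8.0f EUR (treatment %0.0f + ongoing %0.0f)\n",
      nm, x$arms[[nm]]$injections_per_year, cc$total, cc$treatment, cc$ongoing
    ))
  }
  cat(
    "  utilities:", x$config$utility_method, "| discount",
    sprintf("%.1f%%/yr", 100 * x$config$discount_rate_per_year),
    "| cycle", x$config$cycle_length_years, "yr | horizon", x$config$horizon, "\n"
  )
  cat(
    "  life table:", attr(x$life_table, "source") %||% "user", "ages",
    min(x$life_table$age), "-", max(x$life_table$age), "\n"
  )
  invisible(x)
}
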