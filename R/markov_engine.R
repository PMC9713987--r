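#' Convert an annual probability to a per-cycle probability
#'
#' Uses the constant-rate transformation `p_cycle = 1 - e^(-r t)` with
#' `r = -log(1 - p_annual)`, i.e. `1 - (1 - p_annual)^t`. Four quarter-year
#' cycles compose back to the annual probability exactly.
#'
#' @param p_annual annual probability in \[0, 1\] (1 maps to 1: certain
#'   within the year implies certain within any positive cycle under a
#'   constant rate, the documented edge case).
#' @param t cycle length in years (> 0).
#' @return Per-cycle probability.
#' @examples
#' annual_prob_to_cycle_prob(0.3, 0.25)
#' @export
annual_prob_to_cycle_prob <- function(p_annual, t) {
  if (any(t <= 0)) stop("cycle length t must be positive", call. = FALSE)
  if (any(p_annual < 0 | p_annual > 1)) {
    stop("annual probability must lie in [0, 1]", call. = FALSE)
  }
  1 - (1 - p_annual)^t
}

#' @rdname annual_prob_to_cycle_prob
#' @param p_cycle per-cycle probability in \[0, 1\].
#' @export
cycle_prob_to_annual_prob <- function(p_cycle, t) {
  if (any(t <= 0)) stop("cycle length t must be positive", call. = FALSE)
  if (any(p_cycle < 0 | p_cycle > 1)) {
    stop("cycle probability must lie in [0, 1]", call. = FALSE)
  }
  1 - (1 - p_cycle)^(1 / t)
}

#' Discount factor at a point in time
#'
#' Annual-equivalent compounding: `(1 + d)^(-t)`. The engine applies it at
#' cycle start times `k * t`.
#'
#' @param t_years time in years (>= 0).
#' @param d annual discount rate (>= 0).
#' @return Dimensionless factor in (0, 1\].
#' @export
discount_factor <- function(t_years, d) {
  if (any(t_years < 0)) stop("time must be nonnegative", call. = FALSE)
  if (d < 0) stop("discount rate must be nonnegative", call. = FALSE)
  (1 + d)^(-t_years)
}

#' Embed background mortality into a visual-acuity transition matrix
#'
#' Expands a 5x5 visual-acuity matrix to the full 6x6 per-cycle matrix by
#' competing mortality first: each living row is scaled by the cycle
#' survival `1 - q_cycle` and `q_cycle` is placed in the death column; the
#' death row is absorbing. The result is row-stochastic by construction.
#'
#' @param m a valid 5x5 [transition_matrix()].
#' @param q_cycle per-cycle death probability in \[0, 1\].
#' @return 6x6 numeric matrix (5 visual-acuity states + death).
#' @export
embed_mortality <- function(m, q_cycle) {
  violations <- validate_transition_matrix(m)
  if (length(violations)) {
    stop("invalid transition matrix:\n  - ", paste(violations, collapse = "\n  - "),
      call. = FALSE
    )
  }
  if (q_cycle < 0 || q_cycle > 1) stop("q_cycle must lie in [0, 1]", call. = FALSE)
  embed_mortality_fast(unclass(m), q_cycle)
}

# no-validation version for inner loops (matrix validated once upstream)
embed_mortality_fast <- function(m, q_cycle) {
  out <- matrix(0, DEATH_INDEX, DEATH_INDEX)
  out[1:N_VA_STATES, 1:N_VA_STATES] <- m * (1 - q_cycle)
  out[1:N_VA_STATES, DEATH_INDEX] <- q_cycle
  out[DEATH_INDEX, DEATH_INDEX] <- 1
  out
}

# total-variation distance between two conditional-on-alive VA distributions
tv_alive <- function(s1, s2) {
  a1 <- sum(s1[1:N_VA_STATES])
  a2 <- sum(s2[1:N_VA_STATES])
  if (a1 <= 0 || a2 <= 0) {
    return(0)
  }
  0.5 * sum(abs(s1[1:N_VA_STATES] / a1 - s2[1:N_VA_STATES] / a2))
}

# mean state index (1 best .. 5 worst) conditional on being alive
severity_alive <- function(s) {
  a <- sum(s[1:N_VA_STATES])
  if (a <= 0) {
    return(0)
  }
  sum(s[1:N_VA_STATES] * seq_len(N_VA_STATES)) / a
}

# the rebound arm has caught up once its visual-acuity mix is within the
# total-variation tolerance of the reference arm's, or is no longer better
# (the accelerated decline must not push it past the reference trajectory)
rebound_caught_up <- function(s, ref_s, tol) {
  tv_alive(s, ref_s) <= tol || severity_alive(s) >= severity_alive(ref_s)
}

# maximum number of cycles for a run (absorption is guaranteed earlier by
# the terminal qx = 1, this is a hard safety cap)
max_cycles <- function(params, config) {
  t <- config$cycle_length_years
  if (config$horizon == "fixed") {
    as.integer(round(config$horizon_years / t))
  } else {
    as.integer(ceiling((max(params$life_table$age) + 2 - config$starting_age_years) / t))
  }
}

#' Run the deterministic cohort model for one arm
#'
#' Propagates the cohort occupancy vector through age-specific 6x6 cycle
#' matrices built by scaling the arm's visual-acuity matrix with the
#' life-table cycle death probability ([embed_mortality()]). Costs and QALYs
#' accrue at each cycle start from the occupancy at that time (or the
#' adjacent-cycle average when the half-cycle correction is enabled),
#' discounted at `(1 + d)^(-k t)`. A lifetime horizon runs until the cohort
#' is (numerically) fully absorbed or the life table is exhausted; a fixed
#' horizon runs `horizon_years / t` cycles. Dead occupancy accrues neither
#' cost nor utility.
#'
#' Extrapolation beyond the first treatment year follows
#' `config$extrapolation`; see [post_year1_matrix()]. Under `"rebound"`, a
#' call without `reference_trace` is treated as the reference arm
#' (common natural decline after year 1); passing the reference arm's trace
#' makes this arm the better-responding one, whose decline is accelerated
#' until its visual-acuity mix catches up with the reference.
#'
#' @param params a `dme_params` parameter set.
#' @param arm arm name (or `dme_arm`).
#' @param config a `model_config`; defaults to `params$config`.
#' @param reference_trace optional `cohort_trace` of the reference arm,
#'   required only to model the catch-up phase of `"rebound"`.
#' @return A `cohort_trace` data frame with one row per cycle: `cycle`,
#'   `time_years`, `age`, occupancies `occ1..occ5`, `occ_death`, `alive`,
#'   per-cycle `cost`, `disc_cost`, `qaly`, `disc_qaly`, and the per-person
#'   per-cycle `cost_rate`. Attributes carry the final occupancy and the
#'   cycle-matrix sequence (reused by the microsimulation oracle).
#' @export
run_cohort <- function(params, arm, config = params$config, reference_trace = NULL) {
  if (is.character(arm)) arm <- params$arms[[arm]]
  if (is.null(arm)) stop("unknown arm", call. = FALSE)
  t <- config$cycle_length_years
  d <- config$discount_rate_per_year
  hcc <- config$half_cycle_correction

  m_year1 <- arm$transition
  if (!isTRUE(all.equal(params$transition_cycle_length_years, t))) {
    m_year1 <- rescale_transition_matrix(m_year1, params$transition_cycle_length_years, t)
  }
  mode <- config$extrapolation
  m_post <- post_year1_matrix(params, arm, mode, config)
  m_catchup <- NULL
  if (mode == "rebound" && !is.null(reference_trace)) {
    m_common <- post_year1_matrix(params, arm, "one_time_benefit", config)
    m_catchup <- accelerate_decline(m_common, config$rebound_decline_multiplier)
    m_post <- m_common
  }

  u <- state_utilities(params, config$utility_method)
  costs <- annual_cost_components(params, arm, config)
  treatment_forever <- mode %in% c("continuous", "none")

  n_max <- max_cycles(params, config)
  s <- c(config$starting_distribution, 0)
  caught_up <- FALSE
  rows <- vector("list", n_max)
  mats <- vector("list", n_max)
  k <- 0L
  while (k < n_max) {
    time <- k * t
    age <- config$starting_age_years + time
    if (config$horizon == "lifetime" && s[DEATH_INDEX] >= 1 - 1e-9) break

    in_year1 <- time < 1 - 1e-12
    m_va <- if (in_year1) {
      unclass(m_year1)
    } else if (!is.null(m_catchup) && !caught_up) {
      ref_row <- min(k + 1L, nrow(reference_trace))
      ref_s <- as.numeric(reference_trace[ref_row, c(paste0("occ", 1:5), "occ_death")])
      if (rebound_caught_up(s, ref_s, config$rebound_tv_tolerance)) {
        caught_up <- TRUE
        unclass(m_post)
      } else {
        unclass(m_catchup)
      }
    } else {
      unclass(m_post)
    }

    qc <- annual_prob_to_cycle_prob(qx_at(params$life_table, age), t)
    M <- embed_mortality_fast(m_va, qc)
    s_next <- as.numeric(s %*% M)

    s_acc <- if (hcc) (s + s_next) / 2 else s
    alive <- sum(s_acc[1:N_VA_STATES])
    treat_on <- treatment_forever || in_year1
    cost_rate <- (costs$ongoing + if (treat_on) costs$treatment else 0) * t
    df <- (1 + d)^(-time)
    cost_k <- alive * cost_rate
    qaly_k <- sum(s_acc[1:N_VA_STATES] * u) * t

    k <- k + 1L
    rows[[k]] <- c(
      cycle = k - 1L, time_years = time, age = age, s[1:DEATH_INDEX],
      alive = sum(s[1:N_VA_STATES]), cost = cost_k, disc_cost = cost_k * df,
      qaly = qaly_k, disc_qaly = qaly_k * df, cost_rate = cost_rate
    )
    mats[[k]] <- M
    s <- s_next
  }
  tr <- as.data.frame(do.call(rbind, rows[seq_len(k)]))
  names(tr) <- c(
    "cycle", "time_years", "age", paste0("occ", 1:5), "occ_death",
    "alive", "cost", "disc_cost", "qaly", "disc_qaly", "cost_rate"
  )
  structure(tr,
    class = c("cohort_trace", "data.frame"),
    arm = arm$name,
    final_occupancy = s,
    cycle_matrices = mats[seq_len(k)],
    config = config
  )
}

#' Sum a cohort trace into totals
#'
#' @param trace a `cohort_trace` from [run_cohort()].
#' @return List with discounted `cost` and `qaly` totals plus their
#'   undiscounted counterparts.
#' @export
accumulate_trace <- function(trace) {
  list(
    cost = sum(trace$disc_cost),
    qaly = sum(trace$disc_qaly),
    undiscounted_cost = sum(trace$cost),
    undiscounted_qaly = sum(trace$qaly)
  )
}

#' Incremental cost-effectiveness ratio
#'
#' Computes `delta_cost = cost_new - cost_ref`, `delta_qaly = qaly_new -
#' qaly_ref`, and their ratio in euros per QALY. The ICER is reported only
#' when the two increments share a sign and `delta_qaly != 0`; otherwise the
#' comparison is labelled `"dominant"` (new strategy cheaper and more
#' effective) or `"dominated"` (costlier and less effective). A zero QALY
#' difference with a nonzero cost difference yields an undefined ICER and
#' the cost difference alone. The signed ratio `delta_cost / delta_qaly` is
#' always carried in `$ratio` for scenario tables and tornado widths.
#'
#' @param cost_ref,qaly_ref discounted totals for the reference strategy.
#' @param cost_new,qaly_new discounted totals for the new strategy.
#' @param labels optional length-2 character vector (reference, new).
#' @return A `ce_result` list.
#' @examples
#' compute_icer(92340, 4.134, 169689, 6.80)
#' @export
compute_icer <- function(cost_ref, qaly_ref, cost_new, qaly_new,
                         labels = c("reference", "intervention")) {
  stopifnot(is.finite(cost_ref), is.finite(qaly_ref), is.finite(cost_new), is.finite(qaly_new))
  dc <- cost_new - cost_ref
  dq <- qaly_new - qaly_ref
  ratio <- if (dq == 0) NA_real_ else dc / dq
  dominance <- NA_character_
  icer <- NA_real_
  if (dq == 0) {
    # undefined ICER; cost difference reported on its own
  } else if (dc < 0 && dq > 0) {
    dominance <- "dominant"
  } else if (dc > 0 && dq < 0) {
    dominance <- "dominated"
  } else {
    icer <- dc / dq
  }
  structure(
    list(
      arms = data.frame(
        arm = labels, cost = c(cost_ref, cost_new), qaly = c(qaly_ref, qaly_new)
      ),
      delta_cost = dc, delta_qaly = dq,
      icer = icer, ratio = ratio, dominance = dominance
    ),
    class = "ce_result"
  )
}

#' Run the full two-arm cost-utility comparison
#'
#' Runs the cohort engine for both arms (the first arm in `params$arms` is
#' the reference strategy) and assembles the incremental comparison. Under
#' the `"rebound"` extrapolation the reference arm is run first and its
#' trace drives the intervention arm's catch-up phase.
#'
#' @param params a `dme_params` parameter set.
#' @param config a `model_config`; defaults to `params$config`.
#' @return A `ce_result` with per-arm discounted totals, increments, ICER or
#'   dominance label, and the two cohort traces in `$traces`.
#' @export
run_model <- function(params, config = params$config) {
  arm_names <- names(params$arms)
  ref_trace <- run_cohort(params, arm_names[1], config)
  int_trace <- run_cohort(params, arm_names[2], config,
    reference_trace = if (config$extrapolation == "rebound") ref_trace
  )
  ref <- accumulate_trace(ref_trace)
  int <- accumulate_trace(int_trace)
  res <- compute_icer(ref$cost, ref$qaly, int$cost, int$qaly, labels = arm_names)
  res$traces <- stats::setNames(list(ref_trace, int_trace), arm_names)
  res
}

#' @export
print.ce_result <- function(x, ...) {
  cat("<ce_result> incremental cost-utility comparison\n")
  print(transform(x$arms,
    cost = sprintf("%.0f EUR", cost),
    qaly = sprintf("%.3f", qaly)
  ), row.names = FALSE)
  cat(sprintf(
    "  incremental: %+.0f EUR, %+.3f QALY\n", x$delta_cost, x$delta_qaly
  ))
  if (!is.na(x$dominance)) {
    cat("  ", x$arms$arm[2], " is ", x$dominance, " (ICER not reported; ratio ",
      sprintf("%.0f", x$ratio), " EUR/QALY)\n",
      sep = ""
    )
  } else if (is.na(x$icer)) {
    cat("  ICER undefined (zero QALY difference); cost difference ",
      sprintf("%+.0f EUR", x$delta_cost), "\n",
      sep = ""
    )
  } else {
    cat(sprintf("  ICER: %.0f EUR/QALY\n", x$icer))
  }
  invisible(x)
}

#' Export a cohort trace as a delimited table
#'
#' @param trace a `cohort_trace`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  out <- as.data.frame(trace)
  names(out)[match(paste0("occ", 1:5), names(out))] <- va_states()
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
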