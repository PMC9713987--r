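#' Individual-level microsimulation oracle
#'
#' Simulates `n` independent patients through exactly the same sequence of
#' age-specific 6x6 cycle matrices, per-cycle cost rates, utilities, and
#' discount factors as the cohort engine ([run_cohort()] is called
#' internally and its cycle-matrix attribute reused). Each patient starts in
#' a state drawn from the starting distribution and accrues discounted cost
#' and QALYs from the state occupied at each cycle start until death or the
#' end of the cohort run. Because the cohort trace is the exact expectation
#' of this process, the sample means converge to the cohort totals by the
#' law of large numbers; the function is the package's brute-force
#' correctness oracle for the trace arithmetic (accumulation, discounting,
#' absorption).
#'
#' Simulation is vectorised across patients cycle by cycle from a single
#' stream seeded with `seed`, so results are reproducible bit for bit.
#'
#' @param params a `dme_params` parameter set.
#' @param arm arm name.
#' @param n number of simulated patients (>= 1).
#' @param seed integer RNG seed.
#' @param config a `model_config`; defaults to `params$config`.
#' @param reference_trace passed through to [run_cohort()] for the rebound
#'   extrapolation.
#' @param states_at optional integer vector of cycle indices (0-based, as in
#'   the trace) at which to snapshot every patient's state, for comparing
#'   empirical state frequencies with cohort occupancies.
#' @return List with `mean_cost`, `mean_qaly`, their standard errors
#'   `se_cost` and `se_qaly`, `n`, `n_cycles`, and (when requested)
#'   `state_snapshots`, a list of length-`n` state vectors named by cycle.
#' @export
simulate_individuals <- function(params, arm, n, seed = 1,
                                 config = params$config, reference_trace = NULL,
                                 states_at = integer(0)) {
  stopifnot(n >= 1)
  trace <- run_cohort(params, arm, config, reference_trace)
  mats <- attr(trace, "cycle_matrices")
  u <- c(state_utilities(params, config$utility_method), 0)
  t <- config$cycle_length_years
  d <- config$discount_rate_per_year

  set.seed(seed)
  state <- sample.int(N_VA_STATES, n, replace = TRUE, prob = config$starting_distribution)
  cost_tot <- numeric(n)
  qaly_tot <- numeric(n)
  snapshots <- list()
  for (k in seq_len(nrow(trace))) {
    if ((k - 1L) %in% states_at) snapshots[[as.character(k - 1L)]] <- state
    df <- (1 + d)^(-trace$time_years[k])
    alive <- state != DEATH_INDEX
    if (!any(alive)) break
    cost_tot[alive] <- cost_tot[alive] + trace$cost_rate[k] * df
    qaly_tot[alive] <- qaly_tot[alive] + u[state[alive]] * t * df
    M <- mats[[k]]
    new_state <- state
    for (s in seq_len(N_VA_STATES)) {
      idx <- which(state == s) # from the state held at cycle start
      if (length(idx)) {
        new_state[idx] <- findInterval(stats::runif(length(idx)), cumsum(M[s, ])) + 1L
      }
    }
    state <- new_state
  }
  out <- list(
    mean_cost = mean(cost_tot),
    mean_qaly = mean(qaly_tot),
    se_cost = stats::sd(cost_tot) / sqrt(n),
    se_qaly = stats::sd(qaly_tot) / sqrt(n),
    n = n,
    n_cycles = nrow(trace)
  )
  if (length(states_at)) out$state_snapshots <- snapshots
  out
}
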