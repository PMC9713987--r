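#' Gompertz-Makeham annual death probabilities
#'
#' The hazard at age x is `c + a e^(b x)` (an age-independent Makeham term
#' plus an exponentially rising Gompertz term). Integrating over one year of
#' age gives the annual death probability
#' `q_x = 1 - exp(-(c + (a/b)(e^(b(x+1)) - e^(b x))))`; the `b -> 0` limit is
#' the constant-hazard `1 - e^(-(a + c))`.
#'
#' @param age integer age(s) in years.
#' @param a baseline Gompertz hazard at age 0 (per year, > 0).
#' @param b log-hazard slope (per year of age, >= 0).
#' @param c Makeham age-independent hazard (per year, >= 0).
#' @return Annual death probabilities in (0, 1).
#' @export
gompertz_makeham_qx <- function(age, a, b, c = 0) {
  stopifnot(a > 0, b >= 0, c >= 0)
  h <- if (b == 0) a else (a / b) * (exp(b * (age + 1)) - exp(b * age))
  1 - exp(-(c + h))
}

#' Build a synthetic annual life table
#'
#' Generates a [read_life_table()]-compatible life table from a
#' Gompertz-Makeham mortality schedule, forcing `qx = 1` at `max_age`. This
#' is a clearly labelled synthetic stand-in for a national life table; the
#' default parameters are calibrated so that remaining life expectancy at
#' age 68 is roughly 17 years, the order of magnitude of southern-European
#' population tables. Supply a real table via [read_life_table()] for
#' substantive analyses.
#'
#' @inheritParams gompertz_makeham_qx
#' @param min_age,max_age integer age range covered.
#' @return A `life_table` data frame (columns `age`, `qx`).
#' @export
make_life_table <- function(a = 1.05e-5, b = 0.105, c = 5e-4,
                            min_age = 40, max_age = 100) {
  stopifnot(min_age < max_age)
  ages <- min_age:max_age
  qx <- gompertz_makeham_qx(ages, a, b, c)
  if (any(qx[ages < max_age - 1] >= 1)) {
    stop("Gompertz-Makeham parameters give qx >= 1 before max_age - 1", call. = FALSE)
  }
  qx[length(qx)] <- 1
  lt <- as_life_table(data.frame(age = ages, qx = pmin(qx, 1)),
    source = "synthetic_gompertz_makeham"
  )
  attr(lt, "spec") <- list(
    source = "synthetic_gompertz_makeham",
    gompertz_a_per_year = a, gompertz_b_per_year_age = b,
    makeham_c_per_year = c, min_age_years = min_age, max_age_years = max_age
  )
  lt
}

#' Remaining life expectancy implied by a life table
#'
#' Discrete survival sum with a half-year correction for the death year:
#' `e_x = sum_k S(k) - 0.5` where `S` is survival from age `x`.
#'
#' @param life a `life_table`.
#' @param age starting integer age.
#' @return Expected remaining years of life.
#' @export
life_expectancy <- function(life, age) {
  q <- life$qx[life$age >= age]
  surv <- cumprod(1 - q)
  sum(surv) + 0.5
}

#' Starting visual-acuity distribution generator
#'
#' Presets: `"uniform"` (equal fifths) and `"moderate"` (the package's
#' synthetic placeholder, weighted towards the middle bands as is typical
#' for patients presenting with clinically significant macular edema). A
#' numeric 5-vector of positive concentrations instead draws a random
#' distribution by normalising independent gamma variates (a Dirichlet
#' draw), using the current RNG stream.
#'
#' @param concentration preset name or positive numeric 5-vector.
#' @return Probability 5-vector summing to 1.
#' @export
make_starting_distribution <- function(concentration = "moderate") {
  if (is.character(concentration)) {
    return(switch(concentration,
      uniform = rep(1 / N_VA_STATES, N_VA_STATES),
      moderate = c(0.25, 0.35, 0.25, 0.10, 0.05),
      stop("unknown preset '", concentration, "'", call. = FALSE)
    ))
  }
  stopifnot(length(concentration) == N_VA_STATES, all(concentration > 0))
  g <- stats::rgamma(N_VA_STATES, shape = concentration, rate = 1)
  g / sum(g)
}

# random banded VA matrix: one-step improvement, stay, one/two-step decline
random_banded_matrix <- function(improve, decline1, decline2, label) {
  m <- matrix(0, N_VA_STATES, N_VA_STATES)
  for (i in seq_len(N_VA_STATES)) {
    if (i > 1) m[i, i - 1] <- improve[i]
    if (i < N_VA_STATES) m[i, i + 1] <- decline1[i]
    if (i < N_VA_STATES - 1) m[i, i + 2] <- decline2[i]
    if (i == N_VA_STATES - 1) m[i, i + 1] <- decline1[i] + decline2[i]
    m[i, i] <- 1 - sum(m[i, -i])
  }
  transition_matrix(m, arm_label = label)
}

#' Generate a full synthetic parameter set
#'
#' Builds a random but valid two-arm model with the same structure as the
#' bundled reference set: banded transition matrices (one-step improvement,
#' one- and two-step worsening), utilities monotone nonincreasing in
#' visual-acuity severity (ties allowed), positive cost schedules, a
#' synthetic life table, and a random starting distribution. The
#' `decline_gap` knob adds a fixed per-cycle decline probability to the
#' reference arm relative to the treated arm, so larger gaps make the
#' treated arm strictly better; useful for property-based tests and
#' parameter-recovery studies. Draws come from the current RNG stream
#' (`set.seed()` before calling for reproducibility); for a fixed seed the
#' base draws are identical across different `decline_gap` values.
#'
#' @param decline_gap additional per-cycle decline probability for the
#'   reference arm (>= 0).
#' @param starting_age cohort starting age in years.
#' @return A `dme_params` parameter set with arms `reference` and `treated`.
#' @export
make_synthetic_model <- function(decline_gap = 0.02, starting_age = 68.1) {
  stopifnot(decline_gap >= 0, decline_gap <= 0.3)
  improve <- stats::runif(N_VA_STATES, 0.01, 0.12)
  decline1 <- stats::runif(N_VA_STATES, 0.01, 0.06)
  decline2 <- stats::runif(N_VA_STATES, 0.001, 0.02)
  u_means <- sort(stats::runif(N_VA_STATES, 0.4, 0.95), decreasing = TRUE)
  start <- make_starting_distribution(rep(2, N_VA_STATES))
  drug_costs <- stats::runif(2, 300, 1200)
  injections <- stats::runif(2, 2, 12)

  m_treated <- random_banded_matrix(improve, decline1, decline2, "treated")
  m_reference <- random_banded_matrix(
    improve, decline1 + decline_gap, decline2, "reference"
  )

  make_arm <- function(name, m, drug_cost, inj) {
    ru <- data.frame(
      name = c("consultation", "imaging"),
      unit_cost = c(112, 149), unit_cost_sd = c(22.4, 29.8),
      per_year_mean = c(8, 4), per_year_low = c(4, 2), per_year_high = c(12, 8)
    )
    ae <- data.frame(
      name = "endophthalmitis", annual_rate = 0.006,
      unit_cost = 3156, unit_cost_sd = 631.2
    )
    new_arm(
      name = name, transition = m, drug_name = paste0(name, "_drug"),
      drug_unit_cost = drug_cost, drug_unit_cost_sd = 0.2 * drug_cost,
      injections_per_year = inj, resource_use = ru, adverse_events = ae,
      rehabilitation_cost_per_year = 69, equipment_cost_per_year = 211,
      other_annual_cost = 1000
    )
  }

  ut <- utility_table(
    tto = data.frame(
      state = va_states(), mean = u_means,
      low = pmax(u_means - 0.1, 0), high = pmin(u_means + 0.1, 1)
    ),
    sg = data.frame(
      state = va_states(), mean = pmin(u_means + 0.05, 1),
      low = pmax(u_means - 0.05, 0), high = 1
    )
  )

  structure(
    list(
      arms = list(
        reference = make_arm("reference", m_reference, drug_costs[1], injections[1]),
        treated = make_arm("treated", m_treated, drug_costs[2], injections[2])
      ),
      utilities = ut,
      shared = list(
        comorbidity_annual_cost = 771, nonmedical_annual_cost = 1577,
        other_cost_interpretation = "category"
      ),
      life_table = make_life_table(),
      config = model_config(
        starting_age_years = starting_age,
        starting_distribution = start,
        starting_distribution_source = "synthetic draw"
      ),
      transition_cycle_length_years = 0.25
    ),
    class = "dme_params"
  )
}
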