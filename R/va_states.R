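#' Visual-acuity health states
#'
#' The model tracks vision in the better-seeing eye on the Snellen scale,
#' discretised into five bands ordered from best to worst, plus an absorbing
#' death state. The ordering is fixed: state 1 is the best band (`>20/40`),
#' state 5 the worst (`<=20/400`), and death, when included, is always last
#' (index 6).
#'
#' @param include_death logical; append the terminal `"death"` state.
#' @return Character vector of state labels.
#' @examples
#' va_states()
#' va_states(include_death = TRUE)
#' @export
va_states <- function(include_death = FALSE) {
  states <- c(
    ">20/40",
    "<=20/40 to >20/80",
    "<=20/80 to >20/200",
    "<=20/200 to >20/400",
    "<=20/400"
  )
  if (include_death) c(states, "death") else states
}

#' @rdname va_states
#' @format `N_VA_STATES` is the number of living (visual-acuity) states.
#' @export
N_VA_STATES <- 5L

#' @rdname va_states
#' @format `DEATH_INDEX` is the index of the absorbing death state in the
#'   expanded (mortality-embedded) state space.
#' @export
DEATH_INDEX <- 6L
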