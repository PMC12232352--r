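#' Per-quarter event probability
#'
#' Evaluates one complication's per-quarter probability for one or more
#' individuals: inverse-logit of the model's linear predictor plus the
#' regimen's direct log hazard-ratio effect plus the prior-event term.
#' Querying an absorbing event that has already occurred is an error (the
#' individual is no longer at risk of it).
#'
#' @param state named numeric vector or matrix of current risk-factor
#'   levels (columns [risk_factor_names()]).
#' @param profile data frame row(s) with `age`, `sex`,
#'   `years_since_diagnosis`, `cvd_history`.
#' @param regimen regimen code(s).
#' @param history per-event prior-occurrence counts: numeric vector (one
#'   count per individual) for this event; 0 = no prior event.
#' @param model an `event_model`.
#' @param quarter 0-based quarter index (time term).
#' @param registry an `effects_registry` supplying direct effects.
#' @param direct_effect optional precomputed per-individual direct log
#'   hazard-ratio effect of the regimen on this event; bypasses the
#'   registry lookup (used by the cohort runner for speed).
#' @return per-quarter probabilities in (0, 1).
#' @examples
#' m <- event_model("mi", intercept = 0, recurrent = TRUE)
#' p <- event_probability(
#'   state = setNames(rep(1, 9), risk_factor_names()),
#'   profile = data.frame(age = 60, sex = "female",
#'                        years_since_diagnosis = 5, cvd_history = FALSE),
#'   regimen = "no_therapy", history = 0, model = m, quarter = 0)
#' stopifnot(identical(p, 0.5))
#' @export
event_probability <- function(state, profile, regimen, history, model,
                              quarter = 0L,
                              registry = zero_effects_registry(),
                              direct_effect = NULL) {
  stopifnot(inherits(model, "event_model"))
  if (!is.matrix(state)) {
    state <- matrix(state, 1L, dimnames = list(NULL, names(state)))
  }
  n <- nrow(state)
  history <- rep_len(history, n)
  if (model$absorbing && any(history > 0)) {
    stop("absorbing event '", model$event,
         "' has already occurred; individual not at risk", call. = FALSE)
  }
  covars <- cbind(
    state[, intersect(names(model$coef), risk_factor_names()), drop = FALSE],
    age = profile$age,
    sex_male = as.numeric(profile$sex == "male"),
    years_since_diagnosis = profile$years_since_diagnosis,
    cvd_history = as.numeric(profile$cvd_history))
  lp <- model$intercept + model$time * quarter
  for (nm in names(model$coef)) lp <- lp + model$coef[[nm]] * covars[, nm]
  prior <- if (model$prior_mode == "indicator") as.numeric(history > 0)
           else history
  lp <- lp + model$prior_coef * prior
  if (is.null(direct_effect)) {
    direct_effect <- regimen_effect(rep_len(regimen, n), model$event,
                                    registry)
  }
  lp <- lp + direct_effect
  unname(stats::plogis(lp))
}

#' Cumulative incidence from per-quarter probabilities
#'
#' Probability of at least one event by the horizon:
#' `1 - prod(1 - p_t)` over quarters `t <= up_to_quarter`.  Nondecreasing
#' in the horizon; 0 for an empty sequence.
#'
#' @param per_quarter_probs numeric vector of per-quarter probabilities in
#'   \[0, 1\] (quarter 0 first).
#' @param up_to_quarter 0-based index of the last quarter included;
#'   defaults to the whole sequence.
#' @return a single probability.
#' @export
cumulative_incidence <- function(per_quarter_probs,
                                 up_to_quarter = length(per_quarter_probs) - 1L) {
  check_probs(per_quarter_probs)
  k <- min(up_to_quarter + 1L, length(per_quarter_probs))
  if (k <= 0L || length(per_quarter_probs) == 0L) return(0)
  1 - prod(1 - per_quarter_probs[seq_len(k)])
}

#' Expected number of events (recurrent events)
#'
#' Sum of per-quarter probabilities up to the horizon; by linearity of
#' expectation this is the expected event count when events can recur.
#'
#' @inheritParams cumulative_incidence
#' @return expected count (>= 0).
#' @export
expected_event_count <- function(per_quarter_probs,
                                 up_to_quarter = length(per_quarter_probs) - 1L) {
  check_probs(per_quarter_probs)
  k <- min(up_to_quarter + 1L, length(per_quarter_probs))
  if (k <= 0L || length(per_quarter_probs) == 0L) return(0)
  sum(per_quarter_probs[seq_len(k)])
}

check_probs <- function(p) {
  if (length(p) && (any(!is.finite(p)) || any(p < 0) || any(p > 1))) {
    stop("per-quarter probabilities must lie in [0, 1]", call. = FALSE)
  }
  invisible(p)
}
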