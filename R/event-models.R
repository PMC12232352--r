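#' Per-quarter complication event models
#'
#' Each complication is modelled on the per-quarter probability scale with
#' a logistic link: `p = plogis(lp)` where the linear predictor combines an
#' intercept, coefficients on current risk factors and baseline covariates,
#' a time term, a prior-event term for recurrent acute events (entering
#' linearly via the prior-occurrence count, or as a first-vs-any indicator
#' when `prior_mode = "indicator"`), and the regimen's direct log
#' hazard-ratio effect from the effects registry.  At small per-quarter
#' probabilities the discrete-time logistic model approximates a
#' proportional-hazards model.
#'
#' @param event one of [event_names()].
#' @param intercept intercept of the linear predictor.
#' @param coef named numeric coefficients on any of [risk_factor_names()],
#'   `age`, `sex_male`, `years_since_diagnosis`, `cvd_history`.
#' @param time coefficient on the quarter index.
#' @param prior_coef coefficient on the prior-occurrence count (recurrent
#'   events only).
#' @param prior_mode `"count"` (default) or `"indicator"`.
#' @param absorbing is the event absorbing (ESKD, death)?
#' @param recurrent can the event recur (hypoglycaemia, MI, unstable
#'   angina, stroke)?  Mutually exclusive with `absorbing`.
#' @return an `event_model`.
#' @export
event_model <- function(event, intercept, coef = numeric(0), time = 0,
                        prior_coef = 0, prior_mode = c("count", "indicator"),
                        absorbing = FALSE, recurrent = FALSE) {
  prior_mode <- match.arg(prior_mode)
  stopifnot(event %in% event_names(), is.finite(intercept),
            all(is.finite(coef)), is.finite(time), is.finite(prior_coef))
  if (absorbing && recurrent) {
    stop("an event cannot be both absorbing and recurrent", call. = FALSE)
  }
  allowed <- c(risk_factor_names(), "age", "sex_male",
               "years_since_diagnosis", "cvd_history")
  bad <- setdiff(names(coef), allowed)
  if (length(bad)) {
    stop("unknown event-model coefficient(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(event = event, intercept = intercept, coef = coef,
                 time = time, prior_coef = prior_coef,
                 prior_mode = prior_mode, absorbing = absorbing,
                 recurrent = recurrent),
            class = "event_model")
}

#' Bundle event models for all complications
#' @param ... `event_model` objects covering all of [event_names()].
#' @return a named list of class `event_models`.
#' @export
event_models <- function(...) {
  ms <- list(...)
  if (length(ms) == 1L && is.list(ms[[1]]) &&
      !inherits(ms[[1]], "event_model")) {
    ms <- ms[[1]]
  }
  names(ms) <- vapply(ms, `[[`, character(1), "event")
  missing_ev <- setdiff(event_names(), names(ms))
  if (length(missing_ev)) {
    stop("missing event model for: ", paste(missing_ev, collapse = ", "),
         call. = FALSE)
  }
  structure(ms[event_names()], class = "event_models")
}

# intercept yielding a target per-quarter probability at the reference
# profile (age 60, median risk-factor levels, no CVD, quarter 0, count 0)
reference_profile <- function() {
  c(age = 60, sex_male = 0, years_since_diagnosis = 4.9, cvd_history = 0,
    hba1c = 7.9, bmi = 31.3, sbp = 132, dbp = 79, hdl = 42.5, ldl = 81.2,
    total_cholesterol = 158.5, triglycerides = 159.4, egfr = 92)
}

solve_intercept <- function(p_quarter, coef) {
  ref <- reference_profile()
  stats::qlogis(p_quarter) - sum(coef * ref[names(coef)])
}

#' Default event-model coefficients
#'
#' Illustrative logistic models whose intercepts are solved so that a
#' reference individual (age 60, median risk-factor levels, no CVD
#' history) has 5-year cumulative incidences of roughly: eye disease 23%,
#' all-cause death 6%, ESKD 3.2% (before the SGLT2i direct effect),
#' heart-failure hospitalisation 2.8%, stroke 2%, unstable angina 1%,
#' LEA 0.63%, MI 0.52%, and a low background hypoglycaemia rate.
#' Coefficient signs follow clinical epidemiology: worse glycaemia raises
#' microvascular risk, lower eGFR raises ESKD risk, age and prior CVD
#' raise macrovascular and death risk, and prior acute events raise
#' recurrence risk.
#'
#' @return an `event_models` list.
#' @export
default_event_models <- function() {
  p5 <- function(cum5) 1 - (1 - cum5)^(1 / 20)  # 20 quarters in 5 years
  event_models(
    event_model("hypoglycaemia",
                coef = c(hba1c = -0.10),
                intercept = solve_intercept(p5(0.04), c(hba1c = -0.10)),
                prior_coef = 0.5, recurrent = TRUE),
    event_model("mi",
                coef = c(age = 0.05, cvd_history = 1.0, hba1c = 0.10,
                         sbp = 0.015),
                intercept = solve_intercept(
                  p5(0.0052),
                  c(age = 0.05, cvd_history = 0, hba1c = 0.10, sbp = 0.015)),
                prior_coef = 0.7, recurrent = TRUE),
    event_model("unstable_angina",
                coef = c(age = 0.04, cvd_history = 1.0),
                intercept = solve_intercept(p5(0.010), c(age = 0.04)),
                prior_coef = 0.7, recurrent = TRUE),
    event_model("stroke",
                coef = c(age = 0.06, sbp = 0.02, cvd_history = 0.8),
                intercept = solve_intercept(p5(0.020),
                                            c(age = 0.06, sbp = 0.02)),
                prior_coef = 0.7, recurrent = TRUE),
    event_model("hf_hospitalisation",
                coef = c(age = 0.05, bmi = 0.03, cvd_history = 1.0),
                intercept = solve_intercept(p5(0.028),
                                            c(age = 0.05, bmi = 0.03))),
    event_model("lea",
                coef = c(hba1c = 0.15, egfr = -0.01),
                intercept = solve_intercept(
                  p5(0.0063), c(hba1c = 0.15, egfr = -0.01))),
    event_model("eskd",
                coef = c(egfr = -0.06, hba1c = 0.10, sbp = 0.01),
                intercept = solve_intercept(
                  p5(0.032), c(egfr = -0.06, hba1c = 0.10, sbp = 0.01)),
                absorbing = TRUE),
    event_model("eye_disease",
                coef = c(hba1c = 0.25, years_since_diagnosis = 0.02),
                intercept = solve_intercept(
                  p5(0.23),
                  c(hba1c = 0.25, years_since_diagnosis = 0.02))),
    event_model("all_cause_death",
                coef = c(age = 0.09, cvd_history = 0.8),
                intercept = solve_intercept(p5(0.06), c(age = 0.09)),
                absorbing = TRUE)
  )
}

#' Read or write event-model coefficients as a tabular CSV config
#'
#' Same long format as the risk equations: `event`, `term`, `value`, with
#' flag rows `absorbing` and `recurrent` (0/1) and `prior_mode_indicator`.
#'
#' @param models an `event_models` list.
#' @param path CSV path.
#' @export
write_event_models <- function(models, path) {
  rows <- do.call(rbind, lapply(models, function(m) {
    data.frame(event = m$event,
               term = c("intercept", "time", "prior_coef", "absorbing",
                        "recurrent", "prior_mode_indicator", names(m$coef)),
               value = c(m$intercept, m$time, m$prior_coef,
                         as.numeric(m$absorbing), as.numeric(m$recurrent),
                         as.numeric(m$prior_mode == "indicator"),
                         unname(m$coef)))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_models
#' @export
read_event_models <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ms <- lapply(split(df, df$event), function(d) {
    v <- stats::setNames(d$value, d$term)
    special <- c("intercept", "time", "prior_coef", "absorbing", "recurrent",
                 "prior_mode_indicator")
    event_model(d$event[1], intercept = v[["intercept"]],
                coef = v[setdiff(names(v), special)],
                time = v[["time"]], prior_coef = v[["prior_coef"]],
                prior_mode = if (v[["prior_mode_indicator"]] > 0)
                  "indicator" else "count",
                absorbing = v[["absorbing"]] > 0,
                recurrent = v[["recurrent"]] > 0)
  })
  event_models(ms)
}
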