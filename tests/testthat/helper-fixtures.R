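# Fixtures built in code: tiny deterministic cohorts, hand-set timelines,
# and minimal equation/model bundles used across the unit tests.

tiny_cohort <- function(n = 4L, arm = "SU", hba1c = 8, bmi = 30, sbp = 130,
                        dbp = 80, hdl = 45, ldl = 90, total_cholesterol = 170,
                        triglycerides = 150, egfr = 90, age = 60,
                        sex = "female", years_since_diagnosis = 5,
                        cvd_history = FALSE) {
  co <- tibble::tibble(
    id = seq_len(n),
    age = rep_len(age, n), sex = rep_len(sex, n),
    ethnicity = "White", imd_quintile = "3",
    years_since_diagnosis = rep_len(years_since_diagnosis, n),
    hba1c = rep_len(hba1c, n), bmi = rep_len(bmi, n), sbp = rep_len(sbp, n),
    dbp = rep_len(dbp, n), hdl = rep_len(hdl, n), ldl = rep_len(ldl, n),
    total_cholesterol = rep_len(total_cholesterol, n),
    triglycerides = rep_len(triglycerides, n),
    egfr = rep_len(egfr, n),
    hist_angina = FALSE, hist_mi = FALSE, hist_stroke = FALSE,
    hist_hf = FALSE, hist_hypoglycaemia = FALSE,
    cvd_history = rep_len(cvd_history, n),
    second_line_class = rep_len(arm, n))
  class(co) <- c("diamicro_cohort", class(co))
  co
}

# hand-built timelines: every individual on their second-line dual for all
# quarters unless a regimen matrix / censor vector is supplied
manual_timelines <- function(cohort, regimen = NULL, censor_quarter = NULL,
                             statin = FALSE, bp_lowering = FALSE) {
  n <- nrow(cohort)
  H <- 31L
  codes <- regimen_codes()
  if (is.null(regimen)) {
    states <- matrix(match(second_line_regimen(cohort$second_line_class),
                           codes), n, H)
  } else if (is.matrix(regimen)) {
    states <- matrix(match(regimen, codes), n, H)
  } else if (length(regimen) == 1L) {
    states <- matrix(match(regimen, codes), n, H)
  } else {
    stopifnot(length(regimen) == H)
    states <- matrix(match(regimen, codes), n, H, byrow = TRUE)
  }
  if (is.null(censor_quarter)) censor_quarter <- rep(NA_integer_, n)
  st <- matrix(rep_len(statin, n * H), n, H)
  bp <- matrix(rep_len(bp_lowering, n * H), n, H)
  cq <- censor_quarter
  cq[is.na(cq)] <- H + 1L
  mask <- col(states) > cq
  states[mask] <- NA_integer_
  st[mask] <- NA
  bp[mask] <- NA
  structure(list(states = states, statin = st, bp_lowering = bp,
                 censor_quarter = as.integer(censor_quarter),
                 id = cohort$id, codes = codes, horizon = H,
                 seed = NA_integer_),
            class = "diamicro_timelines")
}

# identity risk equations: every factor carried over unchanged
identity_equations <- function() {
  risk_equations(lapply(risk_factor_names(), function(f)
    risk_equation(f, intercept = 0, lag1 = 1, floor = -Inf)))
}

# event models with a flat intercept for every event
flat_event_models <- function(intercept = -10) {
  event_models(lapply(event_names(), function(e)
    event_model(e, intercept = intercept,
                absorbing = e %in% absorbing_events(),
                recurrent = e %in% recurrent_events())))
}

zero_registry <- function() suppressWarnings(effects_registry())

# transition spec where nobody leaves second line and nobody is censored
absorbing_transition_spec <- function() {
  codes <- regimen_codes()
  dest <- matrix(0, 30, length(codes), dimnames = list(NULL, codes))
  dest[, "triple_or_other"] <- 1
  transition_spec(leave_hazard = rep(0, 30), destinations = dest,
                  censor_hazard = rep(0, 31))
}
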