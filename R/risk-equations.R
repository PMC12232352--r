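#' Autoregressive risk equations
#'
#' Each of the nine risk factors advances one quarter at a time as a linear
#' AR(1):
#' \deqn{x_{t+1} = \beta_0 + \lambda x_t + \beta' z + \beta_t t +
#'   \mathrm{effect}(regimen) + \delta_t (+ \epsilon)}
#' where `z` are baseline covariates (age, male sex, years since diagnosis,
#' CVD history) and the quarter's concomitant-therapy flags, `t` is the
#' quarter index, `effect` the additive regimen effect from the registry,
#' `delta_t` an optional recalibration offset, and `epsilon` a Gaussian
#' residual used only in stochastic mode.  Coefficients are fully
#' config-driven; the functional form is the package's declared contract.
#'
#' @param target one of [risk_factor_names()].
#' @param intercept,lag1 intercept and own-lag coefficient.
#' @param age,sex_male,years_since_diagnosis,cvd_history,statin,bp_lowering
#'   covariate coefficients.
#' @param time coefficient on the quarter index.
#' @param resid_sd residual standard deviation (stochastic mode only),
#'   must be >= 0.
#' @param floor physiologic floor; predictions are clipped from below.
#' @return a `risk_equation` list.
#' @export
risk_equation <- function(target, intercept = 0, lag1 = 1, age = 0,
                          sex_male = 0, years_since_diagnosis = 0,
                          cvd_history = 0, statin = 0, bp_lowering = 0,
                          time = 0, resid_sd = 0, floor = 0) {
  stopifnot(target %in% risk_factor_names(), is.finite(lag1), resid_sd >= 0)
  structure(list(target = target, intercept = intercept, lag1 = lag1,
                 age = age, sex_male = sex_male,
                 years_since_diagnosis = years_since_diagnosis,
                 cvd_history = cvd_history, statin = statin,
                 bp_lowering = bp_lowering, time = time,
                 resid_sd = resid_sd, floor = floor, offsets = NULL),
            class = "risk_equation")
}

#' Bundle risk equations for all nine factors
#' @param ... `risk_equation` objects, one per factor, covering all of
#'   [risk_factor_names()].
#' @return a named list of class `risk_equations`.
#' @export
risk_equations <- function(...) {
  eqs <- list(...)
  if (length(eqs) == 1L && is.list(eqs[[1]]) &&
      !inherits(eqs[[1]], "risk_equation")) {
    eqs <- eqs[[1]]
  }
  names(eqs) <- vapply(eqs, `[[`, character(1), "target")
  missing_eq <- setdiff(risk_factor_names(), names(eqs))
  if (length(missing_eq)) {
    stop("missing risk equation for factor(s): ",
         paste(missing_eq, collapse = ", "), call. = FALSE)
  }
  structure(eqs[risk_factor_names()], class = "risk_equations")
}

#' Default risk-equation coefficients
#'
#' Mean-reverting AR(1) defaults with lag-1 coefficient 0.9 (0.95 for BMI,
#' 0.98 for eGFR), intercepts set so the untreated stationary level sits
#' somewhat above the baseline population median (treatment effects then
#' pull levels down), statin effects on LDL/total cholesterol and
#' blood-pressure-therapy effects on SBP/DBP, and a deterministic negative
#' time trend on eGFR giving roughly -0.8 mL/min/1.73m2 per year of
#' asymptotic decline to feed the end-stage kidney disease pathway.
#' Residual standard deviations are modest fractions of each factor's IQR.
#'
#' @return a `risk_equations` list.
#' @export
default_risk_equations <- function() {
  risk_equations(
    risk_equation("hba1c", intercept = 0.96, lag1 = 0.9, resid_sd = 0.15,
                  floor = 4),
    risk_equation("bmi", intercept = 1.59, lag1 = 0.95, resid_sd = 0.20,
                  floor = 12),
    risk_equation("sbp", intercept = 13.8, lag1 = 0.9, bp_lowering = -1.0,
                  resid_sd = 1.5, floor = 60),
    risk_equation("dbp", intercept = 8.2, lag1 = 0.9, bp_lowering = -0.5,
                  resid_sd = 1.0, floor = 35),
    risk_equation("hdl", intercept = 4.25, lag1 = 0.9, resid_sd = 0.8,
                  floor = 5),
    risk_equation("ldl", intercept = 11.0, lag1 = 0.9, statin = -2.8,
                  resid_sd = 2.0, floor = 10),
    risk_equation("total_cholesterol", intercept = 18.8, lag1 = 0.9,
                  statin = -3.5, resid_sd = 3.0, floor = 50),
    risk_equation("triglycerides", intercept = 16.5, lag1 = 0.9,
                  resid_sd = 5.0, floor = 20),
    risk_equation("egfr", intercept = 1.90, lag1 = 0.98, time = -0.004,
                  resid_sd = 0.8, floor = 0)
  )
}

#' Additive recalibration offset schedule for one risk factor
#'
#' @param target one of [risk_factor_names()].
#' @param offsets numeric vector of additive offsets, one per update
#'   quarter (quarters 1..30 of the 31-quarter horizon).
#' @return an `offset_schedule`.
#' @export
offset_schedule <- function(target, offsets) {
  stopifnot(target %in% risk_factor_names(),
            all(is.finite(offsets)))
  structure(list(target = target, offsets = as.numeric(offsets)),
            class = "offset_schedule")
}

#' Attach recalibration offsets to risk equations
#'
#' Attaching is an idempotent replace: applying the same schedule twice, or
#' a zero schedule, leaves predictions unchanged.  The schedule must span
#' every update quarter of the simulation horizon.
#'
#' @param equations a `risk_equations` list.
#' @param schedule an `offset_schedule` or a list of them.
#' @param horizon number of update quarters the schedule must cover.
#' @return the equations with offsets attached.
#' @export
apply_offsets <- function(equations, schedule, horizon = max_quarters() - 1L) {
  stopifnot(inherits(equations, "risk_equations"))
  if (inherits(schedule, "offset_schedule")) schedule <- list(schedule)
  for (sch in schedule) {
    stopifnot(inherits(sch, "offset_schedule"))
    if (length(sch$offsets) != horizon) {
      stop("offset schedule for '", sch$target, "' has length ",
           length(sch$offsets), " but the horizon needs ", horizon,
           call. = FALSE)
    }
    equations[[sch$target]]$offsets <- sch$offsets
  }
  equations
}

#' Read or write risk-equation coefficients as a tabular CSV config
#'
#' Long format with columns `target`, `term`, `value`; terms are
#' `intercept`, `lag1`, `age`, `sex_male`, `years_since_diagnosis`,
#' `cvd_history`, `statin`, `bp_lowering`, `time`, `resid_sd`, `floor`.
#'
#' @param equations a `risk_equations` list.
#' @param path CSV path.
#' @export
write_risk_equations <- function(equations, path) {
  terms <- c("intercept", "lag1", "age", "sex_male", "years_since_diagnosis",
             "cvd_history", "statin", "bp_lowering", "time", "resid_sd",
             "floor")
  rows <- do.call(rbind, lapply(equations, function(eq) {
    data.frame(target = eq$target, term = terms,
               value = unlist(eq[terms], use.names = FALSE))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_risk_equations
#' @export
read_risk_equations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  eqs <- lapply(split(df, df$target), function(d) {
    args <- as.list(stats::setNames(d$value, d$term))
    args$target <- d$target[1]
    do.call(risk_equation, args)
  })
  risk_equations(eqs)
}
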