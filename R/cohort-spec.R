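#' Specify a synthetic baseline cohort
#'
#' A `cohort_spec` parameterises the synthetic cohort generator: marginal
#' distributions for the continuous variables (solved from a target median
#' and IQR), a rank-correlation (Spearman) matrix coupling the nine risk
#' factors through a Gaussian copula, category frequencies for the
#' categorical descriptors, comorbidity-history frequencies, and the
#' second-line arm split.
#'
#' Continuous marginals are parameterised by `family` (`"normal"` or
#' `"lognormal"`), `median`, `q1` and `q3`.  For a normal family the mean is
#' the median and sd = IQR / (2 * qnorm(0.75)); for a log-normal family
#' meanlog = log(median) and sdlog = log(q3/q1) / (2 * qnorm(0.75)).  Both
#' families therefore reproduce the target median exactly in expectation.
#'
#' Comorbidity flags (angina, MI, stroke, heart failure) are generated so
#' that (i) each flag's marginal frequency matches its target, and (ii) the
#' composite "any CVD" frequency matches its own target, which is smaller
#' than the sum of the component frequencies because histories co-occur.
#' Internally this conditions independent Bernoulli draws on "at least one
#' flag set" within the CVD-positive subset, with conditional probabilities
#' solved by fixed-point iteration.
#'
#' @param n number of individuals to generate by default.
#' @param continuous data frame with columns `variable`, `family`,
#'   `median`, `q1`, `q3`.  Must cover `age`, `years_since_diagnosis` and
#'   all of [risk_factor_names()].
#' @param rank_correlation Spearman correlation matrix over
#'   [risk_factor_names()] (symmetric, unit diagonal, positive
#'   semi-definite).  `age` and `years_since_diagnosis` are drawn
#'   independently of the copula.
#' @param sex_female,ethnicity,imd,arms category frequency vectors (each
#'   sums to 1; `sex_female` is the single female proportion).
#' @param comorbidity list with `any_cvd` (composite frequency),
#'   `components` (named frequencies for `angina`, `mi`, `stroke`, `hf`)
#'   and `hypoglycaemia`.
#' @return an object of class `cohort_spec`.
#' @seealso [default_cohort_spec()], [generate_cohort()]
#' @export
cohort_spec <- function(n,
                        continuous,
                        rank_correlation,
                        sex_female,
                        ethnicity,
                        imd,
                        arms,
                        comorbidity) {
  # tolerate printed-percentage rounding: renormalise if within 0.5% of 1
  renorm <- function(p, what) {
    s <- sum(p)
    if (any(p < 0) || abs(s - 1) > 0.005) {
      stop("cohort_spec: '", what, "' frequencies must be nonnegative and ",
           "sum to 1", call. = FALSE)
    }
    p / s
  }
  ethnicity <- renorm(ethnicity, "ethnicity")
  imd <- renorm(imd, "imd")
  arms <- renorm(arms, "arms")
  spec <- structure(
    list(n = as.integer(n), continuous = as.data.frame(continuous),
         rank_correlation = rank_correlation, sex_female = sex_female,
         ethnicity = ethnicity, imd = imd, arms = arms,
         comorbidity = comorbidity),
    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (spec$n < 1L) stop("cohort_spec: n must be >= 1", call. = FALSE)
  cont <- spec$continuous
  needed <- c("age", "years_since_diagnosis", risk_factor_names())
  missing_vars <- setdiff(needed, cont$variable)
  if (length(missing_vars)) {
    stop("cohort_spec: missing continuous variables: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  bad_fam <- setdiff(unique(cont$family), c("normal", "lognormal"))
  if (length(bad_fam)) {
    stop("cohort_spec: unknown distribution family: ",
         paste(bad_fam, collapse = ", "), call. = FALSE)
  }
  if (any(cont$q1 > cont$median | cont$median > cont$q3)) {
    stop("cohort_spec: need q1 <= median <= q3 for every variable",
         call. = FALSE)
  }
  R <- spec$rank_correlation
  rf <- risk_factor_names()
  if (!is.matrix(R) || !identical(dim(R), c(9L, 9L)) ||
      is.null(rownames(R)) || !setequal(rownames(R), rf)) {
    stop("cohort_spec: rank_correlation must be a 9x9 matrix named by the ",
         "risk factors", call. = FALSE)
  }
  R <- R[rf, rf]
  if (max(abs(R - t(R))) > 1e-10 || max(abs(diag(R) - 1)) > 1e-10) {
    stop("cohort_spec: rank_correlation must be symmetric with unit diagonal",
         call. = FALSE)
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("cohort_spec: rank_correlation is not positive semi-definite",
         call. = FALSE)
  }
  for (nm in c("ethnicity", "imd", "arms")) {
    p <- spec[[nm]]
    if (abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
      stop("cohort_spec: '", nm, "' frequencies must be nonnegative and sum ",
           "to 1", call. = FALSE)
    }
  }
  if (spec$sex_female < 0 || spec$sex_female > 1) {
    stop("cohort_spec: sex_female must be in [0, 1]", call. = FALSE)
  }
  com <- spec$comorbidity
  stopifnot(setequal(names(com$components), c("angina", "mi", "stroke", "hf")))
  if (com$any_cvd > sum(com$components) || com$any_cvd < max(com$components)) {
    stop("cohort_spec: any_cvd must lie between max(component) and ",
         "sum(components)", call. = FALSE)
  }
  invisible(spec)
}

#' Default cohort specification
#'
#' Marginal medians/IQRs, category frequencies and the arm split emulate a
#' large England primary-secondary care linked population presenting for
#' second-line treatment (n = 62 640; median age 60, 39.4% female, median
#' HbA1c 7.9%, arm split SU/DPP4i/SGLT2i = 49.0/40.8/10.2%, 13.8% with any
#' CVD history).  Skewed variables (BMI, triglycerides, HbA1c,
#' years-since-diagnosis) use log-normal families; the remainder normal.
#' The default rank-correlation matrix encodes weak, plausible structure
#' (lipid fractions strongly correlated with total cholesterol, SBP with
#' DBP, BMI positively with blood pressure and triglycerides); it is fully
#' user-overridable.
#'
#' @param n cohort size.
#' @return a [cohort_spec()].
#' @export
default_cohort_spec <- function(n = 62640L) {
  continuous <- data.frame(
    variable = c("age", "years_since_diagnosis", risk_factor_names()),
    family = c("normal", "lognormal",
               "lognormal",  # hba1c
               "lognormal",  # bmi
               "normal",     # sbp
               "normal",     # dbp
               "normal",     # hdl
               "normal",     # ldl
               "normal",     # total_cholesterol
               "lognormal",  # triglycerides
               "normal"),    # egfr
    median = c(60.0, 4.9, 7.9, 31.3, 132, 79.0, 42.5, 81.2, 158.5, 159.4, 92),
    q1     = c(52.0, 2.5, 7.3, 28.0, 124, 73.0, 38.7, 61.9, 139.2, 115.1, 80),
    q3     = c(69.0, 5.0, 8.8, 36.0, 140, 82.0, 50.3, 104.4, 185.6, 221.4, 102)
  )
  rf <- risk_factor_names()
  R <- diag(9)
  dimnames(R) <- list(rf, rf)
  set_r <- function(a, b, v) {
    R[a, b] <<- v
    R[b, a] <<- v
  }
  set_r("sbp", "dbp", 0.60)
  set_r("bmi", "sbp", 0.20)
  set_r("bmi", "dbp", 0.15)
  set_r("bmi", "triglycerides", 0.25)
  set_r("bmi", "hdl", -0.20)
  set_r("ldl", "total_cholesterol", 0.85)
  set_r("hdl", "total_cholesterol", 0.25)
  set_r("hdl", "triglycerides", -0.30)
  set_r("ldl", "triglycerides", 0.10)
  set_r("hba1c", "triglycerides", 0.15)
  cohort_spec(
    n = n,
    continuous = continuous,
    rank_correlation = R,
    sex_female = 0.394,
    ethnicity = c(White = 0.725, Black = 0.050, Other = 0.225),
    imd = c(`1` = 0.142, `2` = 0.177, `3` = 0.181, `4` = 0.219, `5` = 0.232,
            missing = 0.050),
    arms = c(SU = 0.490, DPP4i = 0.408, SGLT2i = 0.102),
    comorbidity = list(
      any_cvd = 0.138,
      components = c(angina = 0.033, mi = 0.061, stroke = 0.042, hf = 0.047),
      hypoglycaemia = 0.008)
  )
}

# Solve conditional Bernoulli probabilities q so that, conditioning on at
# least one flag set, each flag's conditional frequency equals
# components/any_cvd.  Fixed point of q_j = target_j * P(at least one).
solve_cvd_conditionals <- function(comorbidity) {
  target <- comorbidity$components / comorbidity$any_cvd
  if (any(target > 1)) {
    stop("comorbidity components inconsistent with any_cvd", call. = FALSE)
  }
  q <- target
  for (i in 1:200) {
    p_any <- 1 - prod(1 - q)
    q_new <- pmin(target * p_any, 1)
    if (max(abs(q_new - q)) < 1e-12) break
    q <- q_new
  }
  q
}

#' Read or write a cohort specification as YAML
#'
#' @param path file path.
#' @param spec a [cohort_spec()].
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  out <- list(
    n = spec$n,
    continuous = spec$continuous,
    rank_correlation = list(variables = rownames(spec$rank_correlation),
                            values = as.vector(spec$rank_correlation)),
    sex_female = spec$sex_female,
    ethnicity = as.list(spec$ethnicity),
    imd = as.list(spec$imd),
    arms = as.list(spec$arms),
    comorbidity = list(any_cvd = spec$comorbidity$any_cvd,
                       components = as.list(spec$comorbidity$components),
                       hypoglycaemia = spec$comorbidity$hypoglycaemia)
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  vars <- raw$rank_correlation$variables
  R <- matrix(unlist(raw$rank_correlation$values), length(vars),
              dimnames = list(vars, vars))
  cont <- as.data.frame(lapply(raw$continuous, unlist))
  cohort_spec(
    n = raw$n, continuous = cont, rank_correlation = R,
    sex_female = raw$sex_female,
    ethnicity = unlist(raw$ethnicity), imd = unlist(raw$imd),
    arms = unlist(raw$arms),
    comorbidity = list(any_cvd = raw$comorbidity$any_cvd,
                       components = unlist(raw$comorbidity$components),
                       hypoglycaemia = raw$comorbidity$hypoglycaemia))
}
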