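#' Generate a synthetic baseline cohort
#'
#' Draws `spec$n` baseline profiles.  Continuous risk factors are coupled
#' by a Gaussian copula: latent multivariate normals with Pearson
#' correlation `2 * sin(pi * r_s / 6)` (the exact inverse of the Gaussian
#' copula's Spearman correlation `r_s`) are mapped through their normal CDF
#' and then through each marginal's quantile function.  Age and
#' years-since-diagnosis are drawn independently; categorical fields are
#' drawn independently at the spec frequencies.
#'
#' Physiological coherence is enforced after marginal sampling: all
#' continuous values are floored at a small positive value, diastolic is
#' capped strictly below systolic pressure, and HDL at total cholesterol.
#' With the default spec these adjustments are vanishingly rare.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; identical (spec, seed) pairs yield identical
#'   cohorts.
#' @param n optional override of `spec$n`.
#' @return a tibble of class `diamicro_cohort`, one row per individual,
#'   with demographic columns, the nine risk factors
#'   ([risk_factor_names()]), history flags (`hist_angina`, `hist_mi`,
#'   `hist_stroke`, `hist_hf`, `hist_hypoglycaemia`), the composite
#'   `cvd_history` (OR of the four cardiovascular flags) and
#'   `second_line_class`.  The generating spec and seed are attached as
#'   attributes.
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(500), seed = 1)
#' summarize_cohort(cohort)
#' @export
generate_cohort <- function(spec, seed, n = NULL) {
  validate_cohort_spec(spec)
  n <- if (is.null(n)) spec$n else as.integer(n)
  stopifnot(n >= 1L)
  set.seed(as.integer(seed))

  rf <- risk_factor_names()
  cont <- spec$continuous
  rownames(cont) <- cont$variable

  # Gaussian copula over the nine risk factors
  R_latent <- 2 * sin(pi * spec$rank_correlation[rf, rf] / 6)
  diag(R_latent) <- 1
  ev <- eigen(R_latent, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    stop("latent copula correlation not positive semi-definite", call. = FALSE)
  }
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  Z <- matrix(stats::rnorm(n * 9L), n, 9L) %*% L
  U <- stats::pnorm(Z)
  colnames(U) <- rf

  q_marginal <- function(u, variable) {
    row <- cont[variable, ]
    k <- 2 * stats::qnorm(0.75)
    if (row$family == "normal") {
      stats::qnorm(u, mean = row$median, sd = (row$q3 - row$q1) / k)
    } else {
      stats::qlnorm(u, meanlog = log(row$median),
                    sdlog = log(row$q3 / row$q1) / k)
    }
  }
  X <- vapply(rf, function(v) q_marginal(U[, v], v), numeric(n))
  X <- pmax(X, 1e-6)
  # enforce sbp > dbp and total_cholesterol >= hdl (rare under defaults)
  X[, "dbp"] <- pmin(X[, "dbp"], X[, "sbp"] - 1)
  X[, "hdl"] <- pmin(X[, "hdl"], X[, "total_cholesterol"])

  age <- pmax(q_marginal(stats::runif(n), "age"), 18)
  years_dx <- pmax(q_marginal(stats::runif(n), "years_since_diagnosis"), 0)

  sex <- ifelse(stats::runif(n) < spec$sex_female, "female", "male")
  ethnicity <- sample(names(spec$ethnicity), n, replace = TRUE,
                      prob = spec$ethnicity)
  imd <- sample(names(spec$imd), n, replace = TRUE, prob = spec$imd)
  arm <- sample(names(spec$arms), n, replace = TRUE, prob = spec$arms)

  # comorbidity: composite drawn at its target frequency; component flags
  # drawn within the CVD-positive subset conditional on at least one set
  com <- spec$comorbidity
  cvd <- stats::runif(n) < com$any_cvd
  q <- solve_cvd_conditionals(com)
  flags <- matrix(FALSE, n, 4L,
                  dimnames = list(NULL, c("angina", "mi", "stroke", "hf")))
  idx <- which(cvd)
  while (length(idx)) {
    draw <- matrix(stats::runif(length(idx) * 4L), ncol = 4L) <
      matrix(q, length(idx), 4L, byrow = TRUE)
    flags[idx, ] <- draw
    idx <- idx[rowSums(draw) == 0L]  # redraw until >= 1 flag (rejection)
  }
  hypo <- stats::runif(n) < com$hypoglycaemia

  cohort <- tibble::tibble(
    id = seq_len(n),
    age = age,
    sex = sex,
    ethnicity = ethnicity,
    imd_quintile = imd,
    years_since_diagnosis = years_dx,
    hba1c = X[, "hba1c"], bmi = X[, "bmi"], sbp = X[, "sbp"],
    dbp = X[, "dbp"], hdl = X[, "hdl"], ldl = X[, "ldl"],
    total_cholesterol = X[, "total_cholesterol"],
    triglycerides = X[, "triglycerides"], egfr = X[, "egfr"],
    hist_angina = flags[, "angina"], hist_mi = flags[, "mi"],
    hist_stroke = flags[, "stroke"], hist_hf = flags[, "hf"],
    hist_hypoglycaemia = hypo,
    cvd_history = flags[, "angina"] | flags[, "mi"] | flags[, "stroke"] |
      flags[, "hf"],
    second_line_class = arm
  )
  structure(cohort, spec = spec, seed = as.integer(seed),
            class = c("diamicro_cohort", class(cohort)))
}

#' Summarise a cohort in the style of a baseline-characteristics table
#'
#' Medians and IQRs use the standard type-7 (linear interpolation) quantile
#' definition; percentages are over the cohort size.
#'
#' @param cohort a `diamicro_cohort` (or any data frame with its columns).
#' @return a tibble with one row per variable: `variable`, `type`
#'   (`continuous`/`categorical`), `level`, `median`, `q1`, `q3`, `count`,
#'   `pct`.
#' @export
summarize_cohort <- function(cohort) {
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  n <- nrow(cohort)
  cont_vars <- c("age", "years_since_diagnosis", risk_factor_names())
  cont <- do.call(rbind, lapply(cont_vars, function(v) {
    qs <- stats::quantile(cohort[[v]], c(0.25, 0.5, 0.75), type = 7,
                          names = FALSE)
    tibble::tibble(variable = v, type = "continuous", level = NA_character_,
                   median = qs[2], q1 = qs[1], q3 = qs[3],
                   count = NA_integer_, pct = NA_real_)
  }))
  cat_row <- function(variable, level, count) {
    tibble::tibble(variable = variable, type = "categorical", level = level,
                   median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                   count = as.integer(count), pct = 100 * count / n)
  }
  cats <- rbind(
    cat_row("sex", "female", sum(cohort$sex == "female")),
    do.call(rbind, lapply(sort(unique(cohort$ethnicity)), function(l)
      cat_row("ethnicity", l, sum(cohort$ethnicity == l)))),
    do.call(rbind, lapply(sort(unique(cohort$imd_quintile)), function(l)
      cat_row("imd_quintile", l, sum(cohort$imd_quintile == l)))),
    cat_row("cvd_history", "yes", sum(cohort$cvd_history)),
    cat_row("hist_angina", "yes", sum(cohort$hist_angina)),
    cat_row("hist_mi", "yes", sum(cohort$hist_mi)),
    cat_row("hist_stroke", "yes", sum(cohort$hist_stroke)),
    cat_row("hist_hf", "yes", sum(cohort$hist_hf)),
    cat_row("hist_hypoglycaemia", "yes", sum(cohort$hist_hypoglycaemia)),
    do.call(rbind, lapply(second_line_classes(), function(l)
      cat_row("second_line_class", l, sum(cohort$second_line_class == l))))
  )
  rbind(cont, cats)
}

#' Write or read a cohort as CSV with a sidecar spec/seed JSON
#'
#' The CSV has one row per individual (column dictionary in the cohort
#' documentation); the sidecar `<path>.json` records the generating spec
#' and seed so a run can be reproduced exactly.
#'
#' @param cohort a `diamicro_cohort`.
#' @param path CSV path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  spec <- attr(cohort, "spec")
  if (!is.null(spec)) {
    sidecar <- list(
      seed = attr(cohort, "seed"),
      n = spec$n,
      continuous = spec$continuous,
      rank_correlation = list(variables = rownames(spec$rank_correlation),
                              values = as.vector(spec$rank_correlation)),
      sex_female = spec$sex_female, ethnicity = as.list(spec$ethnicity),
      imd = as.list(spec$imd), arms = as.list(spec$arms),
      comorbidity = spec$comorbidity)
    jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- tibble::as_tibble(df)
  class(out) <- c("diamicro_cohort", class(out))
  out
}
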