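#' Run the quarterly microsimulation for a cohort
#'
#' Advances every individual through their observed timeline.  Within each
#' quarter the loop order is fixed: (1) read the quarter's regimen and
#' concomitant flags, (2) compute every complication's per-quarter
#' probability from the *current* risk-factor state, (3) update the risk
#' factors into the next quarter.  The run stops at each individual's
#' censoring quarter (and, in stochastic mode, at simulated death, after
#' which no further events or updates occur).
#'
#' In expected mode (the default, matching mean-trajectory reporting) no
#' random numbers are consumed; the prior-event covariate for recurrent
#' events is the expected count accumulated so far, and absorbing events
#' are reported as at-risk probabilities throughout.
#'
#' @param cohort a `diamicro_cohort`.
#' @param timelines a `diamicro_timelines` aligned with the cohort.
#' @param equations a `risk_equations` list.
#' @param models an `event_models` list.
#' @param registry an `effects_registry`.
#' @param mode `"expected"` or `"stochastic"`.
#' @param seed master seed for stochastic mode; per-individual streams are
#'   derived from it so that common random numbers can be shared across
#'   counterfactual arms.
#' @return a `diamicro_results` object: arrays `rf` (n x 31 x 9 factors)
#'   and `event_prob` (n x 31 x 9 events) with `NA` beyond follow-up,
#'   `censor_quarter`, `id`, `arm` (each individual's assigned class for
#'   this run), and in stochastic mode `death_quarter`.
#' @export
run_cohort <- function(cohort, timelines, equations, models,
                       registry = default_effects_registry(),
                       mode = c("expected", "stochastic"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(timelines, "diamicro_timelines"),
            nrow(cohort) == nrow(timelines$states))
  if (!all(cohort$id == timelines$id)) {
    stop("cohort and timelines refer to different individuals",
         call. = FALSE)
  }
  orig <- match(second_line_regimen(cohort$second_line_class),
                timelines$codes)
  first_reg <- timelines$states[, 1L]
  if (any(!is.na(first_reg) & first_reg != orig)) {
    stop("timeline quarter 0 regimen does not match the profile's ",
         "second-line class", call. = FALSE)
  }
  if (mode == "stochastic") set.seed(derive_seed(seed, 1L))

  n <- nrow(cohort)
  H <- timelines$horizon
  rf <- risk_factor_names()
  ev <- event_names()
  eff_ev <- regimen_effect_matrix(registry, ev)

  state <- as.matrix(cohort[, rf])
  rf_arr <- array(NA_real_, c(n, H, length(rf)),
                  dimnames = list(NULL, NULL, rf))
  p_arr <- array(NA_real_, c(n, H, length(ev)),
                 dimnames = list(NULL, NULL, ev))
  counts <- matrix(0, n, length(ev), dimnames = list(NULL, ev))
  dead <- rep(FALSE, n)
  death_quarter <- rep(NA_integer_, n)
  profile <- as.data.frame(cohort)  # plain row subsetting in the hot loop

  for (q in 0:(H - 1L)) {
    reg_idx <- timelines$states[, q + 1L]
    at_risk <- !is.na(reg_idx) & !dead
    if (!any(at_risk)) break
    i <- which(at_risk)
    regimen <- timelines$codes[reg_idx[i]]
    rf_arr[cbind(rep(i, length(rf)), q + 1L,
                 rep(seq_along(rf), each = length(i)))] <-
      as.vector(state[i, rf])
    # event probabilities from the current state
    for (e in ev) {
      m <- models[[e]]
      hist_e <- if (m$absorbing) rep(0, length(i)) else counts[i, e]
      p <- event_probability(state[i, , drop = FALSE], profile[i, ],
                             regimen, hist_e, m, quarter = q,
                             registry = registry,
                             direct_effect = eff_ev[reg_idx[i], e])
      p_arr[i, q + 1L, e] <- p
      if (mode == "expected") {
        if (m$recurrent) counts[i, e] <- counts[i, e] + p
      } else {
        occur <- stats::runif(length(i)) < p
        counts[i, e] <- counts[i, e] + as.numeric(occur)
        if (e == "all_cause_death" && any(occur)) {
          died <- i[occur]
          dead[died] <- TRUE
          death_quarter[died] <- q
        }
      }
    }
    # update risk factors into quarter q + 1
    if (q < H - 1L) {
      upd <- which(at_risk & !dead)
      if (length(upd)) {
        state[upd, ] <- update_risk_factors(
          state[upd, , drop = FALSE], profile[upd, ],
          timelines$codes[reg_idx[upd]], equations, registry,
          quarter = q + 1L,
          statin = timelines$statin[upd, q + 1L] %in% TRUE,
          bp_lowering = timelines$bp_lowering[upd, q + 1L] %in% TRUE,
          mode = mode)
      }
    }
  }

  structure(list(rf = rf_arr, event_prob = p_arr,
                 expected_counts = counts,
                 censor_quarter = timelines$censor_quarter,
                 death_quarter = death_quarter,
                 id = cohort$id, arm = cohort$second_line_class,
                 mode = mode, horizon = H),
            class = "diamicro_results")
}

#' Run the microsimulation for a single individual
#'
#' Thin wrapper around [run_cohort()] for one profile/timeline pair.
#'
#' @param profile one-row `diamicro_cohort` (or data frame with its
#'   columns).
#' @param timeline a `diamicro_timelines` containing that individual.
#' @inheritParams run_cohort
#' @return a list with per-quarter matrices `rf` (quarters x 9) and
#'   `event_prob` (quarters x 9), per-quarter cumulative incidences
#'   `cum_inc`, expected recurrent-event counts, and `censor_quarter`.
#' @export
run_individual <- function(profile, timeline, equations, models,
                           registry = default_effects_registry(),
                           mode = c("expected", "stochastic"), seed = NULL) {
  mode <- match.arg(mode)
  if (nrow(profile) != 1L || nrow(timeline$states) != 1L) {
    stop("run_individual expects exactly one profile and one timeline",
         call. = FALSE)
  }
  res <- run_cohort(profile, timeline, equations, models, registry,
                    mode = mode, seed = seed)
  obs <- which(!is.na(res$event_prob[1L, , "all_cause_death"]))
  if (length(obs) == 0L) {
    empty <- matrix(numeric(0), 0L, length(event_names()),
                    dimnames = list(NULL, event_names()))
    return(list(id = res$id, arm = res$arm, quarters = integer(0),
                rf = matrix(numeric(0), 0L, length(risk_factor_names()),
                            dimnames = list(NULL, risk_factor_names())),
                event_prob = empty, cum_inc = empty,
                expected_counts = res$expected_counts[1L, ],
                censor_quarter = res$censor_quarter))
  }
  pq <- res$event_prob[1L, obs, , drop = TRUE]
  if (length(obs) == 1L) pq <- matrix(pq, 1L, dimnames = list(NULL, event_names()))
  cum_inc <- apply(pq, 2L, function(p) 1 - cumprod(1 - p))
  if (length(obs) == 1L) cum_inc <- matrix(cum_inc, 1L,
                                           dimnames = list(NULL, event_names()))
  list(id = res$id, arm = res$arm,
       quarters = obs - 1L,
       rf = res$rf[1L, obs, , drop = TRUE],
       event_prob = pq,
       cum_inc = cum_inc,
       expected_counts = res$expected_counts[1L, ],
       censor_quarter = res$censor_quarter)
}

#' Counterfactual runs under each second-line treatment
#'
#' Produces three simulation results per individual -- one per second-line
#' class -- from identical copies of the baseline characteristics, the
#' same second-line duration and the same downstream pathway and
#' censoring: wherever an individual's observed timeline shows their
#' original metformin dual, the counterfactual timeline substitutes the
#' assigned class's dual; all other quarters are untouched.  In stochastic
#' mode the three runs share common random numbers (the same derived
#' per-run seed) for variance reduction.
#'
#' @inheritParams run_cohort
#' @param arms which second-line classes to simulate.
#' @return a named list of `diamicro_results` (class
#'   `diamicro_counterfactuals`) with the cohort attached as an attribute.
#' @export
run_counterfactuals <- function(cohort, timelines, equations, models,
                                registry = default_effects_registry(),
                                mode = c("expected", "stochastic"),
                                seed = NULL, arms = second_line_classes()) {
  mode <- match.arg(mode)
  orig <- match(second_line_regimen(cohort$second_line_class),
                timelines$codes)
  n <- nrow(cohort)
  out <- lapply(arms, function(arm) {
    tl <- timelines
    target_code <- match(second_line_regimen(arm), timelines$codes)
    on_orig <- tl$states == matrix(orig, n, tl$horizon)
    tl$states[which(on_orig)] <- target_code
    co <- cohort
    co$second_line_class <- arm
    run_cohort(co, tl, equations, models, registry, mode = mode, seed = seed)
  })
  names(out) <- arms
  structure(out, cohort = cohort, class = "diamicro_counterfactuals")
}

# per-individual endpoint values at a yearly horizon; NA when follow-up is
# shorter than the horizon
value_at_horizon <- function(results, endpoint, horizon_years) {
  h <- as.integer(round(4 * horizon_years))
  H <- results$horizon
  stopifnot(h >= 1L, h <= H - 1L)
  cq <- results$censor_quarter
  followed <- is.na(cq) | cq > h
  if (endpoint %in% risk_factor_names()) {
    v <- results$rf[, h + 1L, endpoint]
  } else if (endpoint %in% event_names()) {
    p <- results$event_prob[, seq_len(h), endpoint, drop = FALSE]
    if (endpoint %in% recurrent_events()) {
      v <- apply(p, 1L, function(x) sum(x, na.rm = TRUE))
    } else {
      v <- 1 - apply(1 - p, 1L, function(x) prod(x, na.rm = TRUE))
    }
  } else {
    stop("unknown endpoint '", endpoint, "'", call. = FALSE)
  }
  v[!followed] <- NA_real_
  v
}

#' Average predictions across individuals with a normal-based CI
#'
#' Mean of the per-individual predicted values at the horizon over
#' individuals whose follow-up reaches it, with the normal-based 95%
#' confidence interval mean +/- 1.96 * sd / sqrt(n).  Event endpoints are
#' cumulative incidences over the first `4 * horizon_years` quarters
#' (expected counts for recurrent events); risk-factor endpoints are
#' levels at that quarter.
#'
#' @param results a `diamicro_results`.
#' @param endpoint a risk factor or event name.
#' @param horizon_years horizon in years (quarter = 4 x years).
#' @return tibble with `endpoint`, `horizon_years`, `mean`, `ci_lo`,
#'   `ci_hi`, `n`.
#' @export
aggregate_predictions <- function(results, endpoint, horizon_years) {
  v <- value_at_horizon(results, endpoint, horizon_years)
  v <- v[!is.na(v)]
  if (length(v) < 2L) {
    stop("fewer than 2 individuals with follow-up at horizon", call. = FALSE)
  }
  se <- stats::sd(v) / sqrt(length(v))
  tibble::tibble(endpoint = endpoint, horizon_years = horizon_years,
                 mean = mean(v), ci_lo = mean(v) - 1.96 * se,
                 ci_hi = mean(v) + 1.96 * se, n = length(v))
}

#' Pairwise treatment contrast at a horizon
#'
#' Paired within-individual differences of predicted values between two
#' counterfactual arms (the three copies are the same individuals, so
#' pairing is mandatory), averaged with a normal-based 95% CI, optionally
#' within a baseline-CVD subgroup.
#'
#' @param results_by_arm a `diamicro_counterfactuals` (named list of
#'   per-arm results over the same individuals).
#' @param pair comparison, e.g. `"DPP4i-SU"`, `"SGLT2i-SU"`,
#'   `"SGLT2i-DPP4i"` (first arm minus second).
#' @param endpoint a risk factor or event name.
#' @param horizon_years horizon in years.
#' @param subgroup `"overall"`, `"cvd"` or `"no_cvd"` (baseline CVD
#'   history).
#' @return tibble with `pair`, `endpoint`, `horizon_years`, `subgroup`,
#'   `mean_diff`, `ci_lo`, `ci_hi`, `n`.
#' @export
contrast <- function(results_by_arm, pair, endpoint, horizon_years,
                     subgroup = c("overall", "cvd", "no_cvd")) {
  subgroup <- match.arg(subgroup)
  arms <- strsplit(pair, "-", fixed = TRUE)[[1]]
  if (length(arms) != 2L || !all(arms %in% names(results_by_arm))) {
    stop("pair must name two simulated arms, e.g. 'SGLT2i-SU'",
         call. = FALSE)
  }
  a <- results_by_arm[[arms[1]]]
  b <- results_by_arm[[arms[2]]]
  if (!identical(a$id, b$id)) {
    stop("arms were simulated for different individuals; pairing is ",
         "mandatory", call. = FALSE)
  }
  d <- value_at_horizon(a, endpoint, horizon_years) -
    value_at_horizon(b, endpoint, horizon_years)
  cohort <- attr(results_by_arm, "cohort")
  keep <- !is.na(d)
  if (subgroup != "overall") {
    if (is.null(cohort)) stop("no cohort attached; cannot subgroup",
                              call. = FALSE)
    keep <- keep & (cohort$cvd_history == (subgroup == "cvd"))
  }
  d <- d[keep]
  if (length(d) < 2L) {
    stop("fewer than 2 individuals with follow-up at horizon", call. = FALSE)
  }
  se <- stats::sd(d) / sqrt(length(d))
  tibble::tibble(pair = pair, endpoint = endpoint,
                 horizon_years = horizon_years, subgroup = subgroup,
                 mean_diff = mean(d), ci_lo = mean(d) - 1.96 * se,
                 ci_hi = mean(d) + 1.96 * se, n = length(d))
}

#' All pairwise contrasts as a table
#'
#' @inheritParams contrast
#' @param endpoints,horizons,subgroups vectors to cross.
#' @return tibble with one row per pair x endpoint x horizon x subgroup.
#' @export
contrast_table <- function(results_by_arm,
                           endpoints = event_names(),
                           horizons = 5,
                           subgroups = "overall") {
  pairs <- c("DPP4i-SU", "SGLT2i-SU", "SGLT2i-DPP4i")
  pairs <- pairs[vapply(strsplit(pairs, "-"), function(p)
    all(p %in% names(results_by_arm)), logical(1))]
  grid <- expand.grid(pair = pairs, endpoint = endpoints,
                      horizon_years = horizons, subgroup = subgroups,
                      stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    contrast(results_by_arm, grid$pair[i], grid$endpoint[i],
             grid$horizon_years[i], grid$subgroup[i])
  }))
}

# deterministic 32-bit-safe seed derivation for sub-streams
derive_seed <- function(seed, stream) {
  if (is.null(seed)) seed <- 0L
  as.integer((as.double(seed) * 48271 + 7919 * stream) %% 2147483647)
}
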