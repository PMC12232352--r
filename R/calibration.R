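#' Stratified development / hold-out split
#'
#' Seed-deterministic partition of a cohort into a development and a
#' hold-out set, stratified by second-line class so arm proportions are
#' preserved to within one individual per stratum.
#'
#' @param cohort a `diamicro_cohort`.
#' @param fraction hold-out fraction, strictly between 0 and 1.
#' @param seed integer seed.
#' @return list with `development` and `holdout` cohorts (disjoint,
#'   exhaustive).
#' @export
split_holdout <- function(cohort, fraction, seed) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("fraction must be strictly between 0 and 1", call. = FALSE)
  }
  set.seed(as.integer(seed))
  hold <- logical(nrow(cohort))
  for (arm in unique(cohort$second_line_class)) {
    idx <- which(cohort$second_line_class == arm)
    k <- round(length(idx) * fraction)
    hold[sample(idx, k)] <- TRUE
  }
  list(development = cohort[!hold, ], holdout = cohort[hold, ])
}

#' Mean predicted trajectories with 95% confidence bands
#'
#' Per-outcome, per-quarter mean of the predicted values across the
#' individuals still observed at that quarter, with the normal-based 95%
#' CI of the mean.
#'
#' @param results a `diamicro_results`.
#' @param outcomes outcome names (risk factors and/or events; events are
#'   summarised as per-quarter probabilities).
#' @return tibble with `outcome`, `quarter`, `mean`, `ci_lo`, `ci_hi`, `n`.
#' @export
predicted_trajectories <- function(results, outcomes = risk_factor_names()) {
  H <- results$horizon
  rows <- lapply(outcomes, function(oc) {
    M <- if (oc %in% risk_factor_names()) results$rf[, , oc, drop = FALSE]
         else results$event_prob[, , oc, drop = FALSE]
    M <- M[, , 1L, drop = TRUE]
    if (is.null(dim(M))) M <- matrix(M, nrow = 1L)
    do.call(rbind, lapply(seq_len(H), function(qc) {
      v <- M[, qc]
      v <- v[!is.na(v)]
      if (length(v) < 2L) return(NULL)
      se <- stats::sd(v) / sqrt(length(v))
      tibble::tibble(outcome = oc, quarter = qc - 1L, mean = mean(v),
                     ci_lo = mean(v) - 1.96 * se,
                     ci_hi = mean(v) + 1.96 * se, n = length(v))
    }))
  })
  do.call(rbind, rows)
}

#' Assess predicted-versus-observed agreement
#'
#' Compares an observed mean trajectory against the predicted 95% CI band
#' quarter by quarter.  Agreement at a quarter means the observed value
#' lies within `[ci_lo, ci_hi]`.  An outcome is flagged for recalibration
#' when it fails the rule: by default any single quarter outside the band
#' (`rule = "any_quarter"`); alternatively a minimum fraction of quarters
#' inside (`rule = "fraction"`, threshold `min_fraction`).
#'
#' @param predicted tibble from [predicted_trajectories()].
#' @param observed tibble with columns `outcome`, `quarter`, `value`; its
#'   quarter grid must match the predicted grid for shared outcomes.
#' @param rule flagging rule.
#' @param min_fraction minimum agreement fraction under
#'   `rule = "fraction"`.
#' @return a `calibration_report`: list with per-quarter `detail` (adds
#'   `observed` and `agree` to the predicted band) and per-outcome
#'   `summary` (`agreement_fraction`, `flagged`).
#' @export
assess_agreement <- function(predicted, observed,
                             rule = c("any_quarter", "fraction"),
                             min_fraction = 0.95) {
  rule <- match.arg(rule)
  shared <- intersect(unique(predicted$outcome), unique(observed$outcome))
  if (!length(shared)) stop("no shared outcomes", call. = FALSE)
  detail <- do.call(rbind, lapply(shared, function(oc) {
    p <- predicted[predicted$outcome == oc, ]
    o <- observed[observed$outcome == oc, ]
    if (!setequal(p$quarter, o$quarter)) {
      stop("quarter grids differ for outcome '", oc, "'", call. = FALSE)
    }
    o <- o[match(p$quarter, o$quarter), ]
    p$observed <- o$value
    p$agree <- p$observed >= p$ci_lo & p$observed <= p$ci_hi
    p
  }))
  summary <- do.call(rbind, lapply(shared, function(oc) {
    d <- detail[detail$outcome == oc, ]
    frac <- mean(d$agree)
    flagged <- if (rule == "any_quarter") any(!d$agree)
               else frac < min_fraction
    tibble::tibble(outcome = oc, agreement_fraction = frac,
                   flagged = flagged)
  }))
  structure(list(detail = detail, summary = summary, rule = rule),
            class = "calibration_report")
}

#' Estimate recalibration offset schedules
#'
#' For each flagged risk-factor outcome, recovers the additive per-quarter
#' equation offsets that reconcile predicted and observed mean
#' trajectories.  Because an offset applied at quarter `t` propagates
#' through the AR(1) dynamics, the raw mean discrepancy
#' `d_t = observed_t - predicted_t` is a geometric accumulation of the
#' underlying equation offsets; they are recovered exactly by the linear
#' deconvolution `delta_t = d_t - lag1 * d_{t-1}` (least squares with
#' exact identification, one offset per quarter), then optionally smoothed
#' with a centred moving average of width `window`.  Quarters beyond the
#' observed grid reuse the last estimated offset.
#'
#' @param equations the `risk_equations` used for the predictions (their
#'   lag-1 coefficients drive the deconvolution).
#' @param predicted,observed as in [assess_agreement()].
#' @param flagged character vector of flagged risk-factor outcomes
#'   (nonempty), e.g. `report$summary$outcome[report$summary$flagged]`.
#' @param window odd moving-average width; 1 = no smoothing.
#' @param horizon number of update quarters the schedules must cover.
#' @return named list of [offset_schedule()]s, one per flagged outcome.
#' @export
recalibrate <- function(equations, predicted, observed, flagged,
                        window = 1L, horizon = max_quarters() - 1L) {
  stopifnot(inherits(equations, "risk_equations"))
  flagged <- intersect(flagged, risk_factor_names())
  if (!length(flagged)) {
    stop("no flagged risk-factor outcomes to recalibrate", call. = FALSE)
  }
  if (window %% 2L != 1L || window < 1L) {
    stop("window must be a positive odd integer", call. = FALSE)
  }
  out <- lapply(flagged, function(oc) {
    p <- predicted[predicted$outcome == oc, ]
    o <- observed[observed$outcome == oc, ]
    o <- o[match(p$quarter, o$quarter), ]
    if (any(is.na(o$value))) {
      stop("observed grid incomplete for '", oc, "'", call. = FALSE)
    }
    ord <- order(p$quarter)
    q <- p$quarter[ord]
    d <- o$value[ord] - p$mean[ord]
    if (length(d) < window) {
      stop("fewer observed quarters than the smoothing window",
           call. = FALSE)
    }
    lam <- equations[[oc]]$lag1
    # d_0 pins the baseline (no offset at quarter 0)
    delta <- d[-1L] - lam * d[-length(d)]
    if (window > 1L) {
      sm <- stats::filter(delta, rep(1 / window, window), sides = 2)
      delta <- ifelse(is.na(sm), delta, as.numeric(sm))
    }
    qs <- q[-1L]
    full <- numeric(horizon)
    full[qs] <- delta
    if (max(qs) < horizon) full[(max(qs) + 1L):horizon] <- delta[length(delta)]
    offset_schedule(oc, full)
  })
  names(out) <- flagged
  out
}

#' Serialise a calibration report
#'
#' Writes the per-quarter detail as CSV and the per-outcome summary as
#' JSON.
#'
#' @param report a `calibration_report`.
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @export
write_calibration_report <- function(report, csv_path = NULL,
                                     json_path = NULL) {
  stopifnot(inherits(report, "calibration_report"))
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(report$detail), csv_path,
                     row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(rule = report$rule,
           summary = as.data.frame(report$summary)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
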