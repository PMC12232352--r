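#' Simulate quarter-resolution treatment pathways
#'
#' Each individual starts at quarter 0 on the metformin dual matching their
#' second-line class and evolves by a first-order Markov process: while on
#' the initial dual they leave it with the spec's per-quarter hazard and
#' sample a destination regimen; once off it they move according to the
#' spec's inter-category matrix (absorbing by default).  Administrative
#' censoring is drawn independently of regimen and arm from the per-quarter
#' censoring hazards.  Concomitant statin and blood-pressure-therapy flags
#' are independent Bernoulli draws per quarter.
#'
#' @param cohort a `diamicro_cohort` from [generate_cohort()].
#' @param spec a [transition_spec()].
#' @param seed integer seed; the simulation is deterministic given
#'   (cohort, spec, seed).
#' @return an object of class `diamicro_timelines`: a list with integer
#'   matrix `states` (individuals x 31 quarters, regimen code indices, `NA`
#'   at and after censoring), logical matrices `statin` and `bp_lowering`,
#'   integer vector `censor_quarter` (`NA` if not censored within the
#'   horizon), `id`, and `codes`.
#' @export
simulate_pathways <- function(cohort, spec, seed) {
  stopifnot(inherits(spec, "transition_spec"), nrow(cohort) >= 1L)
  set.seed(as.integer(seed))
  codes <- regimen_codes()
  n <- nrow(cohort)
  H <- max_quarters()  # 31 quarters, indices 0..30

  orig <- match(second_line_regimen(cohort$second_line_class), codes)

  # censoring quarter from the hazard schedule (independent of regimen)
  surv <- cumprod(1 - spec$censor_hazard)
  u <- stats::runif(n)
  cum_cens <- 1 - surv
  censor_quarter <- as.integer(rowSums(outer(u, cum_cens, ">")) + 1L)
  censor_quarter[censor_quarter > length(cum_cens)] <- NA_integer_

  states <- matrix(NA_integer_, n, H)
  states[, 1L] <- orig
  on_orig <- rep(TRUE, n)
  identity_inter <- is.null(spec$inter_category)
  for (q in seq_len(H - 1L)) {            # transition into quarter q
    cur <- states[, q]
    nxt <- cur
    leavers <- on_orig & stats::runif(n) < spec$leave_hazard[q]
    nl <- sum(leavers)
    if (nl > 0L) {
      nxt[leavers] <- sample.int(length(codes), nl, replace = TRUE,
                                 prob = spec$destinations[q, ])
      on_orig[leavers] <- FALSE
    }
    if (!identity_inter) {
      off <- which(!on_orig & !leavers)
      for (s in unique(cur[off])) {
        rows <- off[cur[off] == s]
        nxt[rows] <- sample.int(length(codes), length(rows), replace = TRUE,
                                prob = spec$inter_category[s, ])
      }
    }
    states[, q + 1L] <- nxt
  }

  statin <- matrix(stats::runif(n * H) < spec$statin_prevalence, n, H)
  bp <- matrix(stats::runif(n * H) < spec$bp_prevalence, n, H)

  # blank out quarters at/after censoring
  cq <- censor_quarter
  cq[is.na(cq)] <- H + 1L
  mask <- col(states) > cq  # columns are quarters + 1
  states[mask] <- NA_integer_
  statin[mask] <- NA
  bp[mask] <- NA

  structure(list(states = states, statin = statin, bp_lowering = bp,
                 censor_quarter = censor_quarter, id = cohort$id,
                 codes = codes, horizon = H, seed = as.integer(seed)),
            class = "diamicro_timelines")
}

#' Regimen-category distribution at a quarter
#'
#' Proportions over the regimen categories among individuals still
#' uncensored at `quarter`; the denominator is reported as attribute `n`
#' and column `n_at_risk`.
#'
#' @param timelines a `diamicro_timelines`.
#' @param quarter 0-based quarter index within the horizon.
#' @return tibble with `category`, `proportion`, `n_at_risk`.
#' @export
pathway_prevalence <- function(timelines, quarter) {
  stopifnot(inherits(timelines, "diamicro_timelines"))
  if (quarter < 0L || quarter >= timelines$horizon) {
    stop("quarter outside horizon", call. = FALSE)
  }
  s <- timelines$states[, quarter + 1L]
  s <- s[!is.na(s)]
  if (length(s) == 0L) {
    stop("no uncensored individuals at quarter ", quarter, " (count 0)",
         call. = FALSE)
  }
  counts <- tabulate(s, nbins = length(timelines$codes))
  out <- tibble::tibble(category = timelines$codes,
                        proportion = counts / length(s),
                        n_at_risk = length(s))
  attr(out, "n") <- length(s)
  out
}

#' Cumulative censoring by follow-up year
#'
#' @param timelines a `diamicro_timelines`.
#' @return tibble with `year` (0..7), `cum_censored` (cumulative proportion
#'   censored by the end of that year; 0 at year 0) and `available_n`
#'   (individuals still observed).
#' @export
censoring_curve <- function(timelines) {
  stopifnot(inherits(timelines, "diamicro_timelines"))
  n <- length(timelines$id)
  if (n == 0L) stop("empty timelines", call. = FALSE)
  cq <- timelines$censor_quarter
  years <- 0:7
  cum <- vapply(years, function(y) {
    if (y == 0) 0 else mean(!is.na(cq) & cq <= 4L * y)
  }, numeric(1))
  tibble::tibble(year = years, cum_censored = cum,
                 available_n = round(n * (1 - cum)))
}

#' Long-format view and CSV serialisation of timelines
#'
#' One row per (individual, observed quarter): `id`, `quarter`, `regimen`,
#' `statin`, `bp_lowering`.  Quarters at/after an individual's censoring
#' quarter are omitted.
#'
#' @param timelines a `diamicro_timelines`.
#' @return a tibble.
#' @export
as_timeline_df <- function(timelines) {
  stopifnot(inherits(timelines, "diamicro_timelines"))
  H <- timelines$horizon
  n <- length(timelines$id)
  keep <- !is.na(as.vector(timelines$states))
  tibble::tibble(
    id = rep(timelines$id, times = H)[keep],
    quarter = rep(0:(H - 1L), each = n)[keep],
    regimen = timelines$codes[as.vector(timelines$states)[keep]],
    statin = as.vector(timelines$statin)[keep],
    bp_lowering = as.vector(timelines$bp_lowering)[keep]
  )[order(rep(timelines$id, times = H)[keep]), ]
}

#' @rdname as_timeline_df
#' @param path CSV path.
#' @export
write_timelines <- function(timelines, path) {
  utils::write.csv(as.data.frame(as_timeline_df(timelines)), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname as_timeline_df
#' @export
read_timelines <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  codes <- regimen_codes()
  ids <- sort(unique(df$id))
  n <- length(ids)
  H <- max_quarters()
  states <- matrix(NA_integer_, n, H)
  statin <- matrix(NA, n, H)
  bp <- matrix(NA, n, H)
  row <- match(df$id, ids)
  colq <- df$quarter + 1L
  states[cbind(row, colq)] <- match(df$regimen, codes)
  statin[cbind(row, colq)] <- as.logical(df$statin)
  bp[cbind(row, colq)] <- as.logical(df$bp_lowering)
  last_obs <- tapply(df$quarter, df$id, max)[as.character(ids)]
  censor_quarter <- ifelse(last_obs < H - 1L, as.integer(last_obs) + 1L,
                           NA_integer_)
  structure(list(states = states, statin = statin, bp_lowering = bp,
                 censor_quarter = as.integer(censor_quarter), id = ids,
                 codes = codes, horizon = H, seed = NA_integer_),
            class = "diamicro_timelines")
}
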