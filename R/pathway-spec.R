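#' Specify quarter-resolution treatment-pathway transitions
#'
#' A `transition_spec` drives the pathway simulator: a per-quarter hazard of
#' leaving the initial second-line metformin dual, a per-quarter destination
#' distribution over regimen categories for leavers, a per-quarter
#' administrative censoring hazard (independent of regimen and arm), an
#' optional inter-category transition matrix applied to individuals no
#' longer on their initial dual (default: stay where they are), and
#' concomitant-therapy prevalences.
#'
#' Quarters are indexed 0-based up to a horizon of 31 quarters (~7.6
#' years); hazards apply to the transition *into* quarters 1..30 and
#' censoring into quarters 1..31.
#'
#' @param leave_hazard numeric length 30, per-quarter probability of
#'   leaving the initial second-line dual.
#' @param destinations 30 x 18 matrix (rows = update quarters, columns =
#'   [regimen_codes()]); each row a probability distribution over the
#'   regimen entered upon leaving second line.
#' @param censor_hazard numeric length 31, per-quarter probability of
#'   administrative censoring.
#' @param inter_category optional 18 x 18 row-stochastic matrix over
#'   [regimen_codes()] applied each quarter to individuals not on their
#'   initial dual; `NULL` means absorbing (identity).
#' @param statin_prevalence,bp_prevalence per-quarter Bernoulli prevalence
#'   of concomitant statin / blood-pressure-lowering therapy.
#' @return an object of class `transition_spec`.
#' @seealso [default_transition_spec()], [simulate_pathways()]
#' @export
transition_spec <- function(leave_hazard,
                            destinations,
                            censor_hazard,
                            inter_category = NULL,
                            statin_prevalence = 0.72,
                            bp_prevalence = 0.62) {
  codes <- regimen_codes()
  H <- max_quarters() - 1L  # 30 update steps
  stopifnot(length(leave_hazard) == H, length(censor_hazard) == H + 1L)
  if (any(leave_hazard < 0 | leave_hazard > 1) ||
      any(censor_hazard < 0 | censor_hazard > 1)) {
    stop("transition_spec: hazards must be in [0, 1]", call. = FALSE)
  }
  destinations <- as.matrix(destinations)
  if (!identical(dim(destinations), c(H, length(codes))) ||
      is.null(colnames(destinations)) ||
      !identical(colnames(destinations), codes)) {
    stop("transition_spec: destinations must be a 30 x 18 matrix with ",
         "columns regimen_codes()", call. = FALSE)
  }
  if (any(destinations < 0) || any(abs(rowSums(destinations) - 1) > 1e-8)) {
    stop("transition_spec: each destination distribution must sum to 1",
         call. = FALSE)
  }
  if (!is.null(inter_category)) {
    inter_category <- as.matrix(inter_category)
    if (!identical(dim(inter_category), c(length(codes), length(codes))) ||
        any(inter_category < 0) ||
        any(abs(rowSums(inter_category) - 1) > 1e-8)) {
      stop("transition_spec: inter_category must be an 18 x 18 ",
           "row-stochastic matrix", call. = FALSE)
    }
    dimnames(inter_category) <- list(codes, codes)
  }
  stopifnot(statin_prevalence >= 0, statin_prevalence <= 1,
            bp_prevalence >= 0, bp_prevalence <= 1)
  structure(list(leave_hazard = leave_hazard, destinations = destinations,
                 censor_hazard = censor_hazard,
                 inter_category = inter_category,
                 statin_prevalence = statin_prevalence,
                 bp_prevalence = bp_prevalence),
            class = "transition_spec")
}

#' Moment-matched default transition specification
#'
#' Deterministically calibrates the pathway transition hazards to a set of
#' printed population percentages rather than fitting to data:
#'
#' * year-1 second-line persistence among those still observed (73%),
#'   together with the year-1 class mix over the full baseline cohort
#'   (33% metformin-SU, 28% metformin-DPP4i, 7% metformin-SGLT2i) and the
#'   arm split (49.0 / 40.8 / 10.2%), via a least-squares compromise for a
#'   single per-quarter year-1 leave hazard common to the three arms
#'   (cessation is exchangeable across arms);
#' * end-of-follow-up dual mix among those still observed (16 / 12 / 4%)
#'   for the post-year-1 leave hazard;
#' * destination mixes from the year-1 proportions on metformin
#'   monotherapy (12%) and triple therapy (7%) and from the 31% on triple
#'   therapy at the end of follow-up;
#' * per-quarter censoring hazards from the available-follow-up counts by
#'   year (57 951, 46 726, 36 814, 28 170, 20 917, 14 988 and 10 035 of
#'   62 640), which imply ~84% cumulative censoring by year 7.
#'
#' @param targets optional list overriding any calibration target; see the
#'   function body for the named defaults.
#' @return a [transition_spec()].
#' @export
default_transition_spec <- function(targets = list()) {
  tg <- utils::modifyList(list(
    arms = c(SU = 0.490, DPP4i = 0.408, SGLT2i = 0.102),
    year1_persistence = 0.73,          # among still observed
    year1_mix = c(0.33, 0.28, 0.07),   # over the full baseline cohort
    end_mix = c(0.16, 0.12, 0.04),     # among still observed
    year1_mono_metformin = 0.12,       # over the full baseline cohort
    year1_triple = 0.07,               # over the full baseline cohort
    end_triple = 0.31,                 # among still observed
    available_by_year = c(57951, 46726, 36814, 28170, 20917, 14988, 10035),
    baseline_n = 62640
  ), targets)

  codes <- regimen_codes()
  H <- max_quarters() - 1L

  # censoring hazards: per-quarter within each follow-up year
  S <- tg$available_by_year / tg$baseline_n
  Sfull <- c(1, S)
  h_year <- 1 - (Sfull[-1] / Sfull[-length(Sfull)])^(1 / 4)
  censor_hazard <- rep(h_year[c(1:7, 7)], each = 4L)[seq_len(H + 1L)]

  # year-1 persistence among observed: least squares over the four targets
  S1 <- S[1]
  a <- S1 * tg$arms
  pi1 <- (sum(a * tg$year1_mix) + tg$year1_persistence) / (sum(a^2) + 1)
  s1 <- pi1^(1 / 4)
  # end-of-follow-up persistence among observed
  piE <- sum(tg$arms * tg$end_mix) / sum(tg$arms^2)
  s2 <- (piE / pi1)^(1 / (H - 4L))
  leave_hazard <- c(rep(1 - s1, 4L), rep(1 - s2, H - 4L))

  # destination distributions by band; residual categories get fixed
  # plausibility weights (no printed targets constrain them)
  L1 <- 1 - pi1
  mono1 <- (tg$year1_mono_metformin / S1) / L1
  triple1 <- (tg$year1_triple / S1) / L1
  rest1 <- 1 - mono1 - triple1
  w1 <- c(no_therapy = 0.35, met_insulin = 0.12, met_GLP1RA = 0.10,
          met_TZD = 0.06, mono_SU = 0.08, mono_insulin = 0.08,
          mono_DPP4i = 0.06, mono_SGLT2i = 0.03, mono_GLP1RA = 0.03,
          mono_TZD = 0.03, SU_insulin = 0.03, SU_TZD = 0.02,
          TZD_insulin = 0.01)
  dest1 <- stats::setNames(numeric(length(codes)), codes)
  dest1["mono_metformin"] <- mono1
  dest1["triple_or_other"] <- triple1
  dest1[names(w1)] <- rest1 * w1 / sum(w1)

  L2 <- pi1 - piE
  triple2 <- (tg$end_triple - tg$year1_triple / S1) / L2
  rest2 <- 1 - triple2
  w2 <- c(mono_metformin = 0.45, no_therapy = 0.15, met_insulin = 0.12,
          mono_insulin = 0.08, met_GLP1RA = 0.06, mono_SU = 0.04,
          mono_DPP4i = 0.03, SU_insulin = 0.03, mono_SGLT2i = 0.02,
          mono_GLP1RA = 0.01, mono_TZD = 0.005, SU_TZD = 0.003,
          TZD_insulin = 0.002)
  dest2 <- stats::setNames(numeric(length(codes)), codes)
  dest2["triple_or_other"] <- triple2
  dest2[names(w2)] <- rest2 * w2 / sum(w2)

  destinations <- rbind(
    matrix(dest1, 4L, length(codes), byrow = TRUE),
    matrix(dest2, H - 4L, length(codes), byrow = TRUE))
  colnames(destinations) <- codes

  transition_spec(leave_hazard = leave_hazard, destinations = destinations,
                  censor_hazard = censor_hazard)
}

#' Read or write a transition specification as YAML
#' @param spec a [transition_spec()].
#' @param path file path.
#' @export
write_transition_spec <- function(spec, path) {
  stopifnot(inherits(spec, "transition_spec"))
  out <- list(
    leave_hazard = spec$leave_hazard,
    destinations = list(codes = colnames(spec$destinations),
                        values = as.vector(spec$destinations)),
    censor_hazard = spec$censor_hazard,
    inter_category = if (!is.null(spec$inter_category))
      as.vector(spec$inter_category),
    statin_prevalence = spec$statin_prevalence,
    bp_prevalence = spec$bp_prevalence)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_transition_spec
#' @export
read_transition_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  codes <- raw$destinations$codes
  dest <- matrix(unlist(raw$destinations$values), ncol = length(codes),
                 dimnames = list(NULL, codes))
  inter <- NULL
  if (!is.null(raw$inter_category)) {
    inter <- matrix(unlist(raw$inter_category), length(codes),
                    dimnames = list(codes, codes))
  }
  transition_spec(unlist(raw$leave_hazard), dest, unlist(raw$censor_hazard),
                  inter, raw$statin_prevalence, raw$bp_prevalence)
}
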