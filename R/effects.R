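#' Treatment-effects registry
#'
#' Holds per-drug-class effect estimates versus no therapy: additive shifts
#' on risk-factor scales (`effect_type = "rf_shift"`, applied each quarter
#' inside the risk equations) and log hazard-ratios on event scales
#' (`effect_type = "log_hr"`, added to the per-quarter logistic linear
#' predictor).  The reference category is no therapy; any (class, target)
#' pair absent from the input is filled with a zero effect (with a
#' warning), so the registry is always complete over
#' [drug_classes()] x ([risk_factor_names()] + [event_names()]).
#'
#' @param effects a data frame with columns `drug_class`, `target`,
#'   `effect_type`, `value` and optionally `source`; may be empty.
#' @param triple_composition representative composition used when a
#'   `triple_or_other` regimen must be resolved to classes.
#' @return a tibble of class `effects_registry` covering every (class,
#'   target) pair.
#' @seealso [default_effects_registry()], [regimen_effect()]
#' @export
effects_registry <- function(effects = NULL,
                             triple_composition = c("metformin", "SU", "DPP4i")) {
  targets <- data.frame(
    target = c(risk_factor_names(), event_names()),
    kind = rep(c("rf_shift", "log_hr"),
               c(length(risk_factor_names()), length(event_names()))))
  full <- expand.grid(drug_class = drug_classes(), target = targets$target,
                      stringsAsFactors = FALSE)
  full$effect_type <- targets$kind[match(full$target, targets$target)]
  full$value <- 0
  full$source <- "default_zero"

  n_missing <- nrow(full)
  if (!is.null(effects) && nrow(effects) > 0L) {
    effects <- as.data.frame(effects)
    req <- c("drug_class", "target", "effect_type", "value")
    if (!all(req %in% names(effects))) {
      stop("effects table must have columns ",
           paste(req, collapse = ", "), call. = FALSE)
    }
    if (is.null(effects$source)) effects$source <- "user"
    for (i in seq_len(nrow(effects))) {
      e <- effects[i, ]
      key <- paste(e$drug_class, e$target)
      j <- match(key, paste(full$drug_class, full$target))
      if (is.na(j)) {
        stop("malformed effect entry: unknown (drug_class, target) = (",
             e$drug_class, ", ", e$target, ")", call. = FALSE)
      }
      if (!identical(e$effect_type, full$effect_type[j])) {
        stop("effect_type '", e$effect_type, "' inconsistent with target '",
             e$target, "' (expected '", full$effect_type[j], "')",
             call. = FALSE)
      }
      if (!is.finite(e$value)) {
        stop("non-finite effect value for (", e$drug_class, ", ", e$target,
             ")", call. = FALSE)
      }
      full$value[j] <- e$value
      full$source[j] <- as.character(e$source)
      n_missing <- n_missing - 1L
    }
  }
  if (n_missing > 0L) {
    warning(n_missing, " (drug_class, target) pairs missing from effects ",
            "config; defaulted to zero", call. = FALSE)
  }
  structure(tibble::as_tibble(full),
            triple_composition = triple_composition,
            class = c("effects_registry", class(tibble::tibble())))
}

#' Load a treatment-effects registry from a flat CSV config
#'
#' Columns: `drug_class`, `target`, `effect_type` (`rf_shift` or `log_hr`),
#' `value`, `source`.
#'
#' @param path CSV path, or a data frame.
#' @inheritParams effects_registry
#' @export
load_effects <- function(path, triple_composition = c("metformin", "SU", "DPP4i")) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  effects_registry(df, triple_composition = triple_composition)
}

#' Default (illustrative) treatment-effects registry
#'
#' Ships point effects whose signs and rough magnitudes follow the
#' published meta-analytic literature on glucose-lowering drug classes:
#' all classes lower HbA1c versus no therapy (SGLT2i and GLP1-RA more than
#' DPP4i); SGLT2i lower BMI, SBP, and the hazards of heart-failure
#' hospitalisation and end-stage kidney disease; sulphonylureas and insulin
#' raise body weight and hypoglycaemia hazard.  The values are
#' **non-authoritative placeholders**: risk-factor shifts are expressed
#' per quarter on the equation scale (with the default lag-1 coefficient of
#' 0.9 the implied steady-state level shift is 10x the per-quarter value)
#' and are intended for qualitative, direction-level use.
#'
#' @return an `effects_registry`.
#' @export
default_effects_registry <- function() {
  # per-quarter rf shifts; steady-state shift = value / (1 - lag1)
  rf <- rbind(
    data.frame(drug_class = "metformin", target = "hba1c", value = -0.10),
    data.frame(drug_class = "SU",        target = "hba1c", value = -0.08),
    data.frame(drug_class = "DPP4i",     target = "hba1c", value = -0.06),
    data.frame(drug_class = "SGLT2i",    target = "hba1c", value = -0.09),
    data.frame(drug_class = "GLP1RA",    target = "hba1c", value = -0.10),
    data.frame(drug_class = "TZD",       target = "hba1c", value = -0.08),
    data.frame(drug_class = "insulin",   target = "hba1c", value = -0.12),
    data.frame(drug_class = "metformin", target = "bmi",   value = -0.05),
    data.frame(drug_class = "SU",        target = "bmi",   value = 0.10),
    data.frame(drug_class = "SGLT2i",    target = "bmi",   value = -0.10),
    data.frame(drug_class = "GLP1RA",    target = "bmi",   value = -0.15),
    data.frame(drug_class = "TZD",       target = "bmi",   value = 0.20),
    data.frame(drug_class = "insulin",   target = "bmi",   value = 0.20),
    data.frame(drug_class = "SGLT2i",    target = "sbp",   value = -0.40),
    data.frame(drug_class = "SGLT2i",    target = "egfr",  value = 0.03)
  )
  rf$effect_type <- "rf_shift"
  hr <- rbind(
    data.frame(drug_class = "SGLT2i",  target = "hf_hospitalisation",
               value = -0.35),
    data.frame(drug_class = "SGLT2i",  target = "eskd", value = -0.40),
    data.frame(drug_class = "SGLT2i",  target = "eye_disease", value = -0.10),
    data.frame(drug_class = "SU",      target = "hypoglycaemia", value = 0.90),
    data.frame(drug_class = "insulin", target = "hypoglycaemia", value = 1.20)
  )
  hr$effect_type <- "log_hr"
  tab <- rbind(rf, hr)
  tab$source <- "illustrative_literature_signs"
  suppressWarnings(effects_registry(tab))
}

#' Combined effect of a regimen on a target versus no therapy
#'
#' Component-class effects combine additively on the transformed scale
#' (risk-factor scale for `rf_shift` targets, log-hazard scale for
#' `log_hr` targets).  `no_therapy` maps to 0; `triple_or_other` uses the
#' registry's representative composition.  A user-supplied `combine` hook
#' may replace the additive rule.
#'
#' @param regimen character vector of regimen codes.
#' @param target a single risk-factor or event name.
#' @param registry an `effects_registry`.
#' @param combine function reducing a numeric vector of component effects
#'   to one number; default `sum`.
#' @return numeric vector of combined effects, one per regimen.
#' @examples
#' reg <- default_effects_registry()
#' regimen_effect("met_SGLT2i", "hba1c", reg)  # metformin + SGLT2i shifts
#' @export
regimen_effect <- function(regimen, target, registry, combine = sum) {
  stopifnot(inherits(registry, "effects_registry"), length(target) == 1L)
  if (!target %in% registry$target) {
    stop("unknown target '", target, "'", call. = FALSE)
  }
  sub <- registry[registry$target == target, ]
  eff <- stats::setNames(sub$value, sub$drug_class)
  comps <- regimen_components(
    regimen, triple_composition = attr(registry, "triple_composition"))
  vapply(comps, function(cl) {
    if (length(cl) == 0L) 0 else combine(unname(eff[cl]))
  }, numeric(1))
}

# all-zero registry without the missing-entry warning (internal default)
zero_effects_registry <- function() {
  suppressWarnings(effects_registry())
}

# fast path: effect of every regimen code on every target, as a matrix
regimen_effect_matrix <- function(registry, targets) {
  codes <- regimen_codes()
  out <- vapply(targets, function(tg) regimen_effect(codes, tg, registry),
                numeric(length(codes)))
  rownames(out) <- codes
  out
}
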