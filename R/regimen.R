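#' Glucose-lowering regimen taxonomy
#'
#' Regimens are categorical codes over drug-class combinations: no therapy;
#' seven monotherapies; nine named dual therapies; and a single
#' `triple_or_other` category collecting triple therapies and any other
#' combination.  The three metformin duals `met_SU`, `met_DPP4i` and
#' `met_SGLT2i` are the second-line regimens compared by the simulator.
#'
#' @return `regimen_codes()` returns the character vector of all valid
#'   regimen codes; `second_line_classes()` the three second-line drug
#'   classes; `drug_classes()` all modelled drug classes.
#' @examples
#' regimen_codes()
#' regimen_components("met_SU")
#' @export
regimen_codes <- function() {
  c("no_therapy",
    paste0("mono_", drug_classes()),
    "met_SU", "met_DPP4i", "met_SGLT2i", "met_GLP1RA", "met_TZD",
    "met_insulin", "SU_TZD", "SU_insulin", "TZD_insulin",
    "triple_or_other")
}

#' @rdname regimen_codes
#' @export
drug_classes <- function() {
  c("metformin", "SU", "DPP4i", "SGLT2i", "GLP1RA", "TZD", "insulin")
}

#' @rdname regimen_codes
#' @export
second_line_classes <- function() c("SU", "DPP4i", "SGLT2i")

#' Drug classes composing a regimen code
#'
#' Resolves a regimen code to the drug classes it contains.  The
#' `triple_or_other` category has no single composition; a representative
#' composition (default metformin + SU + DPP4i, the most prevalent classes)
#' is used wherever a composition is required, e.g. when combining
#' per-class treatment effects.
#'
#' @param regimen character vector of regimen codes.
#' @param triple_composition drug classes standing in for `triple_or_other`.
#' @return a list (one element per input) of character vectors of classes.
#' @export
regimen_components <- function(regimen,
                               triple_composition = c("metformin", "SU", "DPP4i")) {
  stopifnot(all(regimen %in% regimen_codes()))
  stopifnot(all(triple_composition %in% drug_classes()))
  lapply(regimen, function(r) {
    if (r == "no_therapy") return(character(0))
    if (r == "triple_or_other") return(triple_composition)
    if (startsWith(r, "mono_")) return(sub("^mono_", "", r))
    parts <- strsplit(r, "_", fixed = TRUE)[[1]]
    parts[parts == "met"] <- "metformin"
    parts
  })
}

#' @rdname regimen_components
#' @param second_line_class one of `second_line_classes()`.
#' @return `second_line_regimen()` returns the metformin dual code for a
#'   second-line class, e.g. `"met_SU"` for `"SU"`.
#' @export
second_line_regimen <- function(second_line_class) {
  stopifnot(all(second_line_class %in% second_line_classes()))
  paste0("met_", second_line_class)
}

#' Modelled outcomes
#'
#' @return `risk_factor_names()`: the nine clinical risk factors advanced by
#'   the risk engine (HbA1c in %, BMI in kg/m2, SBP/DBP in mm Hg, HDL, LDL,
#'   total cholesterol and non-fasting triglycerides in mg/dL, eGFR in
#'   mL/min/1.73m2).  `event_names()`: the modelled complications, including
#'   all-cause death.
#' @export
risk_factor_names <- function() {
  c("hba1c", "bmi", "sbp", "dbp", "hdl", "ldl",
    "total_cholesterol", "triglycerides", "egfr")
}

#' @rdname risk_factor_names
#' @export
event_names <- function() {
  c("hypoglycaemia", "mi", "unstable_angina", "stroke",
    "hf_hospitalisation", "lea", "eskd", "eye_disease", "all_cause_death")
}

#' @rdname risk_factor_names
#' @export
recurrent_events <- function() {
  c("hypoglycaemia", "mi", "unstable_angina", "stroke")
}

#' @rdname risk_factor_names
#' @export
absorbing_events <- function() c("eskd", "all_cause_death")

# maximum simulation horizon: 31 quarters (~7.6 years)
max_quarters <- function() 31L
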