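#' HbA1c unit conversion (NGSP percent vs IFCC mmol/mol)
#'
#' IFCC master equation: mmol/mol = 10.929 x (% - 2.15).  For display the
#' mmol/mol value is conventionally rounded to the nearest integer;
#' `round` controls this.  The inverse conversion is exact (un-rounded).
#'
#' @param pct HbA1c in NGSP percent; must be positive.
#' @param round round the converted value to the nearest integer
#'   (display convention)?
#' @return HbA1c in IFCC mmol/mol.
#' @examples
#' hba1c_pct_to_mmolmol(7.9)   # 63
#' hba1c_mmolmol_to_pct(hba1c_pct_to_mmolmol(7.9, round = FALSE))  # 7.9
#' @export
hba1c_pct_to_mmolmol <- function(pct, round = TRUE) {
  if (any(!is.finite(pct)) || any(pct <= 0)) {
    stop("HbA1c (%) must be positive and finite", call. = FALSE)
  }
  out <- 10.929 * (pct - 2.15)
  if (round) round(out) else out
}

#' @rdname hba1c_pct_to_mmolmol
#' @param mmolmol HbA1c in IFCC mmol/mol; must be positive.
#' @export
hba1c_mmolmol_to_pct <- function(mmolmol) {
  if (any(!is.finite(mmolmol)) || any(mmolmol <= 0)) {
    stop("HbA1c (mmol/mol) must be positive and finite", call. = FALSE)
  }
  mmolmol / 10.929 + 2.15
}
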