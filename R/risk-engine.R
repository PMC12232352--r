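#' Advance risk factors by one quarter
#'
#' Applies the AR(1) risk equations to move every risk factor from quarter
#' `quarter - 1` to `quarter`.  Expected mode is fully deterministic and
#' consumes no random numbers; stochastic mode adds Gaussian residuals.
#' Outputs are clipped at each equation's physiologic floor; the number of
#' clipped entries is attached as attribute `n_clipped`.
#'
#' @param state named numeric vector over [risk_factor_names()] (one
#'   individual) or a numeric matrix with those columns (one row per
#'   individual).
#' @param profile data frame with one row per individual: `age`, `sex`,
#'   `years_since_diagnosis`, `cvd_history`.
#' @param regimen regimen code(s), recycled to the number of individuals.
#' @param equations a `risk_equations` list (possibly with attached
#'   offsets, see [apply_offsets()]).
#' @param registry an `effects_registry`; its `rf_shift` entries supply the
#'   additive regimen effects.
#' @param quarter 1-based index of the quarter being entered; drives the
#'   time term and the offset schedule.
#' @param statin,bp_lowering logical concomitant-therapy flags for the
#'   quarter.
#' @param mode `"expected"` (default) or `"stochastic"`.
#' @param seed optional seed used only in stochastic mode.
#' @return updated state in the same shape as `state`.
#' @export
update_risk_factors <- function(state, profile, regimen, equations,
                                registry = zero_effects_registry(),
                                quarter = 1L,
                                statin = FALSE, bp_lowering = FALSE,
                                mode = c("expected", "stochastic"),
                                seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(equations, "risk_equations"))
  vec_in <- !is.matrix(state)
  if (vec_in) state <- matrix(state, 1L, dimnames = list(NULL, names(state)))
  rf <- risk_factor_names()
  missing_f <- setdiff(rf, colnames(state))
  if (length(missing_f)) {
    stop("state is missing risk factor(s): ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  }
  n <- nrow(state)
  regimen <- rep_len(regimen, n)
  statin <- rep_len(statin, n)
  bp_lowering <- rep_len(bp_lowering, n)
  if (mode == "stochastic" && !is.null(seed)) set.seed(as.integer(seed))

  eff <- regimen_effect_matrix(registry, rf)
  reg_idx <- match(regimen, regimen_codes())
  male <- as.numeric(profile$sex == "male")

  out <- state[, rf, drop = FALSE]
  n_clipped <- 0L
  for (f in rf) {
    eq <- equations[[f]]
    x <- eq$intercept + eq$lag1 * state[, f] +
      eq$age * profile$age + eq$sex_male * male +
      eq$years_since_diagnosis * profile$years_since_diagnosis +
      eq$cvd_history * as.numeric(profile$cvd_history) +
      eq$statin * as.numeric(statin) +
      eq$bp_lowering * as.numeric(bp_lowering) +
      eq$time * quarter +
      eff[reg_idx, f]
    if (!is.null(eq$offsets)) x <- x + eq$offsets[quarter]
    if (mode == "stochastic" && eq$resid_sd > 0) {
      x <- x + stats::rnorm(n, 0, eq$resid_sd)
    }
    clipped <- x < eq$floor
    n_clipped <- n_clipped + sum(clipped)
    out[, f] <- pmax(x, eq$floor)
  }
  if (vec_in) out <- stats::setNames(out[1L, ], rf)
  attr(out, "n_clipped") <- n_clipped
  out
}
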