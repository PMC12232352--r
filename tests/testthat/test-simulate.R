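# Worked 3-quarter example: one individual on metformin-SU throughout,
# a single non-trivial AR equation for HbA1c, a hypoglycaemia model with a
# prior-count term, and an SU effect on both pathways.  Expected values are
# hand-computed below by plain arithmetic.
worked_setup <- function() {
  co <- tiny_cohort(1L, arm = "SU", hba1c = 8)
  tl <- manual_timelines(co, censor_quarter = 3L)
  eqs <- identity_equations()
  eqs$hba1c <- risk_equation("hba1c", intercept = 0.8, lag1 = 0.9)
  tab <- rbind(
    data.frame(drug_class = "SU", target = "hba1c",
               effect_type = "rf_shift", value = -0.2),
    data.frame(drug_class = "SU", target = "hypoglycaemia",
               effect_type = "log_hr", value = 1.0))
  reg <- suppressWarnings(effects_registry(tab))
  ms <- flat_event_models(-10)
  ms$hypoglycaemia <- event_model("hypoglycaemia", intercept = -3,
                                  coef = c(hba1c = 0.1), prior_coef = 0.5,
                                  recurrent = TRUE)
  list(co = co, tl = tl, eqs = eqs, reg = reg, ms = ms)
}

test_that("run_individual matches the hand-computed forward recursion", {
  s <- worked_setup()
  res <- run_individual(s$co, s$tl, s$eqs, s$ms, s$reg)
  # hand computation:
  h0 <- 8
  p0 <- stats::plogis(-3 + 0.1 * h0 + 1.0)            # quarter 0
  h1 <- 0.8 + 0.9 * h0 - 0.2                          # = 7.8
  p1 <- stats::plogis(-3 + 0.1 * h1 + 1.0 + 0.5 * p0) # quarter 1
  h2 <- 0.8 + 0.9 * h1 - 0.2                          # = 7.62
  p2 <- stats::plogis(-3 + 0.1 * h2 + 1.0 + 0.5 * (p0 + p1))
  expect_equal(res$rf[, "hba1c"], c(h0, h1, h2))
  expect_equal(res$event_prob[, "hypoglycaemia"], c(p0, p1, p2))
  expect_equal(unname(res$cum_inc[3, "hypoglycaemia"]),
               1 - (1 - p0) * (1 - p1) * (1 - p2))
  expect_equal(unname(res$expected_counts["hypoglycaemia"]), p0 + p1 + p2)
  # simulation stops at the censoring quarter
  expect_equal(res$quarters, 0:2)
})

test_that("zero horizon yields empty trajectories and zero incidence", {
  co <- tiny_cohort(1L)
  tl <- manual_timelines(co, censor_quarter = 0L)
  res <- run_individual(co, tl, identity_equations(), flat_event_models(),
                        zero_registry())
  expect_equal(nrow(res$rf), 0L)
  expect_equal(nrow(res$cum_inc), 0L)
})

test_that("mismatched timeline and profile are rejected", {
  co <- tiny_cohort(1L, arm = "SU")
  tl <- manual_timelines(co, regimen = "met_DPP4i")
  expect_error(run_individual(co, tl, identity_equations(),
                              flat_event_models(), zero_registry()),
               "second-line class")
})

test_that("arm-blind inputs give identical trajectories across arms", {
  co <- tiny_cohort(6L, arm = rep(c("SU", "DPP4i", "SGLT2i"), 2))
  tl <- manual_timelines(co)
  res <- run_cohort(co, tl, identity_equations(), flat_event_models(-4),
                    zero_registry())
  # zero-effect registry + intercept-only models: probabilities identical
  # for every individual regardless of arm
  p <- res$event_prob[, 1, "mi"]
  expect_true(all(p == p[1]))
  expect_true(all(res$event_prob[1, , "mi"] ==
                    res$event_prob[4, , "mi"], na.rm = TRUE))
})

test_that("counterfactual copies share pathway and differ only by class", {
  co <- generate_cohort(default_cohort_spec(300L), seed = 8)
  tl <- simulate_pathways(co, default_transition_spec(), seed = 18)
  # identical effects for the three classes => bit-identical results
  tab <- do.call(rbind, lapply(second_line_classes(), function(cl)
    data.frame(drug_class = cl, target = "hba1c", effect_type = "rf_shift",
               value = -0.3)))
  reg_same <- suppressWarnings(effects_registry(tab))
  cf <- run_counterfactuals(co, tl, default_risk_equations(),
                            default_event_models(), reg_same)
  expect_identical(cf$SU$rf, cf$DPP4i$rf)
  expect_identical(cf$SU$event_prob, cf$SGLT2i$event_prob)
  ct <- contrast_table(cf, endpoints = c("eskd", "hba1c"), horizons = c(1, 5))
  expect_true(all(ct$mean_diff == 0))
  expect_true(all(ct$ci_lo == 0 & ct$ci_hi == 0))
})

test_that("a more negative HbA1c effect dominates the trajectory", {
  co <- tiny_cohort(1L, arm = "SU")
  tl <- manual_timelines(co)
  tab <- rbind(
    data.frame(drug_class = "DPP4i", target = "hba1c",
               effect_type = "rf_shift", value = -0.2),
    data.frame(drug_class = "SGLT2i", target = "hba1c",
               effect_type = "rf_shift", value = -0.5))
  reg <- suppressWarnings(effects_registry(tab))
  eqs <- identity_equations()
  eqs$hba1c <- risk_equation("hba1c", intercept = 0.8, lag1 = 0.9)
  cf <- run_counterfactuals(co, tl, eqs, flat_event_models(), reg)
  sg <- cf$SGLT2i$rf[1, , "hba1c"]
  dp <- cf$DPP4i$rf[1, , "hba1c"]
  expect_true(all(sg[-1] < dp[-1]))
})

test_that("label swap reproduces the negated contrast", {
  co <- generate_cohort(default_cohort_spec(400L), seed = 9)
  # everyone persists on their dual so that every quarter is a
  # counterfactual quarter and the swap identity is exact
  tl <- manual_timelines(co)
  reg <- default_effects_registry()
  cf <- run_counterfactuals(co, tl, default_risk_equations(),
                            default_event_models(), reg)
  a <- contrast(cf, "SGLT2i-SU", "eskd", 5)
  b <- contrast(cf, "SU-SGLT2i", "eskd", 5)
  expect_equal(a$mean_diff, -b$mean_diff)
  expect_equal(a$ci_lo, -b$ci_hi)
  # independent re-simulation with swapped effect labels
  swapped <- reg
  i_su <- swapped$drug_class == "SU"
  i_sg <- swapped$drug_class == "SGLT2i"
  orig_su <- reg$value[i_su]
  swapped$value[i_su] <- reg$value[i_sg]
  swapped$value[i_sg] <- orig_su
  cf2 <- run_counterfactuals(co, tl, default_risk_equations(),
                             default_event_models(), swapped)
  a2 <- contrast(cf2, "SGLT2i-SU", "eskd", 5)
  expect_equal(a2$mean_diff, -a$mean_diff, tolerance = 1e-10)
})

test_that("aggregate_predictions computes normal-based CIs", {
  co <- tiny_cohort(2L)
  tl <- manual_timelines(co)
  ms <- flat_event_models(-4)
  res <- run_cohort(co, tl, identity_equations(), ms, zero_registry())
  # identical individuals: CI width 0
  ag <- aggregate_predictions(res, "eskd", 5)
  expect_equal(ag$ci_lo, ag$mean)
  expect_equal(ag$ci_hi, ag$mean)
  # two-value closed form: values 0 and 1 => mean .5, hw 1.96 * .5 / sqrt(2)
  res2 <- res
  res2$rf[1, 21, "hba1c"] <- 0
  res2$rf[2, 21, "hba1c"] <- 1
  ag2 <- aggregate_predictions(res2, "hba1c", 5)
  expect_equal(ag2$mean, 0.5)
  expect_equal(ag2$ci_hi - ag2$mean, 1.96 * stats::sd(c(0, 1)) / sqrt(2))
  expect_error(aggregate_predictions(run_cohort(
    tiny_cohort(1L), manual_timelines(tiny_cohort(1L)),
    identity_equations(), ms, zero_registry()), "eskd", 5),
    "fewer than 2")
})

test_that("aggregation matches independent recomputation from raw output", {
  co <- generate_cohort(default_cohort_spec(200L), seed = 10)
  tl <- simulate_pathways(co, default_transition_spec(), seed = 20)
  res <- run_cohort(co, tl, default_risk_equations(), default_event_models(),
                    default_effects_registry())
  ag <- aggregate_predictions(res, "eye_disease", 3)
  # oracle: recompute per-individual cumulative incidences directly
  cq <- res$censor_quarter
  keep <- is.na(cq) | cq > 12
  p <- res$event_prob[keep, 1:12, "eye_disease"]
  v <- 1 - apply(1 - p, 1, prod)
  expect_equal(ag$mean, mean(v))
  expect_equal(ag$n, length(v))
  expect_equal(ag$ci_hi, mean(v) + 1.96 * stats::sd(v) / sqrt(length(v)))
})

test_that("CVD subgroups partition the overall contrast", {
  co <- generate_cohort(default_cohort_spec(500L), seed = 12)
  tl <- simulate_pathways(co, default_transition_spec(), seed = 21)
  cf <- run_counterfactuals(co, tl, default_risk_equations(),
                            default_event_models(),
                            default_effects_registry())
  overall <- contrast(cf, "SGLT2i-SU", "eskd", 5, "overall")
  cvd <- contrast(cf, "SGLT2i-SU", "eskd", 5, "cvd")
  nocvd <- contrast(cf, "SGLT2i-SU", "eskd", 5, "no_cvd")
  expect_equal(cvd$n + nocvd$n, overall$n)
  expect_equal((cvd$mean_diff * cvd$n + nocvd$mean_diff * nocvd$n) /
                 overall$n, overall$mean_diff)
  expect_error(contrast(cf, "SGLT2i-GLP1RA", "eskd", 5), "pair")
})
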