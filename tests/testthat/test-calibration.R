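test_that("split_holdout is a stratified, seed-deterministic partition", {
  co <- generate_cohort(default_cohort_spec(100L), seed = 14)
  parts <- split_holdout(co, 0.5, seed = 1)
  expect_equal(nrow(parts$development) + nrow(parts$holdout), 100L)
  expect_length(intersect(parts$development$id, parts$holdout$id), 0L)
  expect_setequal(c(parts$development$id, parts$holdout$id), co$id)
  for (arm in second_line_classes()) {
    n_arm <- sum(co$second_line_class == arm)
    n_hold <- sum(parts$holdout$second_line_class == arm)
    expect_lte(abs(n_hold - n_arm * 0.5), 1)
  }
  parts2 <- split_holdout(co, 0.5, seed = 1)
  expect_identical(parts$holdout$id, parts2$holdout$id)
  expect_error(split_holdout(co, 0, seed = 1), "strictly between")
  expect_error(split_holdout(co, 1, seed = 1), "strictly between")
})

make_pred <- function(outcome = "bmi", quarters = 0:30, mean = 30,
                      se = 0.1) {
  tibble::tibble(outcome = outcome, quarter = quarters,
                 mean = mean, ci_lo = mean - 1.96 * se,
                 ci_hi = mean + 1.96 * se, n = 1000L)
}

test_that("agreement flags follow the predicted CI band", {
  pred <- make_pred()
  obs_exact <- tibble::tibble(outcome = "bmi", quarter = 0:30, value = 30)
  rep1 <- assess_agreement(pred, obs_exact)
  expect_equal(rep1$summary$agreement_fraction, 1)
  expect_false(rep1$summary$flagged)
  obs_out <- tibble::tibble(outcome = "bmi", quarter = 0:30,
                            value = 30 + 10 * 1.96 * 0.1)
  rep2 <- assess_agreement(pred, obs_out)
  expect_equal(rep2$summary$agreement_fraction, 0)
  expect_true(rep2$summary$flagged)
  # one excursion flags under any-quarter but not under a 90% fraction rule
  obs_one <- obs_exact
  obs_one$value[15] <- 40
  expect_true(assess_agreement(pred, obs_one)$summary$flagged)
  expect_false(assess_agreement(pred, obs_one, rule = "fraction",
                                min_fraction = 0.9)$summary$flagged)
  expect_error(assess_agreement(pred, obs_exact[1:10, ]), "grids differ")
})

test_that("agreement rule attains ~95% per-quarter coverage under truth", {
  # observed values drawn from the predictive distribution of the mean
  set.seed(33)
  pred <- make_pred(se = 0.25)
  hits <- replicate(300, {
    obs <- tibble::tibble(outcome = "bmi", quarter = 0:30,
                          value = stats::rnorm(31, 30, 0.25))
    r <- assess_agreement(pred, obs)
    r$summary$agreement_fraction
  })
  expect_gt(mean(hits), 0.93)
  expect_lt(mean(hits), 0.97)
})

test_that("recalibrate recovers constant and zero discrepancies exactly", {
  eqs <- default_risk_equations()
  lam <- eqs$bmi$lag1
  # observed = predicted + accumulated constant equation offset c
  c0 <- 0.8
  d <- c0 * cumsum(lam^(0:29))  # discrepancy accumulated through the AR lag
  pred <- make_pred(quarters = 0:30, mean = 30)
  obs <- tibble::tibble(outcome = "bmi", quarter = 0:30,
                        value = 30 + c(0, d))
  sch <- recalibrate(eqs, pred, obs, flagged = "bmi")
  expect_equal(sch$bmi$offsets, rep(c0, 30), tolerance = 1e-10)
  # zero discrepancy => zero offsets; idempotence of a matched system
  obs0 <- tibble::tibble(outcome = "bmi", quarter = 0:30, value = 30)
  sch0 <- recalibrate(eqs, pred, obs0, flagged = "bmi")
  expect_equal(sch0$bmi$offsets, rep(0, 30))
  expect_error(recalibrate(eqs, pred, obs, flagged = character(0)),
               "no flagged")
  expect_error(recalibrate(eqs, pred[1:2, ], obs[1:2, ], flagged = "bmi",
                           window = 5), "window")
})

test_that("injected linear drift on BMI is recovered from synthetic data", {
  # ground truth: equation-level offsets 0.05 * t injected into the
  # data-generating run; recovery from hold-out means via deconvolution
  co <- generate_cohort(default_cohort_spec(10000L), seed = 25)
  tl <- simulate_pathways(co, default_transition_spec(), seed = 26)
  eqs <- default_risk_equations()
  truth <- 0.05 * (1:30)
  eqs_drift <- apply_offsets(eqs, offset_schedule("bmi", truth))
  pred <- predicted_trajectories(
    run_cohort(co, tl, eqs, default_event_models(),
               default_effects_registry()), outcomes = "bmi")
  obs_run <- run_cohort(co, tl, eqs_drift, default_event_models(),
                        default_effects_registry(), mode = "stochastic",
                        seed = 27)
  obs_traj <- predicted_trajectories(obs_run, outcomes = "bmi")
  report <- assess_agreement(pred, tibble::tibble(
    outcome = obs_traj$outcome, quarter = obs_traj$quarter,
    value = obs_traj$mean))
  expect_true(report$summary$flagged[report$summary$outcome == "bmi"])
  sch <- recalibrate(eqs, pred,
                     tibble::tibble(outcome = obs_traj$outcome,
                                    quarter = obs_traj$quarter,
                                    value = obs_traj$mean),
                     flagged = "bmi")
  err <- sch$bmi$offsets - truth
  rmse <- sqrt(mean(err^2))
  expect_lt(rmse, 0.2 * sqrt(mean(truth^2)))
  expect_lt(max(abs(err)), 0.2)
  # applying the recovered offsets restores agreement on the same data
  eqs_fixed <- apply_offsets(eqs, sch$bmi)
  pred_fixed <- predicted_trajectories(
    run_cohort(co, tl, eqs_fixed, default_event_models(),
               default_effects_registry()), outcomes = "bmi")
  resid <- pred_fixed$mean - obs_traj$mean
  expect_lt(max(abs(resid)), 0.15)
})

test_that("recovery error shrinks with hold-out size", {
  run_rmse <- function(n, seed) {
    co <- generate_cohort(default_cohort_spec(n), seed = seed)
    tl <- simulate_pathways(co, default_transition_spec(), seed = seed + 1)
    eqs <- default_risk_equations()
    truth <- rep(0.3, 30)
    eqs_drift <- apply_offsets(eqs, offset_schedule("bmi", truth))
    pred <- predicted_trajectories(
      run_cohort(co, tl, eqs, default_event_models(),
                 default_effects_registry()), outcomes = "bmi")
    obs <- predicted_trajectories(
      run_cohort(co, tl, eqs_drift, default_event_models(),
                 default_effects_registry(), mode = "stochastic",
                 seed = seed + 2), outcomes = "bmi")
    sch <- recalibrate(eqs, pred,
                       tibble::tibble(outcome = obs$outcome,
                                      quarter = obs$quarter,
                                      value = obs$mean), flagged = "bmi")
    sqrt(mean((sch$bmi$offsets - truth)^2))
  }
  expect_lt(run_rmse(10000L, 40), run_rmse(1000L, 41))
})

test_that("calibration report serialises to CSV and JSON", {
  pred <- make_pred()
  obs <- tibble::tibble(outcome = "bmi", quarter = 0:30, value = 30)
  rep <- assess_agreement(pred, obs)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_calibration_report(rep, csv, js)
  expect_true(file.exists(csv) && file.exists(js))
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$summary$agreement_fraction, 1)
})
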