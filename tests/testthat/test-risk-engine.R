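profile1 <- function() data.frame(age = 60, sex = "female",
                                  years_since_diagnosis = 5,
                                  cvd_history = FALSE)

state1 <- function() {
  stats::setNames(c(8, 30, 130, 80, 45, 90, 170, 150, 90),
                  risk_factor_names())
}

test_that("identity equations with no therapy are a fixed point", {
  out <- update_risk_factors(state1(), profile1(), "no_therapy",
                             identity_equations(), zero_registry())
  expect_equal(unname(out[risk_factor_names()]),
               unname(state1()[risk_factor_names()]))
})

test_that("regimen effects enter additively on the factor scale", {
  tab <- data.frame(drug_class = "SGLT2i", target = "hba1c",
                    effect_type = "rf_shift", value = -0.5)
  reg <- suppressWarnings(effects_registry(tab))
  out <- update_risk_factors(state1(), profile1(), "met_SGLT2i",
                             identity_equations(), reg)
  expect_equal(unname(out["hba1c"]), 8 - 0.5)
  expect_equal(unname(out["bmi"]), 30)
})

test_that("expected mode is deterministic and consumes no RNG", {
  set.seed(123)
  before <- .Random.seed
  out1 <- update_risk_factors(state1(), profile1(), "met_SU",
                              default_risk_equations(),
                              default_effects_registry())
  expect_identical(.Random.seed, before)
  out2 <- update_risk_factors(state1(), profile1(), "met_SU",
                              default_risk_equations(),
                              default_effects_registry())
  expect_identical(out1, out2)
})

test_that("AR(1) trajectories converge to the closed-form stationary mean", {
  eqs <- identity_equations()
  eqs$hba1c <- risk_equation("hba1c", intercept = 0.8, lag1 = 0.9)
  # starting at the stationary mean 0.8 / (1 - 0.9) = 8: one step is a no-op
  out <- update_risk_factors(state1(), profile1(), "no_therapy", eqs,
                             zero_registry())
  expect_equal(unname(out["hba1c"]), 8.0)
  # starting far away: within 1e-6 of the stationary mean by quarter 200
  st <- state1()
  st["hba1c"] <- 20
  for (q in 1:200) {
    st <- update_risk_factors(st, profile1(), "no_therapy", eqs,
                              zero_registry(), quarter = q)
  }
  expect_lt(abs(st[["hba1c"]] - 8.0), 1e-6)
})

test_that("offsets are linear and match a brute-force forward recursion", {
  lam <- 0.7
  eqs <- identity_equations()
  eqs$bmi <- risk_equation("bmi", intercept = 9, lag1 = lam)
  a <- 0.3 * sin(1:30)
  b <- 0.1 * (1:30)
  run_traj <- function(offsets) {
    eo <- apply_offsets(eqs, offset_schedule("bmi", offsets))
    st <- state1()
    out <- numeric(30)
    for (q in 1:30) {
      st <- update_risk_factors(st, profile1(), "no_therapy", eo,
                                zero_registry(), quarter = q)
      out[q] <- st[["bmi"]]
    }
    out
  }
  # independent oracle: plain scalar AR recursion
  oracle <- function(offsets) {
    x <- numeric(31)
    x[1] <- 30
    for (q in 1:30) x[q + 1] <- 9 + lam * x[q] + offsets[q]
    x[-1]
  }
  expect_equal(run_traj(a), oracle(a), tolerance = 1e-12)
  expect_equal(run_traj(a + b), oracle(a + b), tolerance = 1e-12)
  # linearity of the offset response
  base <- run_traj(rep(0, 30))
  expect_equal(run_traj(a + b) - base,
               (run_traj(a) - base) + (run_traj(b) - base),
               tolerance = 1e-10)
})

test_that("offset attachment is idempotent, zero is a no-op, horizon checked", {
  eqs <- default_risk_equations()
  zero <- offset_schedule("bmi", rep(0, 30))
  e1 <- apply_offsets(eqs, zero)
  out0 <- update_risk_factors(state1(), profile1(), "no_therapy", eqs,
                              zero_registry())
  out1 <- update_risk_factors(state1(), profile1(), "no_therapy", e1,
                              zero_registry())
  expect_equal(out0, out1)
  const <- offset_schedule("bmi", rep(1, 30))
  e2 <- apply_offsets(apply_offsets(eqs, const), const)  # replace, not add
  out2 <- update_risk_factors(state1(), profile1(), "no_therapy", e2,
                              zero_registry())
  expect_equal(unname(out2["bmi"] - out0["bmi"]), 1)
  expect_error(apply_offsets(eqs, offset_schedule("bmi", rep(1, 10))),
               "horizon")
})

test_that("predictions are clipped at physiologic floors and clips counted", {
  eqs <- identity_equations()
  eqs$egfr <- risk_equation("egfr", intercept = -200, lag1 = 1, floor = 0)
  out <- update_risk_factors(state1(), profile1(), "no_therapy", eqs,
                             zero_registry())
  expect_equal(unname(out["egfr"]), 0)
  expect_equal(attr(out, "n_clipped"), 1L)
})

test_that("a missing equation is reported by factor name", {
  eqs <- identity_equations()
  expect_error(risk_equations(eqs[setdiff(risk_factor_names(), "egfr")]),
               "egfr")
})

test_that("stochastic mode adds residual noise with the configured sd", {
  eqs <- identity_equations()
  eqs$hba1c <- risk_equation("hba1c", intercept = 0, lag1 = 1,
                             resid_sd = 0.5, floor = -Inf)
  st <- matrix(rep(state1(), each = 4000), 4000,
               dimnames = list(NULL, risk_factor_names()))
  prof <- profile1()[rep(1, 4000), ]
  out <- update_risk_factors(st, prof, "no_therapy", eqs, zero_registry(),
                             mode = "stochastic", seed = 77)
  expect_equal(stats::sd(out[, "hba1c"]), 0.5, tolerance = 0.05)
  expect_equal(mean(out[, "hba1c"]), 8, tolerance = 0.05)
})

test_that("risk-equation CSV config round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_risk_equations(default_risk_equations(), path)
  back <- read_risk_equations(path)
  expect_equal(back$egfr$time, default_risk_equations()$egfr$time)
  out0 <- update_risk_factors(state1(), profile1(), "met_SU",
                              default_risk_equations(),
                              default_effects_registry())
  out1 <- update_risk_factors(state1(), profile1(), "met_SU", back,
                              default_effects_registry())
  expect_equal(out0, out1)
})
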