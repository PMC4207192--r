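# Vehicle-relative changes, the control distribution, and the 2-SD rule.

test_that("relative change arithmetic and undefined markers", {
  expect_equal(relative_change(25, 50), -50)
  expect_equal(relative_change(50, 50), 0)
  expect_equal(relative_change(900, 600), 50)
  expect_true(is.na(relative_change(40, 0)))
  expect_true(is.na(relative_change(NA_real_, 50)))
  m <- make_metrics(amplitude = c(50, 40, 30, 20), tiq = rep(600, 4))
  expect_equal(
    relative_change(m[2, ], m[1, ], metric = "amplitude"), -20)
})

test_that("control distribution: closed-form SD, and guards", {
  # two control experiments whose amplitude changes are -4% and +4%
  m1 <- make_metrics(amplitude = c(50, 48, 48, 48), tiq = rep(600, 4))
  m2 <- make_metrics(amplitude = c(50, 52, 52, 52), tiq = rep(600, 4))
  ctrl <- build_control_distribution(list(m1, m2))
  amp1 <- ctrl[ctrl$metric == "amplitude_mean" & ctrl$phase_label == "conc1", ]
  expect_equal(amp1$mean, 0)
  expect_equal(amp1$sd, sqrt(32), tolerance = 1e-12) # 5.657%
  expect_equal(amp1$n, 2)
  expect_error(build_control_distribution(list(m1)), "at least 2")
  m3 <- make_metrics(amplitude = c(50, 48, 48), tiq = rep(600, 3),
                     concentrations = c(0.3, 3))
  expect_error(build_control_distribution(list(m1, m3)), "mismatched")
})

test_that("2-SD positivity is two-sided, strict, and centred on the control mean", {
  expect_true(call_positive(-11, 0, 5))
  expect_false(call_positive(10, 0, 5)) # boundary: strict inequality
  expect_false(call_positive(-6, -3, 2)) # |(-6) - (-3)| = 3 <= 4
  expect_true(is.na(call_positive(NA_real_, 0, 5)))
  # symmetry: reflecting a change about the control mean preserves the call
  set.seed(8)
  for (i in 1:50) {
    mu <- runif(1, -10, 10)
    sdv <- runif(1, 0.5, 10)
    x <- rnorm(1, mu, 3 * sdv)
    expect_identical(call_positive(x, mu, sdv),
                     call_positive(2 * mu - x, mu, sdv))
  }
})

ctrl_flat <- local({
  # four controls, amplitude sd ~ 2.2%, tiq sd ~ 1.3% around 0
  ms <- lapply(list(c(-2, 1, 3), c(2, -1, -3), c(1, 2, -1), c(-1, -2, 1)),
               function(d) {
    make_metrics(amplitude = c(50, 50 * (1 + d / 100)),
                 tiq = c(600, 600 * (1 - d / 200)))
  })
  build_control_distribution(ms)
})

test_that("compound calls: OR rule, max dose vs clinical dose, empty window", {
  # positive TIQ change only at the top dose (clinically irrelevant)
  m <- make_metrics(amplitude = c(50, 50, 50, 50),
                    tiq = c(600, 600, 600, 320))
  call_top <- call_compound(m, ctrl_flat, max_exposure = 0.001)
  expect_true(call_top$positive_at_max_dose)
  expect_false(call_top$positive_at_clinical_dose) # negative-by-window
  expect_true(call_top$window_empty)
  # same compound with an exposure admitting the lowest two doses
  call_win <- call_compound(m, ctrl_flat, max_exposure = 0.1)
  expect_identical(call_win$clinical_phase, "conc2")
  expect_false(call_win$positive_at_clinical_dose)
  # OR rule: amplitude positive, tiq negative => compound positive
  m_or <- make_metrics(amplitude = c(50, 50, 50, 25),
                       tiq = c(600, 600, 600, 600))
  expect_true(call_compound(m_or, ctrl_flat,
                            max_exposure = 1)$positive_at_clinical_dose)
  # all changes well within 1 SD => both calls negative
  m_neg <- make_metrics(amplitude = rep(50, 4), tiq = rep(600, 4))
  call_neg <- call_compound(m_neg, ctrl_flat, max_exposure = 1)
  expect_false(call_neg$positive_at_max_dose)
  expect_false(call_neg$positive_at_clinical_dose)
})

test_that("making one more metric positive never turns a positive compound negative", {
  base_amp <- c(50, 50, 50, 50)
  base_tiq <- c(600, 600, 600, 320) # tiq positive at top dose
  m0 <- make_metrics(amplitude = base_amp, tiq = base_tiq)
  stopifnot(call_compound(m0, ctrl_flat, max_exposure = 1)$positive_at_max_dose)
  for (phase in 2:4) {
    amp <- base_amp
    amp[phase] <- 20 # force the amplitude metric positive at this phase
    m1 <- make_metrics(amplitude = amp, tiq = base_tiq)
    call1 <- call_compound(m1, ctrl_flat, max_exposure = 1)
    expect_true(call1$positive_at_max_dose)
  }
})

test_that("undefined vehicle metrics propagate as not-assessable with a warning", {
  m <- make_metrics(amplitude = c(NA, 50, 50, 25), tiq = c(600, 600, 600, 300))
  expect_warning(call <- call_compound(m, ctrl_flat, max_exposure = 1),
                 "not assessable")
  expect_true(call$not_assessable)
  expect_true(call$positive_at_max_dose) # tiq still drives the call
})

test_that("dose-lowering planner flags compounds positive at the lowest dose", {
  m_low <- make_metrics(amplitude = c(50, 25, 25, 25), tiq = rep(600, 4))
  call_low <- call_compound(m_low, ctrl_flat, max_exposure = 1)
  plan <- needs_dose_lowering(call_low)
  expect_true(plan$rerun_required)
  expect_equal(plan$suggested_concentrations, c(0.03, 0.3, 3))
  m_hi <- make_metrics(amplitude = c(50, 50, 50, 25), tiq = rep(600, 4))
  plan_hi <- needs_dose_lowering(call_compound(m_hi, ctrl_flat,
                                               max_exposure = 1))
  expect_false(plan_hi$rerun_required)
  expect_null(plan_hi$suggested_concentrations)
})

test_that("control self-test: positives under the empirical rule occur at a tail-like rate", {
  des <- experiment_design(phase_duration = 600)
  cfg <- generator_config()
  cohort <- simulate_control_cohort(6, des, cfg, seed = 404)
  metrics <- lapply(cohort, quantify_experiment)
  ctrl <- build_control_distribution(metrics)
  calls <- vapply(metrics, function(m) {
    isTRUE(call_compound(m, ctrl)$positive_at_max_dose)
  }, logical(1))
  rate <- mean(calls)
  expect_gte(rate, 0)
  expect_lte(rate, 1)
  message(sprintf(
    "control self-test: %.0f%% of controls called positive by their own 2-SD rule",
    100 * rate))
})
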