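# Trace generator: configuration guards, renewal/amplitude calibration,
# determinism, and the Hill concentration-response scaling.

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(noise_sd = -1), "noise_sd")
  expect_error(generator_config(baseline_pressure = NaN), "baseline_pressure")
  expect_error(generator_config(mean_interval = 30, event_duration = 40),
               "mean_interval")
  expect_error(generator_config(event_duration = 0), "event_duration")
  expect_error(generator_config(drift_per_phase = 1), "drift_per_phase")
  expect_error(generator_config(interval_shape = -2), "interval_shape")
})

test_that("stationary renewal calibration: mean event count is duration/mean_interval", {
  cfg <- generator_config()
  n_phases <- 600
  counts <- vapply(seq_len(n_phases), function(i) {
    nrow(simulate_phase(cfg, 900, seed = 5000 + i, events_only = TRUE)$annotations)
  }, numeric(1))
  expected <- 900 / cfg$mean_interval
  expect_lt(abs(mean(counts) - expected) / expected, 0.02)
})

test_that("annotated amplitudes are calibrated to event_amplitude", {
  cfg <- generator_config()
  amps <- unlist(lapply(1:400, function(i) {
    simulate_phase(cfg, 900, seed = 9000 + i, events_only = TRUE)$annotations$amplitude
  }))
  mc_bound <- 3 * cfg$event_amplitude * cfg$amplitude_cv / sqrt(length(amps))
  expect_gt(length(amps), 1500)
  expect_lt(abs(mean(amps) - cfg$event_amplitude), mc_bound)
})

test_that("identical seeds reproduce phases bit-for-bit", {
  cfg <- generator_config()
  a <- simulate_phase(cfg, 300, seed = 77)
  b <- simulate_phase(cfg, 300, seed = 77)
  expect_identical(a$trace$samples, b$trace$samples)
  expect_identical(a$annotations, b$annotations)
  c <- simulate_phase(cfg, 300, seed = 78)
  expect_false(identical(a$trace$samples, c$trace$samples))
})

test_that("degenerate generator: zero amplitude and noise gives a flat, event-free trace", {
  cfg <- generator_config(noise_sd = 0, event_amplitude = 0, blip_rate = 0)
  ph <- simulate_phase(cfg, 120, seed = 1)
  expect_equal(nrow(ph$annotations), 0)
  expect_true(all(ph$trace$samples == cfg$baseline_pressure))
  expect_equal(length(ph$trace$samples), 120 * 100)
})

test_that("Hill scaling: null dose, half-maximal point, saturation, monotonicity", {
  cfg <- generator_config()
  m <- drug_effect_model("event_amplitude", emax = 3, ec50 = 2, hill_n = 1)
  expect_identical(apply_drug_effect(cfg, m, 0), cfg)
  expect_equal(apply_drug_effect(cfg, m, 2)$event_amplitude,
               cfg$event_amplitude * 2)
  # saturation: approach emax within 0.1%
  sat <- apply_drug_effect(cfg, m, 2e6)$event_amplitude / cfg$event_amplitude
  expect_lt(abs(sat - 3) / 3, 0.001)
  # monotone in concentration for random valid models, both directions
  set.seed(31)
  for (i in 1:20) {
    par <- sample(c("event_amplitude", "mean_interval"), 1)
    # cap emax so an inhibitory interval effect cannot force overlap
    emax_hi <- if (par == "mean_interval") 3 else 8
    mm <- drug_effect_model(
      par,
      emax = runif(1, 1.2, emax_hi), ec50 = runif(1, 0.05, 40),
      hill_n = runif(1, 0.4, 3),
      direction = sample(c("excitatory", "inhibitory"), 1)
    )
    concs <- sort(runif(8, 0, 100))
    vals <- vapply(concs, function(cc) {
      apply_drug_effect(cfg, mm, cc)[[mm$parameter]]
    }, numeric(1))
    diffs <- diff(vals)
    expect_true(all(diffs >= -1e-12) || all(diffs <= 1e-12))
  }
})

test_that("inhibitory effects keep parameters positive; infeasible scalings error", {
  cfg <- generator_config()
  m <- drug_effect_model("event_amplitude", emax = 100, ec50 = 0.1,
                         direction = "inhibitory")
  out <- apply_drug_effect(cfg, m, 1e4)
  expect_gt(out$event_amplitude, 0)
  # shrinking the interval below the event duration must be refused
  bad <- drug_effect_model("mean_interval", emax = 10, ec50 = 0.1,
                           direction = "inhibitory")
  expect_error(apply_drug_effect(cfg, bad, 100), "mean_interval")
})

test_that("null-drug experiments drift multiplicatively across phases", {
  des <- experiment_design(phase_duration = 300)
  cfg <- generator_config()
  n_exp <- 25
  per_phase <- matrix(NA_real_, n_exp, 5)
  for (i in seq_len(n_exp)) {
    ex <- simulate_experiment(des, cfg, model = NULL, seed = 400 + i)
    per_phase[i, ] <- vapply(ex$phases, function(ph) {
      mean(ph$annotations$amplitude)
    }, numeric(1))
  }
  observed <- colMeans(per_phase, na.rm = TRUE) / cfg$event_amplitude
  expected <- (1 + cfg$drift_per_phase)^(0:4)
  # Monte-Carlo bound: ~2 events/300-s phase, cv 0.1, 25 experiments
  expect_true(all(abs(observed - expected) < 3 * 0.1 / sqrt(2 * n_exp)))
})

test_that("a strong motility-suppressing model lowers event counts monotonically", {
  cfg <- generator_config()
  model <- drug_effect_model("mean_interval", emax = 6, ec50 = 1,
                             direction = "excitatory")
  concs <- c(0.3, 3, 30)
  mean_counts <- vapply(concs, function(cc) {
    cfg_c <- apply_drug_effect(cfg, model, cc)
    mean(vapply(1:100, function(i) {
      nrow(simulate_phase(cfg_c, 900, seed = 100 * cc + i,
                          events_only = TRUE)$annotations)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_counts) <= 0))
})

test_that("control cohorts require n >= 2 and reproduce under a fixed seed", {
  des <- experiment_design(phase_duration = 120)
  cfg <- generator_config()
  expect_error(simulate_control_cohort(1, des, cfg), ">= 2")
  a <- simulate_control_cohort(2, des, cfg, seed = 5)
  b <- simulate_control_cohort(2, des, cfg, seed = 5)
  expect_identical(a[[1]]$phases[[1]]$trace$samples,
                   b[[1]]$phases[[1]]$trace$samples)
  expect_identical(a[[2]]$phases[[5]]$annotations,
                   b[[2]]$phases[[5]]$annotations)
})

test_that("drift-free control relative changes are centred at zero", {
  des <- experiment_design(phase_duration = 600)
  cfg <- generator_config(drift_per_phase = 0)
  cohort <- simulate_control_cohort(8, des, cfg, seed = 91)
  ctrl <- build_control_distribution(cohort)
  amp <- ctrl[ctrl$metric == "amplitude_mean", ]
  sem <- amp$sd / sqrt(amp$n)
  expect_true(all(abs(amp$mean) < 2.5 * sem))
})
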