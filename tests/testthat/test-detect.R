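# Event detection and per-phase metrics: baseline estimation, hysteresis,
# merging, metric identities, and oracle equivalence on noise-free traces.

test_that("baseline of a constant trace is the constant", {
  tr <- make_pulse_trace(duration = 60, baseline = 5)
  expect_equal(estimate_baseline(tr), 5)
  expect_error(estimate_baseline(cpmcassay:::new_pressure_trace(
    numeric(0), 100, "vehicle", 0)), "empty")
})

test_that("baseline estimation recovers the configured resting pressure", {
  cfg <- generator_config()
  params <- detection_params()
  errs <- vapply(1:100, function(i) {
    ph <- simulate_phase(cfg, 300, seed = 3000 + i)
    estimate_baseline(ph, params) - cfg$baseline_pressure
  }, numeric(1))
  expect_true(all(abs(errs) < cfg$noise_sd))
})

test_that("a trace with no quiescent plateau triggers the baseline warning", {
  set.seed(4)
  vals <- c(rep(5, 800), runif(9200, 50, 250))
  tr <- cpmcassay:::new_pressure_trace(sample(vals), 100, "vehicle", 0)
  expect_warning(estimate_baseline(tr, detection_params(smooth_window = 0)),
                 "plateau")
})

test_that("hysteresis detection: flat traces, sub-threshold bumps, exact pulse counts", {
  params <- detection_params()
  flat <- make_pulse_trace(duration = 300)
  expect_equal(nrow(detect_cpmcs(flat, params)), 0)
  # a bump above the offset threshold but below the onset threshold is no event
  bump <- make_pulse_trace(duration = 300, onsets = 100, amplitude = 8,
                           width = 40)
  expect_equal(nrow(detect_cpmcs(bump, params)), 0)
  # three well-separated pulses are three events with accurate amplitudes
  tr <- make_pulse_trace(duration = 600, onsets = c(50, 250, 450),
                         amplitude = 50, width = 40)
  ev <- detect_cpmcs(tr, params)
  expect_equal(nrow(ev), 3)
  expect_true(all(abs(ev$amplitude - 50) < 0.5))
  expect_true(all(abs(ev$peak_time - c(70, 270, 470)) < 1))
  expect_false(any(ev$truncated))
})

test_that("events separated by less than merge_gap merge into one", {
  fs <- 100
  n <- 300 * fs
  p <- rep(5, n)
  # two 20-s square pulses whose below-offset gap is 1 s < merge_gap = 2 s
  p[(100 * fs):(120 * fs)] <- 55
  p[(121 * fs):(141 * fs)] <- 60
  tr <- cpmcassay:::new_pressure_trace(p, fs, "vehicle", 0)
  ev <- detect_cpmcs(tr, detection_params(smooth_window = 0))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$amplitude, 55, tolerance = 1e-6)
  # with a wide gap they stay separate
  p2 <- rep(5, n)
  p2[(100 * fs):(120 * fs)] <- 55
  p2[(130 * fs):(150 * fs)] <- 60
  tr2 <- cpmcassay:::new_pressure_trace(p2, fs, "vehicle", 0)
  expect_equal(nrow(detect_cpmcs(tr2, detection_params(smooth_window = 0))), 2)
})

test_that("events shorter than min_event_duration are dropped", {
  fs <- 100
  p <- rep(5, 300 * fs)
  p[(100 * fs):(102 * fs)] <- 55 # 2-s spike
  tr <- cpmcassay:::new_pressure_trace(p, fs, "vehicle", 0)
  expect_equal(nrow(detect_cpmcs(tr, detection_params(smooth_window = 0))), 0)
})

test_that("noise-free synthetic phases are detected in exact agreement with annotations", {
  cfg <- generator_config(noise_sd = 0, blip_rate = 0)
  ph <- simulate_phase(cfg, 900, seed = 12, fit_events_within = TRUE)
  ev <- detect_cpmcs(ph)
  a <- ph$annotations
  expect_equal(nrow(ev), nrow(a))
  expect_true(all(abs(ev$amplitude - a$amplitude) / a$amplitude < 0.01))
  expect_true(all(abs(ev$onset - a$onset) < cfg$event_duration / 2))
})

test_that("metrics of a flat phase are all-quiescent", {
  tr <- make_pulse_trace(duration = 900)
  params <- detection_params()
  m <- phase_metrics(tr, detect_cpmcs(tr, params), params)
  expect_equal(m$frequency, 0)
  expect_equal(m$tiq, 900)
  expect_equal(m$auc, 0)
  expect_true(is.na(m$ti_mean))
  expect_true(is.na(m$amplitude_mean))
})

test_that("six identical pulses at 150-s spacing give frequency 6 and TI 150", {
  tr <- make_pulse_trace(duration = 900, onsets = 20 + 150 * (0:5),
                         amplitude = 50, width = 40)
  params <- detection_params()
  ev <- detect_cpmcs(tr, params)
  m <- phase_metrics(tr, ev, params)
  expect_equal(m$frequency, 6)
  expect_equal(m$ti_mean, 150, tolerance = 1e-6)
  expect_equal(m$amplitude_mean, 50, tolerance = 0.01)
  # single event: TI undefined
  tr1 <- make_pulse_trace(duration = 900, onsets = 400)
  m1 <- phase_metrics(tr1, detect_cpmcs(tr1, params), params)
  expect_equal(m1$frequency, 1)
  expect_true(is.na(m1$ti_mean))
})

test_that("time in and out of the quiescence band partition the phase exactly", {
  cfg <- generator_config()
  params <- detection_params()
  for (seed in c(3, 14, 159)) {
    ph <- simulate_phase(cfg, 450, seed = seed)
    q <- quantify_phase(ph, params)
    s <- cpmcassay:::smoothed_samples(ph$trace, params)
    above <- sum(s > q$baseline + params$quiescence_band) / 100
    expect_equal(q$metrics$tiq + above, 450)
  }
})

test_that("AUC is non-negative, additive over sub-intervals, and pulse-monotone", {
  params <- detection_params(smooth_window = 0)
  tr <- make_pulse_trace(duration = 600, onsets = c(100, 420), width = 40)
  m_full <- phase_metrics(tr, detect_cpmcs(tr, params), params)
  expect_gte(m_full$auc, 0)
  # additivity: split at a sample boundary, halves share the boundary sample
  half <- function(idx, lab) {
    cpmcassay:::new_pressure_trace(tr$samples[idx], 100, lab, 0)
  }
  n <- length(tr$samples)
  t1 <- half(1:(n / 2 + 1), "a")
  t2 <- half((n / 2 + 1):n, "b")
  auc_of <- function(t) {
    s <- t$samples
    y <- pmax(s - 5, 0) # shared, known baseline for the additivity identity
    (sum(y) - (y[1] + y[length(y)]) / 2) * 0.01
  }
  expect_equal(auc_of(t1) + auc_of(t2), auc_of(tr))
  # adding an extra pulse never decreases frequency or AUC
  tr_more <- make_pulse_trace(duration = 600, onsets = c(100, 260, 420),
                              width = 40)
  m_more <- phase_metrics(tr_more, detect_cpmcs(tr_more, params), params)
  expect_gte(m_more$frequency, m_full$frequency)
  expect_gte(m_more$auc, m_full$auc)
})

test_that("events from a different trace are refused", {
  params <- detection_params()
  tr <- make_pulse_trace(duration = 300, onsets = 100)
  ev <- detect_cpmcs(tr, params)
  short <- make_pulse_trace(duration = 60)
  expect_error(phase_metrics(short, ev, params), "belong")
})

test_that("detection parameter guards enforce the hysteresis ordering", {
  expect_error(detection_params(onset_threshold = 4, offset_threshold = 5),
               "onset_threshold")
  expect_error(detection_params(offset_threshold = 3, quiescence_band = 4),
               "onset_threshold")
  expect_error(detection_params(min_event_duration = 0), "min_event_duration")
})
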