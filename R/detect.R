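# CPMC event detection and per-phase motility metrics.
#
# Detection runs on a lightly smoothed copy of the 100-Hz trace: the
# baseline is a low percentile of the smoothed samples, an event opens when
# smoothed pressure exceeds baseline + onset_threshold and closes when it
# falls below baseline + offset_threshold (hysteresis), nearby events are
# merged and short ones dropped. All five per-phase metrics are measured on
# the same smoothed signal so their mutual identities (e.g. TIQ + time above
# the quiescence band = phase duration) hold exactly.

#' Detection parameters for CPMC quantification
#'
#' @param baseline_percentile Percentile of the smoothed samples used as the
#'   baseline estimate (dimensionless, in (0, 100)).
#' @param onset_threshold Event-opening threshold above baseline, mmHg.
#' @param offset_threshold Event-closing threshold above baseline, mmHg.
#'   Must be below `onset_threshold` (hysteresis).
#' @param quiescence_band Half-band above baseline within which the tissue
#'   counts as quiescent, mmHg.
#' @param min_event_duration Events shorter than this are dropped, s.
#' @param merge_gap Events separated by less than this are merged, s.
#' @param smooth_window Centred moving-average window applied before
#'   detection, s. The default 1 s suppresses sample-level sensor noise
#'   while leaving the tens-of-seconds CPMC waveform essentially untouched.
#' @return A `detection_params` object.
#' @export
detection_params <- function(baseline_percentile = 10,
                             onset_threshold = 10,
                             offset_threshold = 5,
                             quiescence_band = 5,
                             min_event_duration = 5,
                             merge_gap = 2,
                             smooth_window = 1) {
  check_scalar(baseline_percentile, "baseline_percentile", lower = 0,
               upper = 100, strict_lower = TRUE)
  if (baseline_percentile >= 100) {
    stop("`baseline_percentile` must be < 100", call. = FALSE)
  }
  check_scalar(onset_threshold, "onset_threshold", lower = 0,
               strict_lower = TRUE)
  check_scalar(offset_threshold, "offset_threshold", lower = 0,
               strict_lower = TRUE)
  check_scalar(quiescence_band, "quiescence_band", lower = 0,
               strict_lower = TRUE)
  if (!(onset_threshold > offset_threshold &&
        offset_threshold >= quiescence_band)) {
    stop("need onset_threshold > offset_threshold >= quiescence_band",
         call. = FALSE)
  }
  check_scalar(min_event_duration, "min_event_duration", lower = 0,
               strict_lower = TRUE)
  check_scalar(merge_gap, "merge_gap", lower = 0)
  check_scalar(smooth_window, "smooth_window", lower = 0)
  structure(
    list(baseline_percentile = baseline_percentile,
         onset_threshold = onset_threshold,
         offset_threshold = offset_threshold,
         quiescence_band = quiescence_band,
         min_event_duration = min_event_duration,
         merge_gap = merge_gap,
         smooth_window = smooth_window),
    class = "detection_params"
  )
}

# Centred moving average with windows truncated at the trace edges.
moving_average <- function(x, k) {
  k <- as.integer(k)
  if (k <= 1L) return(x)
  n <- length(x)
  half <- k %/% 2L
  cs <- c(0, cumsum(x))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

smoothed_samples <- function(trace, params) {
  k <- max(1L, round(params$smooth_window * trace$sample_rate))
  moving_average(trace$samples, k)
}

as_trace <- function(x) {
  if (inherits(x, "simulated_phase")) x$trace else x
}

#' Estimate the resting baseline pressure of a phase
#'
#' Returns the `baseline_percentile`-th percentile of the (smoothed) phase
#' samples. If fewer than 5% of samples lie within the quiescence band of
#' the estimate, the phase has no resolvable quiescent plateau (e.g. one
#' long contraction) and the estimate is flagged with a warning as likely
#' biased high.
#'
#' @param trace A `pressure_trace` (or `simulated_phase`).
#' @param params A [detection_params()].
#' @return Baseline pressure, mmHg.
#' @export
estimate_baseline <- function(trace, params = detection_params()) {
  trace <- as_trace(trace)
  stopifnot(inherits(trace, "pressure_trace"))
  if (length(trace$samples) == 0L) {
    stop("cannot estimate a baseline from an empty trace", call. = FALSE)
  }
  s <- smoothed_samples(trace, params)
  b <- as.numeric(stats::quantile(s, params$baseline_percentile / 100,
                                  names = FALSE))
  quiescent_frac <- mean(abs(s - b) <= params$quiescence_band)
  if (quiescent_frac < 0.05) {
    warning(sprintf(
      "only %.1f%% of samples lie near the baseline estimate; ",
      100 * quiescent_frac),
      "no quiescent plateau - baseline is likely biased high",
      call. = FALSE)
  }
  b
}

#' Detect CPMC events in a pressure trace
#'
#' Hysteresis detection on the smoothed trace: an event opens when pressure
#' first exceeds `baseline + onset_threshold`, closes when it falls below
#' `baseline + offset_threshold`; events separated by less than `merge_gap`
#' are merged, then events shorter than `min_event_duration` are dropped.
#' Events truncated at a phase edge are kept when they meet the duration
#' criterion within the phase, and carry `truncated = TRUE`. Amplitude is
#' the peak excursion above the estimated baseline.
#'
#' @param trace A `pressure_trace` (or `simulated_phase`).
#' @param params A [detection_params()].
#' @return A `cpmc_events` data frame (`onset`, `offset`, `peak_time`,
#'   `amplitude`, `truncated`), time-ordered and non-overlapping, with the
#'   baseline estimate attached as attribute `"baseline"`.
#' @export
detect_cpmcs <- function(trace, params = detection_params()) {
  trace <- as_trace(trace)
  stopifnot(inherits(trace, "pressure_trace"))
  s <- smoothed_samples(trace, params)
  b <- estimate_baseline(trace, params)
  fs <- trace$sample_rate
  dt <- 1 / fs
  tt <- (seq_along(s) - 1) * dt
  on_thr <- b + params$onset_threshold
  off_thr <- b + params$offset_threshold

  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      peak_time = numeric(0), amplitude = numeric(0),
                      truncated = logical(0))
  above <- s >= off_thr
  if (!any(above)) {
    return(structure(empty, baseline = b, class = c("cpmc_events",
                                                    "data.frame")))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_start <- starts[r$values]
  run_end <- ends[r$values]

  events <- list()
  for (j in seq_along(run_start)) {
    idx <- run_start[j]:run_end[j]
    over_on <- idx[s[idx] > on_thr]
    if (length(over_on) == 0L) next # bump above off-threshold only: no event
    onset_i <- over_on[1L]
    events[[length(events) + 1L]] <- c(onset_i, run_end[j])
  }
  if (length(events) == 0L) {
    return(structure(empty, baseline = b, class = c("cpmc_events",
                                                    "data.frame")))
  }
  ev <- do.call(rbind, events)

  # Merge events whose inter-event gap is shorter than merge_gap.
  merged <- list(ev[1, ])
  for (j in seq_len(nrow(ev))[-1]) {
    prev <- merged[[length(merged)]]
    gap <- (ev[j, 1] - prev[2]) * dt
    if (gap < params$merge_gap) {
      merged[[length(merged)]] <- c(prev[1], ev[j, 2])
    } else {
      merged[[length(merged) + 1L]] <- ev[j, ]
    }
  }
  ev <- do.call(rbind, merged)

  onset_idx <- ev[, 1]
  offset_idx <- ev[, 2]
  dur <- (offset_idx - onset_idx + 1L) * dt
  keep <- dur >= params$min_event_duration
  onset_idx <- onset_idx[keep]
  offset_idx <- offset_idx[keep]
  if (length(onset_idx) == 0L) {
    return(structure(empty, baseline = b, class = c("cpmc_events",
                                                    "data.frame")))
  }
  n <- length(s)
  peak_idx <- mapply(function(i0, i1) {
    i0 + which.max(s[i0:i1]) - 1L
  }, onset_idx, offset_idx)
  amp <- s[peak_idx] - b
  truncated <- (onset_idx == 1L & above[1L]) | (offset_idx == n)
  out <- data.frame(
    onset = tt[onset_idx],
    offset = tt[offset_idx] + dt, # half-open [onset, offset)
    peak_time = tt[peak_idx],
    amplitude = amp,
    truncated = truncated
  )
  structure(out, baseline = b, class = c("cpmc_events", "data.frame"))
}

#' Compute the five per-phase CPMC motility metrics
#'
#' Frequency (events per phase), mean inter-complex onset interval (TI, s;
#' `NA` when fewer than two events), time in quiescence (TIQ, s: total time
#' with smoothed pressure at or below `baseline + quiescence_band`), mean
#' event amplitude (mmHg; edge-truncated events are excluded because their
#' peak may be clipped; `NA` when no measurable event), and the trapezoidal
#' area under the baseline-subtracted, zero-clipped pressure curve over the
#' whole phase (AUC, mmHg·s).
#'
#' @param trace A `pressure_trace` (or `simulated_phase`).
#' @param events Events from [detect_cpmcs()] on the same trace.
#' @param params The [detection_params()] used for detection.
#' @return A one-row data frame: `phase_label`, `frequency`, `ti_mean`,
#'   `tiq`, `amplitude_mean`, `auc`.
#' @export
phase_metrics <- function(trace, events, params = detection_params()) {
  trace <- as_trace(trace)
  stopifnot(inherits(trace, "pressure_trace"))
  if (!inherits(events, "cpmc_events")) {
    stop("`events` must come from detect_cpmcs()", call. = FALSE)
  }
  if (nrow(events) > 0 &&
      (max(events$offset) > trace$duration + 1e-9 || min(events$onset) < 0)) {
    stop("`events` do not belong to this trace (times outside the phase)",
         call. = FALSE)
  }
  s <- smoothed_samples(trace, params)
  b <- attr(events, "baseline")
  if (is.null(b)) b <- estimate_baseline(trace, params)
  dt <- 1 / trace$sample_rate

  frequency <- nrow(events)
  ti_mean <- if (frequency >= 2) mean(diff(events$onset)) else NA_real_
  tiq <- sum(s <= b + params$quiescence_band) * dt
  measurable <- events$amplitude[!events$truncated]
  amplitude_mean <- if (length(measurable) > 0) mean(measurable) else NA_real_
  y <- pmax(s - b, 0)
  auc <- (sum(y) - (y[1] + y[length(y)]) / 2) * dt
  data.frame(
    phase_label = trace$phase_label,
    frequency = frequency,
    ti_mean = ti_mean,
    tiq = tiq,
    amplitude_mean = amplitude_mean,
    auc = auc,
    stringsAsFactors = FALSE
  )
}

#' Detect events and compute metrics for one phase
#'
#' @param phase A `simulated_phase` or `pressure_trace`.
#' @param params A [detection_params()].
#' @return List with `baseline`, `events`, and `metrics`.
#' @export
quantify_phase <- function(phase, params = detection_params()) {
  trace <- as_trace(phase)
  events <- detect_cpmcs(trace, params)
  list(baseline = attr(events, "baseline"),
       events = events,
       metrics = phase_metrics(trace, events, params))
}

#' Quantify every phase of an experiment
#'
#' @param experiment A `cpmc_experiment` from [simulate_experiment()].
#' @param params A [detection_params()].
#' @return Data frame of per-phase metrics with `phase_index` and
#'   `concentration` columns prepended.
#' @export
quantify_experiment <- function(experiment, params = detection_params()) {
  stopifnot(inherits(experiment, "cpmc_experiment"))
  rows <- lapply(seq_along(experiment$phases), function(i) {
    m <- quantify_phase(experiment$phases[[i]], params)$metrics
    cbind(data.frame(phase_index = i,
                     concentration =
                       experiment$design$phases$concentration[i]),
          m)
  })
  do.call(rbind, rows)
}

#' Simulate and quantify a cohort of baseline phases
#'
#' The calibration workhorse: simulates `n_phases` independent vehicle
#' phases at `config`, quantifies each with `params`, and summarises the
#' cohort mean, SD and SEM of the five metrics. TI and amplitude are
#' averaged over the phases where they are defined.
#'
#' @param n_phases Number of phases (the reference cohort used 99 tissues).
#' @param config A [generator_config()].
#' @param params A [detection_params()].
#' @param seed Integer seed.
#' @param duration Phase duration, s.
#' @return List with `metrics` (per-phase data frame) and `summary`
#'   (data frame: `metric`, `mean`, `sd`, `sem`, `n`).
#' @export
baseline_cohort_stats <- function(n_phases = 99,
                                  config = generator_config(),
                                  params = detection_params(),
                                  seed = NULL,
                                  duration = 900) {
  metrics <- with_seed(seed, {
    phase_seeds <- sample.int(.Machine$integer.max, n_phases)
    do.call(rbind, lapply(seq_len(n_phases), function(i) {
      ph <- simulate_phase(config, duration = duration, seed = phase_seeds[i])
      quantify_phase(ph, params)$metrics
    }))
  })
  summarise_metric <- function(x) {
    x <- x[is.finite(x)]
    data.frame(mean = mean(x), sd = stats::sd(x),
               sem = stats::sd(x) / sqrt(length(x)), n = length(x))
  }
  cols <- c("frequency", "ti_mean", "tiq", "amplitude_mean", "auc")
  summary <- do.call(rbind, lapply(cols, function(cl) {
    cbind(data.frame(metric = cl), summarise_metric(metrics[[cl]]))
  }))
  list(metrics = metrics, summary = summary)
}
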