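# Synthetic intraluminal-pressure traces with CPMC activity.
#
# A 15-min phase is modelled as a ~5 mmHg baseline carrying large, discrete
# colonic peristaltic motor complexes (CPMCs, raised-cosine pressure waves),
# a low-amplitude sub-threshold contraction component, and Gaussian sensor
# noise. CPMC onsets follow a stationary gamma renewal process so that the
# expected event count over a window of length T is exactly T/mean_interval.

#' Run code with a private, restorable RNG stream
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper) {
    stop(sprintf("`%s` = %g is outside its valid range", name, x),
         call. = FALSE)
  }
  invisible(x)
}

#' Generator configuration for synthetic CPMC pressure traces
#'
#' Defaults are calibrated so that a cohort of 900-s baseline phases,
#' quantified with [detection_params()] defaults, jointly reproduces the
#' published baseline statistics of the assay: frequency 5.6 CPMCs/900 s,
#' inter-complex interval 161.4 s, time in quiescence 661 s, amplitude
#' 49 mmHg and AUC 6410 mmHg·s. The small sub-threshold contraction
#' component (`blip_*` parameters, ~7 mmHg) models the non-propagating
#' activity seen between complexes in real recordings; it stays below the
#' event-detection threshold but contributes to time above the quiescence
#' band and to the AUC.
#'
#' @param baseline_pressure Resting intraluminal pressure, mmHg (>= 0).
#' @param noise_sd Gaussian sensor noise SD, mmHg (>= 0).
#' @param mean_interval Mean CPMC onset-to-onset interval, s.
#' @param interval_shape Gamma shape of the interval distribution
#'   (dimensionless, > 0). Larger values give more regular pacing; the
#'   default 4 gives the sub-Poisson regularity implied by the small
#'   between-phase spread of observed frequencies.
#' @param event_duration Width of the raised-cosine CPMC pressure wave, s.
#' @param event_amplitude Mean peak excursion above baseline, mmHg.
#' @param amplitude_cv Lognormal coefficient of variation of per-event
#'   amplitudes (dimensionless, >= 0).
#' @param drift_per_phase Multiplicative change in `event_amplitude` per
#'   successive phase of an experiment (fraction/phase; the vehicle
#'   time-drift confound). Must satisfy `abs(drift_per_phase) < 1`.
#' @param blip_rate Expected number of sub-threshold contractions per second.
#' @param blip_amplitude Mean peak of sub-threshold contractions, mmHg.
#'   Must stay below the detector onset threshold to remain "sub-threshold".
#' @param blip_duration Width of sub-threshold contractions, s.
#' @return An object of class `generator_config` (named list).
#' @examples
#' cfg <- generator_config()
#' cfg$mean_interval
#' @export
generator_config <- function(baseline_pressure = 5,
                             noise_sd = 1,
                             mean_interval = 161.4,
                             interval_shape = 4,
                             event_duration = 44.2,
                             event_amplitude = 49,
                             amplitude_cv = 0.1,
                             drift_per_phase = -0.02,
                             blip_rate = 8.9 / 900,
                             blip_amplitude = 7,
                             blip_duration = 15) {
  check_scalar(baseline_pressure, "baseline_pressure", lower = 0)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(event_duration, "event_duration", lower = 0, strict_lower = TRUE)
  check_scalar(mean_interval, "mean_interval", lower = event_duration,
               strict_lower = TRUE)
  check_scalar(interval_shape, "interval_shape", lower = 0, strict_lower = TRUE)
  # amplitude 0 is permitted as a degenerate (event-free) generator
  check_scalar(event_amplitude, "event_amplitude", lower = 0)
  check_scalar(amplitude_cv, "amplitude_cv", lower = 0)
  check_scalar(drift_per_phase, "drift_per_phase", lower = -1, upper = 1,
               strict_lower = TRUE)
  if (abs(drift_per_phase) >= 1) {
    stop("`drift_per_phase` must satisfy abs(drift_per_phase) < 1",
         call. = FALSE)
  }
  check_scalar(blip_rate, "blip_rate", lower = 0)
  check_scalar(blip_amplitude, "blip_amplitude", lower = 0)
  check_scalar(blip_duration, "blip_duration", lower = 0, strict_lower = TRUE)
  structure(
    list(
      baseline_pressure = baseline_pressure,
      noise_sd = noise_sd,
      mean_interval = mean_interval,
      interval_shape = interval_shape,
      event_duration = event_duration,
      event_amplitude = event_amplitude,
      amplitude_cv = amplitude_cv,
      drift_per_phase = drift_per_phase,
      blip_rate = blip_rate,
      blip_amplitude = blip_amplitude,
      blip_duration = blip_duration
    ),
    class = "generator_config"
  )
}

#' Concentration-response (Emax/Hill) drug effect model
#'
#' Describes how a bath concentration scales one or more generator
#' parameters. At concentration `c` the Hill fraction is
#' `f = c^n / (c^n + ec50^n)` and the scale factor is
#' `s = 1 + (emax - 1) * f`. Excitatory effects multiply the targeted
#' parameter by `s`; inhibitory effects divide it by `s`, which keeps the
#' parameter strictly positive for any concentration.
#'
#' @param parameter Targeted generator parameter(s); one or more of
#'   `"event_amplitude"`, `"mean_interval"`, `"event_duration"`.
#' @param emax Maximal fold-change bound (dimensionless, >= 1).
#' @param ec50 Half-maximal concentration, uM (> 0).
#' @param hill_n Hill slope (dimensionless, > 0).
#' @param direction `"excitatory"` or `"inhibitory"`, per effect.
#' @return A `drug_effect_model` data frame, one row per targeted parameter.
#' @examples
#' inhib <- drug_effect_model("event_amplitude", emax = 4, ec50 = 3,
#'                            direction = "inhibitory")
#' @export
drug_effect_model <- function(parameter, emax, ec50, hill_n = 1,
                              direction = c("excitatory", "inhibitory")) {
  valid_par <- c("event_amplitude", "mean_interval", "event_duration")
  if (!all(parameter %in% valid_par)) {
    stop("`parameter` must be one of: ", paste(valid_par, collapse = ", "),
         call. = FALSE)
  }
  n <- length(parameter)
  emax <- rep_len(emax, n)
  ec50 <- rep_len(ec50, n)
  hill_n <- rep_len(hill_n, n)
  direction <- rep_len(match.arg(direction, several.ok = TRUE), n)
  if (any(!is.finite(emax)) || any(emax < 1)) {
    stop("`emax` must be finite and >= 1", call. = FALSE)
  }
  if (any(!is.finite(ec50)) || any(ec50 <= 0)) {
    stop("`ec50` must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(hill_n)) || any(hill_n <= 0)) {
    stop("`hill_n` must be finite and > 0", call. = FALSE)
  }
  structure(
    data.frame(parameter = parameter, emax = emax, ec50 = ec50,
               hill_n = hill_n, direction = direction,
               stringsAsFactors = FALSE),
    class = c("drug_effect_model", "data.frame")
  )
}

#' Cumulative concentration-response experiment design
#'
#' Four successive 15-min perfusion phases (vehicle followed by incremental
#' drug concentrations), optionally followed by a washout phase at zero
#' concentration. Pressure is sampled at 100 Hz.
#'
#' @param concentrations Strictly increasing drug concentrations, uM.
#' @param phase_duration Duration of each phase, s.
#' @param sample_rate Sampling rate, Hz.
#' @param washout Append a washout phase at concentration 0?
#' @return An `experiment_design` object with a `phase_label` /
#'   `concentration` table.
#' @examples
#' experiment_design()$phases
#' @export
experiment_design <- function(concentrations = c(0.3, 3, 30),
                              phase_duration = 900,
                              sample_rate = 100,
                              washout = TRUE) {
  if (length(concentrations) < 1L || any(!is.finite(concentrations)) ||
      any(concentrations <= 0)) {
    stop("`concentrations` must be positive and finite", call. = FALSE)
  }
  if (is.unsorted(concentrations, strictly = TRUE)) {
    stop("`concentrations` must be strictly increasing", call. = FALSE)
  }
  check_scalar(phase_duration, "phase_duration", lower = 0,
               strict_lower = TRUE)
  check_scalar(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  labels <- c("vehicle", paste0("conc", seq_along(concentrations)),
              if (isTRUE(washout)) "washout")
  concs <- c(0, concentrations, if (isTRUE(washout)) 0)
  structure(
    list(
      phases = data.frame(phase_label = labels, concentration = concs,
                          stringsAsFactors = FALSE),
      concentrations = concentrations,
      phase_duration = phase_duration,
      sample_rate = sample_rate,
      washout = isTRUE(washout)
    ),
    class = "experiment_design"
  )
}

new_pressure_trace <- function(samples, sample_rate, phase_label, start_time) {
  structure(
    list(samples = samples, sample_rate = sample_rate,
         phase_label = phase_label, start_time = start_time,
         duration = length(samples) / sample_rate),
    class = "pressure_trace"
  )
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat(sprintf(
    "<pressure_trace> phase '%s': %d samples @ %g Hz (%.0f s), %.1f-%.1f mmHg\n",
    x$phase_label, length(x$samples), x$sample_rate, x$duration,
    min(x$samples), max(x$samples)))
  invisible(x)
}

#' Sample times of a pressure trace
#'
#' Half-open phase-local sample times `[0, duration)`.
#'
#' @param trace A `pressure_trace`.
#' @return Numeric vector of times in seconds.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "pressure_trace"))
  (seq_along(trace$samples) - 1) / trace$sample_rate
}

# Raised-cosine pulse evaluated at time-from-onset `t_rel` for width `w`.
raised_cosine <- function(t_rel, w) {
  0.5 * (1 - cos(2 * pi * t_rel / w))
}

# Draw CPMC onsets on [0, duration) from a stationary gamma renewal process.
# The first onset is an equilibrium residual (U * length-biased interval);
# subsequent intervals are gamma draws redrawn while shorter than
# `min_gap` so that complexes never overlap.
draw_onsets <- function(duration, mean_interval, shape, min_gap) {
  scale <- mean_interval / shape
  onsets <- numeric(0)
  t <- stats::runif(1) * stats::rgamma(1, shape = shape + 1, scale = scale)
  while (t < duration) {
    onsets <- c(onsets, t)
    repeat {
      x <- stats::rgamma(1, shape = shape, scale = scale)
      if (x >= min_gap) break
    }
    t <- t + x
  }
  onsets
}

# Lognormal multipliers with mean 1 and coefficient of variation `cv`.
lognormal_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Simulate one 15-min phase of CPMC activity
#'
#' Generates a pressure trace (baseline + Gaussian noise + one raised-cosine
#' pulse per CPMC + sub-threshold contractions) together with ground-truth
#' event annotations. CPMC onsets are drawn from a stationary gamma renewal
#' process with mean `config$mean_interval`, so the expected number of
#' annotated events is `duration / mean_interval`. A complex whose pulse
#' would extend past the end of the phase is truncated there and flagged.
#'
#' @param config A [generator_config()].
#' @param duration Phase duration, s.
#' @param seed Integer seed for reproducibility, or `NULL`.
#' @param sample_rate Sampling rate, Hz.
#' @param phase_label Label stored on the trace.
#' @param start_time Experiment-level start time of the phase, s.
#' @param fit_events_within If `TRUE`, only complexes whose full pulse lies
#'   inside the phase are generated (no truncated edge event); used when
#'   validating the detector against annotations.
#' @param events_only If `TRUE`, skip sample synthesis and return only the
#'   annotations (fast path for renewal-calibration checks).
#' @return A `simulated_phase` list with elements `trace` (a
#'   `pressure_trace`, or `NULL` when `events_only`) and `annotations`
#'   (data frame: `onset`, `offset`, `peak_time`, `amplitude`, `truncated`).
#' @examples
#' ph <- simulate_phase(generator_config(), duration = 900, seed = 1)
#' nrow(ph$annotations)
#' @export
simulate_phase <- function(config, duration = 900, seed = NULL,
                           sample_rate = 100, phase_label = "vehicle",
                           start_time = 0, fit_events_within = FALSE,
                           events_only = FALSE) {
  if (!inherits(config, "generator_config")) {
    stop("`config` must be a generator_config object", call. = FALSE)
  }
  check_scalar(duration, "duration", lower = 0, strict_lower = TRUE)
  check_scalar(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  w <- config$event_duration
  with_seed(seed, {
    onsets <- draw_onsets(duration, config$mean_interval,
                          config$interval_shape, min_gap = w)
    if (fit_events_within) onsets <- onsets[onsets + w <= duration]
    n_ev <- length(onsets)
    amps <- if (config$event_amplitude > 0 && n_ev > 0) {
      config$event_amplitude * lognormal_mult(n_ev, config$amplitude_cv)
    } else {
      numeric(n_ev) # zero-amplitude degenerate generator: no events
    }
    if (config$event_amplitude == 0) {
      onsets <- numeric(0)
      amps <- numeric(0)
      n_ev <- 0L
    }
    offsets <- pmin(onsets + w, duration)
    truncated <- (onsets + w) > duration
    peak_time <- pmin(onsets + w / 2, offsets - 1 / (2 * sample_rate))
    annotations <- data.frame(
      onset = onsets, offset = offsets, peak_time = peak_time,
      amplitude = amps, truncated = truncated
    )
    if (events_only) {
      return(structure(list(trace = NULL, annotations = annotations),
                       class = "simulated_phase"))
    }
    n <- round(duration * sample_rate)
    tt <- (seq_len(n) - 1) / sample_rate
    pressure <- config$baseline_pressure +
      if (config$noise_sd > 0) stats::rnorm(n, 0, config$noise_sd) else 0
    pressure <- rep_len(pressure, n) # scalar when noise_sd = 0
    for (i in seq_len(n_ev)) {
      i0 <- floor(onsets[i] * sample_rate) + 1
      i1 <- min(ceiling((onsets[i] + w) * sample_rate) + 1, n)
      idx <- i0:i1
      t_rel <- tt[idx] - onsets[i]
      keep <- t_rel >= 0 & t_rel <= w
      pressure[idx[keep]] <- pressure[idx[keep]] +
        amps[i] * raised_cosine(t_rel[keep], w)
    }
    # Sub-threshold contractions, placed in gaps between complexes.
    wb <- config$blip_duration
    if (config$blip_rate > 0 && config$blip_amplitude > 0 &&
        duration > wb) {
      n_blip <- stats::rpois(1, config$blip_rate * duration)
      placed <- matrix(numeric(0), ncol = 2)
      occupied <- rbind(cbind(onsets, onsets + w), placed)
      starts <- numeric(0)
      for (b in seq_len(n_blip)) {
        for (try in seq_len(100)) {
          s0 <- stats::runif(1, 0, duration - wb)
          if (nrow(occupied) == 0 ||
              all(s0 + wb <= occupied[, 1] | s0 >= occupied[, 2])) {
            starts <- c(starts, s0)
            occupied <- rbind(occupied, c(s0, s0 + wb))
            break
          }
        }
      }
      if (length(starts) > 0) {
        bl_amps <- config$blip_amplitude *
          lognormal_mult(length(starts), config$amplitude_cv)
        for (i in seq_along(starts)) {
          i0 <- floor(starts[i] * sample_rate) + 1
          i1 <- min(ceiling((starts[i] + wb) * sample_rate) + 1, n)
          idx <- i0:i1
          t_rel <- tt[idx] - starts[i]
          keep <- t_rel >= 0 & t_rel <= wb
          pressure[idx[keep]] <- pressure[idx[keep]] +
            bl_amps[i] * raised_cosine(t_rel[keep], wb)
        }
      }
    }
    trace <- new_pressure_trace(pressure, sample_rate, phase_label, start_time)
    structure(list(trace = trace, annotations = annotations),
              class = "simulated_phase")
  })
}

#' Scale generator parameters by a Hill concentration-response model
#'
#' @param config A [generator_config()].
#' @param model A [drug_effect_model()] (possibly multi-row), or `NULL` for
#'   no effect.
#' @param conc Bath concentration, uM (>= 0). `conc = 0` returns the
#'   configuration unchanged.
#' @return A modified `generator_config`.
#' @examples
#' m <- drug_effect_model("event_amplitude", emax = 3, ec50 = 1)
#' apply_drug_effect(generator_config(), m, conc = 1)$event_amplitude # x2
#' @export
apply_drug_effect <- function(config, model, conc) {
  if (!inherits(config, "generator_config")) {
    stop("`config` must be a generator_config object", call. = FALSE)
  }
  check_scalar(conc, "conc", lower = 0)
  if (is.null(model) || conc == 0) return(config)
  if (!inherits(model, "drug_effect_model")) {
    stop("`model` must be a drug_effect_model object", call. = FALSE)
  }
  out <- unclass(config)
  for (i in seq_len(nrow(model))) {
    frac <- conc^model$hill_n[i] /
      (conc^model$hill_n[i] + model$ec50[i]^model$hill_n[i])
    scale <- 1 + (model$emax[i] - 1) * frac
    p <- model$parameter[i]
    out[[p]] <- if (model$direction[i] == "excitatory") {
      out[[p]] * scale
    } else {
      out[[p]] / scale
    }
    if (!is.finite(out[[p]]) || out[[p]] <= 0) {
      stop(sprintf("drug effect drives `%s` to a non-positive value", p),
           call. = FALSE)
    }
  }
  if (out$mean_interval <= out$event_duration) {
    stop("drug effect drives `mean_interval` below `event_duration`; ",
         "complexes would overlap", call. = FALSE)
  }
  do.call(generator_config, out)
}

#' Simulate a full cumulative concentration-response experiment
#'
#' One trace per phase of `design`. The vehicle time-drift confound is
#' applied multiplicatively to `event_amplitude` by phase index in every
#' phase (drug and control runs alike); drug phases are additionally scaled
#' by the Hill model at the phase concentration. The washout phase returns
#' to concentration 0 but retains the cumulative drift.
#'
#' @param design An [experiment_design()].
#' @param base A [generator_config()].
#' @param model A [drug_effect_model()] or `NULL` (vehicle-only run).
#' @param seed Integer seed, or `NULL`.
#' @return A `cpmc_experiment`: list with `phases` (list of
#'   `simulated_phase`), `design`, and `model`.
#' @export
simulate_experiment <- function(design, base, model = NULL, seed = NULL) {
  if (!inherits(design, "experiment_design")) {
    stop("`design` must be an experiment_design object", call. = FALSE)
  }
  if (!inherits(base, "generator_config")) {
    stop("`base` must be a generator_config object", call. = FALSE)
  }
  n_phase <- nrow(design$phases)
  with_seed(seed, {
    phase_seeds <- sample.int(.Machine$integer.max, n_phase)
    phases <- vector("list", n_phase)
    for (i in seq_len(n_phase)) {
      cfg <- base
      cfg$event_amplitude <-
        base$event_amplitude * (1 + base$drift_per_phase)^(i - 1)
      conc <- design$phases$concentration[i]
      if (conc > 0) cfg <- apply_drug_effect(cfg, model, conc)
      phases[[i]] <- simulate_phase(
        cfg, duration = design$phase_duration, seed = phase_seeds[i],
        sample_rate = design$sample_rate,
        phase_label = design$phases$phase_label[i],
        start_time = (i - 1) * design$phase_duration
      )
    }
    structure(list(phases = phases, design = design, model = model),
              class = "cpmc_experiment")
  })
}

#' Simulate a cohort of time-matched vehicle control experiments
#'
#' `n` independent experiments with every phase at concentration 0 (the
#' serial-dilution vehicle protocol); the amplitude drift is retained so the
#' cohort carries the same time-dependent confound as drug runs.
#'
#' @param n Number of control experiments (>= 2; the downstream control SD
#'   is undefined otherwise).
#' @param design An [experiment_design()].
#' @param base A [generator_config()].
#' @param seed Integer seed, or `NULL`.
#' @return A `cpmc_cohort`: list of `cpmc_experiment` objects.
#' @export
simulate_control_cohort <- function(n, design, base, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 2) {
    stop("`n` must be >= 2 (control SD is undefined otherwise)",
         call. = FALSE)
  }
  with_seed(seed, {
    exp_seeds <- sample.int(.Machine$integer.max, n)
    experiments <- lapply(seq_len(n), function(i) {
      simulate_experiment(design, base, model = NULL, seed = exp_seeds[i])
    })
    structure(experiments, class = "cpmc_cohort")
  })
}
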