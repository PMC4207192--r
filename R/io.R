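# Fixture loading, trace/metrics/config round-trips, the one-shot
# reproduction of the published concordance tables, and an end-to-end
# synthetic demonstration of the full pipeline.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "cpmcassay")
  if (p == "") {
    # during development (pkgload) the extdata lives under inst/
    p <- file.path("inst", "extdata", file)
  }
  if (!file.exists(p)) stop("fixture not found: ", file, call. = FALSE)
  p
}

finding_code_map <- c(none = "NE", nausea = "NE", diarrhea = "D",
                      constipation = "C", loose_stools = "D")

#' Load the clinical findings and exposure table
#'
#' Fifteen compounds with their clinical finding, percentage of subjects
#' affected, and minimum/maximum plasma exposure range (uM; free exposure
#' except where `exposure_is_total` marks compounds whose protein binding
#' was unknown).
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return Validated data frame, one row per compound.
#' @export
load_clinical_table <- function(path = fixture_path("table1_clinical.csv")) {
  t1 <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound", "clinical_finding", "pct_subjects_affected",
            "min_free_exposure_uM", "max_free_exposure_uM",
            "exposure_is_total")
  if (!all(need %in% names(t1))) {
    stop("clinical table is missing columns: ",
         paste(setdiff(need, names(t1)), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(t1$compound)) {
    stop("duplicated compound id(s) in clinical table", call. = FALSE)
  }
  is_motility_gadr(t1$clinical_finding) # validates the vocabulary
  if (any(t1$min_free_exposure_uM > t1$max_free_exposure_uM)) {
    stop("malformed exposure range (min > max) in clinical table",
         call. = FALSE)
  }
  if (any(t1$max_free_exposure_uM <= 0)) {
    stop("non-positive maximum exposure in clinical table", call. = FALSE)
  }
  t1
}

#' Load the in vitro assay summary table
#'
#' Per compound: tested concentrations, assay positivity at the maximum
#' dose, per-metric (amplitude/TIQ) positivity at the highest clinically
#' relevant dose, and the transcribed predictive-outcome columns for both
#' dosing schemes.
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return Validated data frame, one row per compound.
#' @export
load_invitro_table <- function(path = fixture_path("table2_invitro.csv")) {
  t2 <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound", "n_experiments", "tested_concentrations_uM",
            "clinical_finding_code", "assay_positive_max",
            "amplitude_positive_therapeutic", "tiq_positive_therapeutic",
            "outcome_max_dose", "outcome_therapeutic_dose")
  if (!all(need %in% names(t2))) {
    stop("in vitro table is missing columns: ",
         paste(setdiff(need, names(t2)), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(t2$compound)) {
    stop("duplicated compound id(s) in in vitro table", call. = FALSE)
  }
  lapply(t2$tested_concentrations_uM, parse_concentrations)
  stopifnot(is.logical(t2$assay_positive_max),
            is.logical(t2$amplitude_positive_therapeutic),
            is.logical(t2$tiq_positive_therapeutic))
  ok <- c("TP", "FP", "TN", "FN")
  if (!all(t2$outcome_max_dose %in% ok) ||
      !all(t2$outcome_therapeutic_dose %in% ok)) {
    stop("unknown predictive-outcome label in in vitro table", call. = FALSE)
  }
  t2
}

#' Load the charcoal-meal summary table
#'
#' Per compound: measured plasma-concentration range, the transit effect
#' label (`Decrease`/`Increase`/`NC`), whether the effect occurred within
#' the 50-fold exposure window, and the transcribed predictive outcome.
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return Validated data frame, one row per compound.
#' @export
load_charcoal_table <- function(path = fixture_path("table3_charcoal.csv")) {
  t3 <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound", "n_animals", "charcoal_effect",
            "effect_within_window", "clinical_finding_code",
            "predictive_outcome")
  if (!all(need %in% names(t3))) {
    stop("charcoal table is missing columns: ",
         paste(setdiff(need, names(t3)), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(t3$compound)) {
    stop("duplicated compound id(s) in charcoal table", call. = FALSE)
  }
  if (!all(t3$charcoal_effect %in% c("Decrease", "Increase", "NC"))) {
    stop("unknown charcoal effect label", call. = FALSE)
  }
  if (!all(t3$predictive_outcome %in% c("TP", "FP", "TN", "FN"))) {
    stop("unknown predictive-outcome label in charcoal table", call. = FALSE)
  }
  t3
}

#' Load and cross-validate all three fixture tables
#'
#' Checks that the 15 compound ids agree across tables and that the
#' shorthand clinical-finding codes in the assay tables are consistent
#' with the clinical findings table (a motility GADR iff the code is not
#' `"NE"`).
#'
#' @return List with elements `clinical`, `invitro`, `charcoal`.
#' @export
load_gadr_tables <- function() {
  clinical <- load_clinical_table()
  invitro <- load_invitro_table()
  charcoal <- load_charcoal_table()
  if (!identical(clinical$compound, invitro$compound) ||
      !identical(clinical$compound, charcoal$compound)) {
    stop("compound ids disagree across the fixture tables", call. = FALSE)
  }
  if (nrow(clinical) != 15L) {
    stop("expected 15 compounds, found ", nrow(clinical), call. = FALSE)
  }
  codes <- unname(finding_code_map[clinical$clinical_finding])
  gadr <- is_motility_gadr(clinical$clinical_finding)
  if (any((invitro$clinical_finding_code != "NE") != gadr) ||
      any((charcoal$clinical_finding_code != "NE") != gadr)) {
    stop("clinical-finding codes disagree with the clinical table",
         call. = FALSE)
  }
  list(clinical = clinical, invitro = invitro, charcoal = charcoal,
       finding_codes = codes)
}

#' Reproduce the published concordance analysis
#'
#' Recomputes every per-compound TP/FP/TN/FN category from the packaged
#' tables — in vitro at the maximum dose tested, in vitro at the highest
#' clinically relevant (within `fold`-fold exposure) dose, and the
#' charcoal-meal assay — verifies them against the transcribed outcome
#' columns (any mismatch is an error naming the compounds), and derives
#' the three predictive capacities, the exact-test comparison of the two
#' in vitro schemes, and sensitivity/specificity.
#'
#' @param fold Exposure window multiplier.
#' @return A `concordance_report` list: `invitro` and `charcoal`
#'   per-compound data frames, `counts` (per scheme), `capacity`
#'   (per scheme, as fractions), `scheme_comparison`, `rates` (per scheme).
#' @examples
#' rep <- reproduce_paper()
#' rep$capacity
#' @export
reproduce_paper <- function(fold = 50) {
  tabs <- load_gadr_tables()
  inv <- score_invitro(tabs$clinical, tabs$invitro, fold = fold)
  cha <- score_charcoal(tabs$clinical, tabs$charcoal)
  counts <- list(
    invitro_max = concordance_counts(inv$category_max),
    invitro_therapeutic = concordance_counts(inv$category_therapeutic),
    charcoal = concordance_counts(cha$category)
  )
  capacity <- vapply(counts, predictive_capacity, numeric(1))
  rates <- lapply(counts, derived_rates)
  cmp <- compare_schemes(counts$invitro_max, counts$invitro_therapeutic)
  structure(
    list(invitro = inv, charcoal = cha, counts = counts,
         capacity = capacity, scheme_comparison = cmp, rates = rates,
         fold = fold),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Concordance of assay calls with clinical GADR labels",
      sprintf("(%g-fold exposure window)\n", x$fold))
  for (nm in names(x$counts)) {
    k <- x$counts[[nm]]
    cat(sprintf(
      "  %-20s TP %d  FP %d  TN %d  FN %d   predictive capacity %d/%d = %.0f%%\n",
      nm, k[["tp"]], k[["fp"]], k[["tn"]], k[["fn"]],
      k[["tp"]] + k[["tn"]], sum(k), 100 * x$capacity[[nm]]))
  }
  cat(sprintf(
    "  max-dose vs therapeutic-dose scheme: Fisher exact p = %.3f\n",
    x$scheme_comparison$p_value))
  r <- x$rates$invitro_therapeutic
  cat(sprintf(
    "  in vitro (therapeutic): sensitivity %.2f, specificity %.2f\n",
    r[["sensitivity"]], r[["specificity"]]))
  invisible(x)
}

# ---- trace / metrics / config round-trips ---------------------------------

#' Write a simulated phase to CSV with a JSON sidecar
#'
#' Produces `<prefix>.csv` (`time_s`, `pressure_mmHg`),
#' `<prefix>_annotations.csv` (`onset_s`, `offset_s`, `peak_s`,
#' `amplitude_mmHg`, `truncated`), and `<prefix>.json` (sample rate, phase
#' label, start time).
#'
#' @param phase A `simulated_phase` or `pressure_trace`.
#' @param prefix Output path prefix.
#' @return The three file paths, invisibly.
#' @export
write_trace_csv <- function(phase, prefix) {
  trace <- as_trace(phase)
  stopifnot(inherits(trace, "pressure_trace"))
  csv <- paste0(prefix, ".csv")
  js <- paste0(prefix, ".json")
  ann_csv <- paste0(prefix, "_annotations.csv")
  utils::write.csv(
    data.frame(time_s = trace_times(trace), pressure_mmHg = trace$samples),
    csv, row.names = FALSE)
  jsonlite::write_json(
    list(sample_rate = trace$sample_rate, phase_label = trace$phase_label,
         start_time = trace$start_time, duration = trace$duration),
    js, auto_unbox = TRUE, digits = NA)
  paths <- c(trace = csv, sidecar = js)
  if (inherits(phase, "simulated_phase")) {
    a <- phase$annotations
    utils::write.csv(
      data.frame(onset_s = a$onset, offset_s = a$offset,
                 peak_s = a$peak_time, amplitude_mmHg = a$amplitude,
                 truncated = a$truncated),
      ann_csv, row.names = FALSE)
    paths <- c(paths, annotations = ann_csv)
  }
  invisible(paths)
}

#' Read a trace written by [write_trace_csv()]
#'
#' @param prefix Path prefix used when writing.
#' @return A `pressure_trace`.
#' @export
read_trace_csv <- function(prefix) {
  d <- utils::read.csv(paste0(prefix, ".csv"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  new_pressure_trace(d$pressure_mmHg, meta$sample_rate, meta$phase_label,
                     meta$start_time)
}

#' Write per-phase metrics to CSV
#'
#' @param metrics Metrics data frame from [quantify_experiment()] or
#'   [phase_metrics()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' Read per-phase metrics written by [write_metrics_csv()]
#'
#' @param path CSV path.
#' @return Metrics data frame.
#' @export
read_metrics_csv <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  # all-NA numeric columns (e.g. ti_mean with < 2 events) parse as logical
  for (cl in intersect(c("frequency", "ti_mean", "tiq", "amplitude_mean",
                         "auc", "concentration"), names(m))) {
    m[[cl]] <- as.numeric(m[[cl]])
  }
  m
}

#' Write a generator/detection configuration to YAML or JSON
#'
#' The format follows the file extension (`.yaml`/`.yml` or `.json`);
#' field names mirror the constructor arguments.
#'
#' @param config A `generator_config`, `detection_params`, or plain list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path, precision = 15)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("config path must end in .yaml, .yml or .json", call. = FALSE)
  }
  invisible(path)
}

#' Read a configuration written by [write_config()]
#'
#' @param path YAML or JSON path.
#' @param constructor Constructor applied to the fields (e.g.
#'   [generator_config()] or [detection_params()]); `NULL` returns the raw
#'   list.
#' @return The constructed configuration object.
#' @export
read_config <- function(path, constructor = generator_config) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config path must end in .yaml, .yml or .json", call. = FALSE)
  }
  if (is.null(constructor)) x else do.call(constructor, x)
}

#' Global run configuration
#'
#' Houses the pipeline-wide constants: the exposure-window multiplier, the
#' control-SD decision threshold, and the transit-test significance level.
#'
#' @param seed Master seed for all randomness in a run.
#' @param generator A [generator_config()].
#' @param design An [experiment_design()].
#' @param detection A [detection_params()].
#' @param fold_margin Exposure window multiplier (> 0).
#' @param sd_multiplier Decision threshold in control SDs (> 0).
#' @param alpha Transit-test significance level (in (0, 1)).
#' @return A `run_config` object.
#' @export
run_config <- function(seed = 1,
                       generator = generator_config(),
                       design = experiment_design(),
                       detection = detection_params(),
                       fold_margin = 50,
                       sd_multiplier = 2,
                       alpha = 0.05) {
  check_scalar(fold_margin, "fold_margin", lower = 0, strict_lower = TRUE)
  check_scalar(sd_multiplier, "sd_multiplier", lower = 0,
               strict_lower = TRUE)
  check_scalar(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  if (alpha >= 1) stop("`alpha` must be < 1", call. = FALSE)
  structure(
    list(seed = seed, generator = generator, design = design,
         detection = detection, fold_margin = fold_margin,
         sd_multiplier = sd_multiplier, alpha = alpha),
    class = "run_config"
  )
}

#' End-to-end synthetic demonstration of the pipeline
#'
#' Simulates a time-matched control cohort and a small panel of synthetic
#' compounds with known concentration-response models and known GADR
#' labels, quantifies every phase, applies the control-SD decision rule,
#' and classifies each compound against its ground-truth label.
#'
#' @param config A [run_config()].
#' @param n_control Number of time-matched control experiments.
#' @param panel Data frame defining the synthetic panel (`compound`,
#'   `gadr`, `max_exposure`, plus an `effects` list-column of
#'   [drug_effect_model()] objects or `NULL`); `NULL` uses a built-in
#'   five-compound panel.
#' @return A `demo_report` list: `calls` (per-compound data frame with
#'   positivity, category and ground truth), `counts`, `capacity`,
#'   `control` (the control distribution).
#' @export
end_to_end_demo <- function(config = run_config(), n_control = 4,
                            panel = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(panel)) {
    panel <- data.frame(
      compound = c("inhib_amplitude", "excit_amplitude", "slow_pacing",
                   "null_effect", "weak_offscale"),
      gadr = c(TRUE, TRUE, TRUE, FALSE, FALSE),
      max_exposure = 1, # every tested concentration clinically relevant
      stringsAsFactors = FALSE
    )
    # effect sizes are kept within the assay's measurable range: an
    # amplitude suppression much beyond ~3-fold pushes complexes under the
    # detection threshold and the amplitude metric becomes not-assessable
    panel$effects <- list(
      drug_effect_model("event_amplitude", emax = 3, ec50 = 1,
                        direction = "inhibitory"),
      drug_effect_model("event_amplitude", emax = 2.5, ec50 = 1,
                        direction = "excitatory"),
      drug_effect_model("mean_interval", emax = 6, ec50 = 1,
                        direction = "excitatory"),
      NULL,
      drug_effect_model("event_amplitude", emax = 5, ec50 = 1e5,
                        direction = "inhibitory")
    )
  }
  with_seed(config$seed, {
    cohort <- simulate_control_cohort(n_control, config$design,
                                      config$generator,
                                      seed = sample.int(2^31 - 1, 1))
    ctrl <- build_control_distribution(cohort, config$detection)
    compound_seeds <- sample.int(.Machine$integer.max, nrow(panel))
    rows <- lapply(seq_len(nrow(panel)), function(i) {
      ex <- simulate_experiment(config$design, config$generator,
                                model = panel$effects[[i]],
                                seed = compound_seeds[i])
      m <- quantify_experiment(ex, config$detection)
      call <- call_compound(m, ctrl, max_exposure = panel$max_exposure[i],
                            fold = config$fold_margin,
                            sd_multiplier = config$sd_multiplier)
      data.frame(
        compound = panel$compound[i],
        gadr = panel$gadr[i],
        positive_at_max_dose = call$positive_at_max_dose,
        positive_at_clinical_dose = call$positive_at_clinical_dose,
        category = classify_outcome(call$positive_at_clinical_dose,
                                    panel$gadr[i]),
        stringsAsFactors = FALSE
      )
    })
    calls <- do.call(rbind, rows)
    counts <- concordance_counts(calls$category)
    structure(
      list(calls = calls, counts = counts,
           capacity = predictive_capacity(counts), control = ctrl),
      class = "demo_report"
    )
  })
}

#' @export
print.demo_report <- function(x, ...) {
  cat("End-to-end synthetic panel:\n")
  print(x$calls, row.names = FALSE)
  cat(sprintf("predictive capacity vs ground truth: %.0f%%\n",
              100 * x$capacity))
  invisible(x)
}
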