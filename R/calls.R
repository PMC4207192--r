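# Vehicle-relative changes and the time-matched-control 2-SD decision rule.
#
# Amplitude and TIQ for each drug phase are expressed as percentage changes
# relative to the experiment's own vehicle phase; a phase/metric is positive
# when its relative change lies more than `sd_multiplier` control SDs from
# the time-matched control mean (two-sided, strict inequality). A compound
# is positive when either metric is positive (OR rule).

#' Percentage change of a metric relative to the vehicle phase
#'
#' `100 * (drug - vehicle) / vehicle`. Undefined (`NA`) when either value
#' is missing or the vehicle value is zero; undefined changes propagate as
#' not-assessable rather than silently becoming zero.
#'
#' @param drug Metric value (or one-row metrics data frame) for a drug phase.
#' @param vehicle Matching value/row for the vehicle phase.
#' @param metric Metric name when data frames are supplied
#'   (`"amplitude_mean"` or `"tiq"`; `"amplitude"` is accepted as an alias).
#' @return Relative change in percent, or `NA_real_`.
#' @examples
#' relative_change(25, 50) # -50
#' @export
relative_change <- function(drug, vehicle, metric = NULL) {
  if (is.data.frame(drug) || is.data.frame(vehicle)) {
    if (is.null(metric)) {
      stop("`metric` is required when passing metrics data frames",
           call. = FALSE)
    }
    metric <- normalise_metric(metric)
    drug <- drug[[metric]]
    vehicle <- vehicle[[metric]]
  }
  if (length(drug) != 1L || length(vehicle) != 1L) {
    stop("`drug` and `vehicle` must be single values", call. = FALSE)
  }
  if (is.na(drug) || is.na(vehicle) || vehicle == 0) return(NA_real_)
  100 * (drug - vehicle) / vehicle
}

normalise_metric <- function(metric) {
  metric <- match.arg(metric, c("amplitude_mean", "tiq", "amplitude"))
  if (metric == "amplitude") "amplitude_mean" else metric
}

decision_metrics <- c("amplitude_mean", "tiq")

# Relative changes (vs the phase-1 vehicle) for the drug phases of one
# quantified experiment. Returns long data frame:
# phase_index, phase_label, concentration, metric, relative_change.
experiment_relative_changes <- function(metrics,
                                        metrics_cols = decision_metrics) {
  stopifnot(is.data.frame(metrics),
            all(c("phase_label", metrics_cols) %in% names(metrics)))
  veh <- metrics[metrics$phase_label == "vehicle", , drop = FALSE]
  if (nrow(veh) != 1L) {
    stop("metrics must contain exactly one vehicle phase", call. = FALSE)
  }
  drug <- metrics[grepl("^conc", metrics$phase_label), , drop = FALSE]
  if (nrow(drug) == 0L) {
    stop("metrics contain no drug phases", call. = FALSE)
  }
  out <- expand.grid(row = seq_len(nrow(drug)), metric = metrics_cols,
                     stringsAsFactors = FALSE)
  out$phase_label <- drug$phase_label[out$row]
  out$concentration <- if ("concentration" %in% names(drug)) {
    drug$concentration[out$row]
  } else {
    NA_real_
  }
  out$relative_change <- vapply(seq_len(nrow(out)), function(i) {
    relative_change(drug[[out$metric[i]]][out$row[i]],
                    veh[[out$metric[i]]])
  }, numeric(1))
  out[c("phase_label", "concentration", "metric", "relative_change")]
}

#' Null distribution of relative changes from time-matched controls
#'
#' For every drug-phase position and metric, computes each control
#' experiment's relative change versus its own vehicle phase, then the mean
#' and sample SD (n - 1 denominator) across experiments.
#'
#' @param cohort_metrics A list of per-experiment metrics data frames (as
#'   returned by [quantify_experiment()]), or a `cpmc_cohort` from
#'   [simulate_control_cohort()] (quantified internally).
#' @param params A [detection_params()], used only when a raw cohort is
#'   supplied.
#' @return A `control_distribution` data frame: `phase_label`, `metric`,
#'   `mean`, `sd`, `n`.
#' @export
build_control_distribution <- function(cohort_metrics,
                                       params = detection_params()) {
  if (inherits(cohort_metrics, "cpmc_cohort")) {
    cohort_metrics <- lapply(cohort_metrics, quantify_experiment,
                             params = params)
  }
  if (!is.list(cohort_metrics) || length(cohort_metrics) < 2L) {
    stop("need metrics from at least 2 control experiments ",
         "(the control SD is undefined otherwise)", call. = FALSE)
  }
  changes <- lapply(cohort_metrics, experiment_relative_changes)
  key0 <- paste(changes[[1]]$phase_label, changes[[1]]$metric)
  for (ch in changes[-1]) {
    if (!identical(paste(ch$phase_label, ch$metric), key0)) {
      stop("control experiments have mismatched phase structures",
           call. = FALSE)
    }
  }
  values <- sapply(changes, `[[`, "relative_change") # rows x experiments
  out <- changes[[1]][c("phase_label", "metric")]
  out$mean <- apply(values, 1, function(v) mean(v[!is.na(v)]))
  out$sd <- apply(values, 1, function(v) stats::sd(v[!is.na(v)]))
  out$n <- apply(values, 1, function(v) sum(!is.na(v)))
  structure(out, class = c("control_distribution", "data.frame"))
}

#' Two-sided 2-SD positivity call for one relative change
#'
#' Positive iff `abs(value - ctrl_mean) > sd_multiplier * ctrl_sd` (strict
#' inequality, deviations in either direction count).
#'
#' @param value Relative change, percent (`NA` = not assessable).
#' @param ctrl_mean,ctrl_sd Control mean and SD for the matching phase and
#'   metric, percent.
#' @param sd_multiplier Decision threshold in control SDs.
#' @return `TRUE`, `FALSE`, or `NA` when the change is not assessable.
#' @examples
#' call_positive(-11, 0, 5)  # TRUE
#' call_positive(10, 0, 5)   # FALSE (strict inequality)
#' @export
call_positive <- function(value, ctrl_mean, ctrl_sd, sd_multiplier = 2) {
  check_scalar(sd_multiplier, "sd_multiplier", lower = 0, strict_lower = TRUE)
  if (is.na(value)) return(NA)
  abs(value - ctrl_mean) > sd_multiplier * ctrl_sd
}

#' Compound-level assay call from per-phase relative changes
#'
#' Applies [call_positive()] to every drug phase and metric of one
#' quantified experiment, combines metrics with the OR rule, and derives the
#' two compound-level calls: positivity at the highest dose tested, and
#' positivity at the highest dose inside the clinically relevant exposure
#' window. When no tested concentration lies within the window the clinical
#' call is negative-by-window (`positive_at_clinical_dose = FALSE`,
#' `window_empty = TRUE`).
#'
#' @param metrics Per-phase metrics data frame for the compound experiment
#'   (from [quantify_experiment()]; must include a `concentration` column).
#' @param ctrl A `control_distribution` from [build_control_distribution()].
#' @param max_exposure Maximum clinical free plasma exposure, uM, or `NA`
#'   to skip the clinical-dose call.
#' @param fold Exposure window multiplier (clinical window = concentrations
#'   within `fold` times `max_exposure`).
#' @param sd_multiplier Decision threshold in control SDs.
#' @return An `assay_call` list: `per_phase` (data frame with
#'   `relative_change` and `positive` per phase/metric),
#'   `positive_at_max_dose`, `positive_at_clinical_dose`, `window_empty`,
#'   `clinical_phase` (label or `NA`), `not_assessable` (any undefined
#'   change at the phases used for calls).
#' @export
call_compound <- function(metrics, ctrl, max_exposure = NA, fold = 50,
                          sd_multiplier = 2) {
  if (!inherits(ctrl, "control_distribution")) {
    stop("`ctrl` must come from build_control_distribution()", call. = FALSE)
  }
  changes <- experiment_relative_changes(metrics)
  key <- paste(changes$phase_label, changes$metric)
  ctrl_key <- paste(ctrl$phase_label, ctrl$metric)
  idx <- match(key, ctrl_key)
  if (anyNA(idx)) {
    stop("control distribution does not cover all drug phases/metrics",
         call. = FALSE)
  }
  changes$positive <- mapply(call_positive, changes$relative_change,
                             ctrl$mean[idx], ctrl$sd[idx],
                             MoreArgs = list(sd_multiplier = sd_multiplier))
  if (all(is.na(changes$relative_change))) {
    stop("no assessable relative change in any drug phase", call. = FALSE)
  }
  phase_positive <- function(label) {
    p <- changes$positive[changes$phase_label == label]
    if (all(is.na(p))) NA else any(p, na.rm = TRUE)
  }
  concs <- unique(changes[c("phase_label", "concentration")])
  max_label <- concs$phase_label[which.max(concs$concentration)]
  positive_at_max <- phase_positive(max_label)

  window_empty <- FALSE
  clinical_phase <- NA_character_
  if (is.na(max_exposure)) {
    positive_at_clinical <- NA
  } else {
    admissible <- clinical_window(concs$concentration, max_exposure,
                                  fold = fold)
    if (length(admissible) == 0L) {
      window_empty <- TRUE
      positive_at_clinical <- FALSE # negative-by-window
    } else {
      clinical_phase <-
        concs$phase_label[concs$concentration == max(admissible)]
      positive_at_clinical <- phase_positive(clinical_phase)
    }
  }
  not_assessable <- anyNA(changes$relative_change)
  if (not_assessable) {
    warning("some relative changes are not assessable (undefined vehicle ",
            "metric); they are excluded from positivity", call. = FALSE)
  }
  structure(
    list(per_phase = changes,
         positive_at_max_dose = positive_at_max,
         positive_at_clinical_dose = positive_at_clinical,
         window_empty = window_empty,
         clinical_phase = clinical_phase,
         not_assessable = not_assessable),
    class = "assay_call"
  )
}

#' Flag a compound for retesting at lower concentrations
#'
#' The dose-lowering protocol rule: if a compound is already positive at the
#' lowest concentration tested, the concentration range must be reduced
#' (divided by `factor`) and the cumulative experiment repeated. This
#' planner flags the rerun and proposes the lowered range; it does not merge
#' runs.
#'
#' @param call An `assay_call` from [call_compound()].
#' @param factor Division factor for the rerun concentrations.
#' @return List `rerun_required` (logical) and `suggested_concentrations`
#'   (numeric, or `NULL`).
#' @export
needs_dose_lowering <- function(call, factor = 10) {
  stopifnot(inherits(call, "assay_call"))
  per <- call$per_phase
  lowest <- per[per$concentration == min(per$concentration), , drop = FALSE]
  pos <- if (all(is.na(lowest$positive))) FALSE else
    any(lowest$positive, na.rm = TRUE)
  list(
    rerun_required = pos,
    suggested_concentrations =
      if (pos) sort(unique(per$concentration)) / factor else NULL
  )
}
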