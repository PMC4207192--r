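# Translational concordance: assay calls vs clinical GADR labels.
#
# A compound is a clinical positive when its reported adverse reaction is a
# motility-related GADR (diarrhea, constipation, loose stools); nausea and
# "no finding" are clinical negatives. Crossing the assay call with the
# clinical flag gives TP/FN/FP/TN, and predictive capacity is the fraction
# of correct calls.

gadr_vocabulary <- c("diarrhea", "constipation", "loose_stools", "nausea",
                     "none")
motility_gadrs <- c("diarrhea", "constipation", "loose_stools")

#' Clinically relevant concentrations within the exposure window
#'
#' Concentrations no more than `fold` times the maximum clinical plasma
#' exposure. The admissible set may be empty (every tested concentration
#' exceeds the safety margin), in which case the compound cannot be
#' assessed at a clinically relevant dose.
#'
#' @param tested Tested concentrations, uM.
#' @param max_exposure Maximum clinical plasma exposure, uM (> 0).
#' @param fold Window multiplier (default 50-fold).
#' @return The admissible subset of `tested` (possibly empty).
#' @examples
#' clinical_window(c(0.3, 3, 30), 0.0710) # 0.3 and 3
#' @export
clinical_window <- function(tested, max_exposure, fold = 50) {
  if (!is.numeric(max_exposure) || length(max_exposure) != 1L ||
      !is.finite(max_exposure) || max_exposure <= 0) {
    stop("`max_exposure` must be a single positive number", call. = FALSE)
  }
  check_scalar(fold, "fold", lower = 0, strict_lower = TRUE)
  if (any(!is.finite(tested)) || any(tested <= 0)) {
    stop("`tested` concentrations must be positive and finite",
         call. = FALSE)
  }
  tested[tested <= fold * max_exposure]
}

#' Is a clinical finding a motility-related GADR?
#'
#' `TRUE` for diarrhea, constipation and loose stools; `FALSE` for nausea
#' and for compounds with no reported finding. Nausea is not a motility
#' finding and does not count as a clinical positive for this assay.
#'
#' @param finding Character vector over the controlled vocabulary:
#'   diarrhea, constipation, loose_stools, nausea, none.
#' @return Logical vector.
#' @export
is_motility_gadr <- function(finding) {
  if (!all(finding %in% gadr_vocabulary)) {
    bad <- setdiff(unique(finding), gadr_vocabulary)
    stop("unknown clinical finding label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  finding %in% motility_gadrs
}

#' Cross an assay call with the clinical GADR flag
#'
#' @param assay_positive Logical vector of assay calls. `NA` (not
#'   assessable) yields `NA` with a warning; such compounds are excluded
#'   from counts downstream.
#' @param clinical_gadr Logical vector of clinical motility-GADR flags.
#' @return Character vector over `"TP"`, `"FN"`, `"FP"`, `"TN"`.
#' @examples
#' classify_outcome(TRUE, TRUE)   # "TP"
#' classify_outcome(FALSE, TRUE)  # "FN"
#' @export
classify_outcome <- function(assay_positive, clinical_gadr) {
  if (length(assay_positive) != length(clinical_gadr)) {
    stop("`assay_positive` and `clinical_gadr` must have equal length",
         call. = FALSE)
  }
  if (anyNA(clinical_gadr)) {
    stop("`clinical_gadr` must be TRUE/FALSE", call. = FALSE)
  }
  if (anyNA(assay_positive)) {
    warning("not-assessable assay call(s): excluded from classification",
            call. = FALSE)
  }
  ifelse(is.na(assay_positive), NA_character_,
         ifelse(assay_positive,
                ifelse(clinical_gadr, "TP", "FP"),
                ifelse(clinical_gadr, "FN", "TN")))
}

#' Tally TP/FP/TN/FN categories
#'
#' @param categories Character vector of categories (`NA`s are dropped).
#' @return Named integer vector with elements `tp`, `fp`, `tn`, `fn`.
#' @export
concordance_counts <- function(categories) {
  categories <- categories[!is.na(categories)]
  if (!all(categories %in% c("TP", "FP", "TN", "FN"))) {
    stop("categories must be TP/FP/TN/FN", call. = FALSE)
  }
  c(tp = sum(categories == "TP"), fp = sum(categories == "FP"),
    tn = sum(categories == "TN"), fn = sum(categories == "FN"))
}

#' Predictive capacity: fraction of correct assay calls
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param counts Named counts from [concordance_counts()], or a character
#'   vector of categories.
#' @return Fraction in `[0, 1]`.
#' @examples
#' predictive_capacity(c(tp = 5, fp = 3, tn = 4, fn = 3)) # 0.6
#' @export
predictive_capacity <- function(counts) {
  if (is.character(counts)) counts <- concordance_counts(counts)
  total <- sum(counts[c("tp", "fp", "tn", "fn")])
  if (is.na(total) || total == 0) {
    stop("no classified compounds: predictive capacity undefined",
         call. = FALSE)
  }
  unname((counts[["tp"]] + counts[["tn"]]) / total)
}

#' Sensitivity and specificity of the assay
#'
#' `sensitivity = TP / (TP + FN)`; `specificity = TN / (TN + FP)`. Each is
#' `NA` when its denominator is zero.
#'
#' @param counts Named counts from [concordance_counts()].
#' @return Named numeric vector `c(sensitivity =, specificity =)`.
#' @export
derived_rates <- function(counts) {
  pos <- counts[["tp"]] + counts[["fn"]]
  neg <- counts[["tn"]] + counts[["fp"]]
  c(sensitivity = if (pos > 0) counts[["tp"]] / pos else NA_real_,
    specificity = if (neg > 0) counts[["tn"]] / neg else NA_real_)
}

#' Compare the correct/incorrect split of two classification schemes
#'
#' Builds the 2x2 contingency table (correct = TP + TN, incorrect =
#' FP + FN for each scheme) and applies Fisher's exact conditional test.
#'
#' @param counts_a,counts_b Named counts from [concordance_counts()]. Both
#'   schemes must classify the same number of compounds.
#' @return List with `p_value` and the 2x2 `table`.
#' @export
compare_schemes <- function(counts_a, counts_b) {
  correct <- function(k) k[["tp"]] + k[["tn"]]
  incorrect <- function(k) k[["fp"]] + k[["fn"]]
  if (correct(counts_a) + incorrect(counts_a) !=
      correct(counts_b) + incorrect(counts_b)) {
    stop("schemes classify different totals; not comparable", call. = FALSE)
  }
  tab <- matrix(c(correct(counts_a), incorrect(counts_a),
                  correct(counts_b), incorrect(counts_b)),
                nrow = 2,
                dimnames = list(c("correct", "incorrect"),
                                c("scheme_a", "scheme_b")))
  list(p_value = stats::fisher.test(tab)$p.value, table = tab)
}

#' Score the in vitro assay table against clinical labels
#'
#' Recomputes, for every compound, the maximum-dose and therapeutic-dose
#' categories from (i) the assay positivity flags, (ii) the clinical
#' finding, and (iii) the 50-fold exposure window, and (optionally)
#' verifies them against the transcribed outcome columns; any mismatch is a
#' hard failure naming the offending compounds.
#'
#' @param clinical Clinical table from [load_clinical_table()].
#' @param invitro In vitro assay table from [load_invitro_table()].
#' @param fold Exposure window multiplier.
#' @param verify Check recomputed categories against the transcribed
#'   outcome columns?
#' @return Data frame with per-compound calls and categories for both
#'   schemes.
#' @export
score_invitro <- function(clinical, invitro, fold = 50, verify = TRUE) {
  stopifnot(identical(clinical$compound, invitro$compound))
  gadr <- is_motility_gadr(clinical$clinical_finding)
  n <- nrow(invitro)
  window_n <- integer(n)
  positive_therapeutic <- logical(n)
  for (i in seq_len(n)) {
    tested <- parse_concentrations(invitro$tested_concentrations_uM[i])
    adm <- clinical_window(tested, clinical$max_free_exposure_uM[i],
                           fold = fold)
    window_n[i] <- length(adm)
    positive_therapeutic[i] <- length(adm) > 0 &&
      (invitro$amplitude_positive_therapeutic[i] ||
         invitro$tiq_positive_therapeutic[i])
  }
  out <- data.frame(
    compound = invitro$compound,
    clinical_gadr = gadr,
    n_admissible_concentrations = window_n,
    positive_max = invitro$assay_positive_max,
    positive_therapeutic = positive_therapeutic,
    category_max = classify_outcome(invitro$assay_positive_max, gadr),
    category_therapeutic = classify_outcome(positive_therapeutic, gadr),
    stringsAsFactors = FALSE
  )
  if (verify) {
    verify_categories(out$compound, out$category_max,
                      invitro$outcome_max_dose, "maximum-dose")
    verify_categories(out$compound, out$category_therapeutic,
                      invitro$outcome_therapeutic_dose, "therapeutic-dose")
  }
  out
}

#' Score the charcoal-meal table against clinical labels
#'
#' A compound is assay-positive when it changed intestinal transit
#' (`charcoal_effect` other than `"NC"`) at a dose within the 50-fold
#' exposure window (`effect_within_window`).
#'
#' @param clinical Clinical table from [load_clinical_table()].
#' @param charcoal Charcoal-meal table from [load_charcoal_table()].
#' @param verify Check recomputed categories against the transcribed
#'   outcome column?
#' @return Data frame with per-compound calls and categories.
#' @export
score_charcoal <- function(clinical, charcoal, verify = TRUE) {
  stopifnot(identical(clinical$compound, charcoal$compound))
  gadr <- is_motility_gadr(clinical$clinical_finding)
  positive <- charcoal$charcoal_effect != "NC" &
    !is.na(charcoal$effect_within_window) & charcoal$effect_within_window
  out <- data.frame(
    compound = charcoal$compound,
    clinical_gadr = gadr,
    charcoal_effect = charcoal$charcoal_effect,
    positive = positive,
    category = classify_outcome(positive, gadr),
    stringsAsFactors = FALSE
  )
  if (verify) {
    verify_categories(out$compound, out$category,
                      charcoal$predictive_outcome, "charcoal-meal")
  }
  out
}

verify_categories <- function(compound, recomputed, transcribed, label) {
  bad <- compound[recomputed != transcribed]
  if (length(bad) > 0) {
    stop(sprintf(
      "recomputed %s categories disagree with the transcribed table for: %s",
      label, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

parse_concentrations <- function(x) {
  out <- as.numeric(strsplit(x, ";", fixed = TRUE)[[1]])
  if (anyNA(out) || any(out <= 0) || is.unsorted(out, strictly = TRUE)) {
    stop("malformed tested-concentration list: ", x, call. = FALSE)
  }
  out
}
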