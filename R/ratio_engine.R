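# PFS-ratio engine: consecutive-line pairs, ratios with censoring semantics,
# benefit classification, naive and Kaplan-Meier median ratios per sequence.

pair_modes <- c("consecutive_all_lines", "after_line1_only", "after_specific_therapy")

#' Extract consecutive-line sequence pairs from therapy courses
#'
#' Builds one (PFS1, PFS2) pair per couple of consecutive treatment lines
#' (line i followed by line i + 1) across all patients. The antecedent line
#' must be event-terminated: a PFS1 interval without documented progression
#' gives no valid ratio denominator, so such candidate pairs are excluded and
#' recorded (attribute `"exclusions"`) rather than silently dropped, as are
#' pairs with a nonpositive PFS1.
#'
#' @param records A cohort tibble/data.frame with columns `patient_id`,
#'   `line_number`, `therapy`, `pfs_months`, `progression_event` and optionally
#'   `histology`, `primary_site` (carried through when present).
#' @param mode `"consecutive_all_lines"` (default) pairs every consecutive
#'   couple; `"after_line1_only"` restricts to first-line antecedents (the
#'   PFS1/PFS2 analysis proper); `"after_specific_therapy"` keeps pairs whose
#'   antecedent therapy equals `therapy`.
#' @param therapy Antecedent therapy label, required for
#'   `mode = "after_specific_therapy"`.
#'
#' @return A tibble of pairs (`patient_id`, subgroup columns, `therapy1`,
#'   `therapy2`, `line1`, `line2`, `pfs1_months`, `pfs2_months`, `event2`)
#'   with an `"exclusions"` attribute (tibble: `patient_id`, `line1`,
#'   `therapy1`, `reason`). Patients with fewer than two lines contribute no
#'   pairs; duplicated (patient, line) combinations are an error.
#' @export
extract_pairs <- function(records,
                          mode = c("consecutive_all_lines", "after_line1_only",
                                   "after_specific_therapy"),
                          therapy = NULL) {
  mode <- match.arg(mode)
  records <- tibble::as_tibble(records)
  required <- c("patient_id", "line_number", "therapy", "pfs_months",
                "progression_event")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(records[c("patient_id", "line_number")])) {
    stop("duplicated (patient_id, line_number) combinations", call. = FALSE)
  }
  if (mode == "after_specific_therapy" && is.null(therapy)) {
    stop('`therapy` must be given for mode = "after_specific_therapy"',
         call. = FALSE)
  }

  extras <- intersect(c("histology", "primary_site"), names(records))
  cand <- records |>
    dplyr::arrange(.data$patient_id, .data$line_number) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(
      next_line = dplyr::lead(.data$line_number),
      therapy2 = dplyr::lead(.data$therapy),
      pfs2_months = dplyr::lead(.data$pfs_months),
      event2 = dplyr::lead(.data$progression_event)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$next_line),
                  .data$next_line == .data$line_number + 1L)

  cand <- switch(mode,
    consecutive_all_lines = cand,
    after_line1_only = dplyr::filter(cand, .data$line_number == 1L),
    after_specific_therapy = dplyr::filter(cand, .data$therapy == !!therapy)
  )

  excluded <- dplyr::filter(cand, !.data$progression_event | .data$pfs_months <= 0)
  exclusions <- tibble::tibble(
    patient_id = excluded$patient_id,
    line1 = excluded$line_number,
    therapy1 = excluded$therapy,
    reason = ifelse(excluded$pfs_months <= 0, "pfs1_nonpositive", "pfs1_censored")
  )
  kept <- dplyr::filter(cand, .data$progression_event & .data$pfs_months > 0)

  pairs <- tibble::tibble(
    patient_id = kept$patient_id,
    therapy1 = kept$therapy,
    therapy2 = kept$therapy2,
    line1 = as.integer(kept$line_number),
    line2 = as.integer(kept$next_line),
    pfs1_months = kept$pfs_months,
    pfs2_months = kept$pfs2_months,
    event2 = kept$event2
  )
  for (col in extras) pairs[[col]] <- kept[[col]]
  pairs <- pairs[c("patient_id", extras, setdiff(names(pairs), c("patient_id", extras)))]
  if (nrow(exclusions)) {
    message(nrow(exclusions), " candidate pair(s) excluded (",
            paste(unique(exclusions$reason), collapse = ", "), ")")
  }
  attr(pairs, "exclusions") <- exclusions
  pairs
}

#' Compute PFS ratios for sequence pairs
#'
#' Adds `ratio = pfs2_months / pfs1_months` and its censoring status. A pair
#' whose PFS2 is censored carries a right-censored ratio: the true ratio is at
#' least the recorded value. A zero PFS2 (progression at treatment start)
#' yields ratio 0 recorded as an event, with a warning; dropping such pairs
#' would bias ratios upward.
#'
#' @param pairs A tibble from [extract_pairs()] (columns `pfs1_months`,
#'   `pfs2_months`, `event2`).
#' @return `pairs` with columns `ratio` (dimensionless) and `event` appended.
#' @export
compute_ratios <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  req <- c("pfs1_months", "pfs2_months", "event2")
  if (!all(req %in% names(pairs))) {
    stop("`pairs` must contain columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(pairs$pfs1_months == 0)) {
    stop("pfs1 = 0 gives an undefined ratio", call. = FALSE)
  }
  if (any(pairs$pfs1_months < 0) || any(pairs$pfs2_months < 0)) {
    stop("negative PFS durations are not allowed", call. = FALSE)
  }
  zero2 <- pairs$pfs2_months == 0
  if (any(zero2)) {
    warning(sum(zero2), " pair(s) with pfs2 = 0: ratio 0 recorded as an event",
            call. = FALSE)
  }
  pairs$ratio <- pairs$pfs2_months / pairs$pfs1_months
  pairs$event <- pairs$event2 | zero2
  pairs
}

#' Classify PFS ratios against the benefit thresholds
#'
#' Thresholds are applied as printed: `high` when ratio > 1.3, `low` when
#' ratio < 0.77, `intermediate` otherwise; the classes partition the
#' nonnegative reals. A separate `excellent` flag marks ratios >= 1.33, the
#' classical bar for an unanticipated improvement under the subsequent
#' therapy.
#'
#' @param ratio Numeric vector of nonnegative PFS ratios.
#' @return A tibble with columns `ratio`, `label` (factor
#'   low/intermediate/high) and `excellent` (logical).
#' @examples
#' classify_ratio(c(1.86, 1.0, 0.46))
#' @export
classify_ratio <- function(ratio) {
  if (!is.numeric(ratio) || anyNA(ratio) || any(ratio < 0)) {
    stop("`ratio` must be nonnegative and non-missing", call. = FALSE)
  }
  label <- ifelse(ratio > 1.3, "high", ifelse(ratio < 0.77, "low", "intermediate"))
  tibble::tibble(
    ratio = ratio,
    label = factor(label, levels = c("low", "intermediate", "high")),
    excellent = ratio >= 1.33
  )
}

#' Naive (censoring-ignoring) median PFS ratio
#'
#' Sample median of the recorded ratios, treating censored ratios at face
#' value, censoring flags ignored. For an even sample the default is the
#' conventional midpoint of the two middle order statistics;
#' `convention = "lower"` takes the lower one, matching the step-function
#' convention of the Kaplan-Meier median.
#'
#' @param ratio Numeric vector of ratios.
#' @param convention `"midpoint"` (default) or `"lower"`.
#' @return A single number.
#' @export
naive_median_ratio <- function(ratio, convention = c("midpoint", "lower")) {
  convention <- match.arg(convention)
  if (length(ratio) == 0L) stop("empty ratio vector", call. = FALSE)
  if (anyNA(ratio)) stop("missing ratios are not allowed", call. = FALSE)
  if (convention == "midpoint") {
    stats::median(ratio)
  } else {
    sort(ratio)[floor((length(ratio) + 1) / 2)]
  }
}

#' Censoring-aware median PFS ratio (Kaplan-Meier)
#'
#' Treats the ratio as the duration axis of a product-limit fit (event =
#' progression on the subsequent therapy) and returns the Kaplan-Meier median
#' with its confidence interval, so censored ratios (lower bounds) push the
#' estimate up rather than drag it down.
#'
#' @param ratio Numeric vector of nonnegative ratios.
#' @param event Logical event indicator (progression on therapy 2).
#' @param conf_level Confidence level (default 0.95).
#' @return A `km_summary` (see [km_median_ci()]); if no events at all, an
#'   all-`NA` ("NE") summary with a warning.
#' @export
km_median_ratio <- function(ratio, event, conf_level = 0.95) {
  if (is.numeric(event)) event <- event != 0
  if (length(ratio) == 0L) stop("empty ratio vector", call. = FALSE)
  if (!any(event)) {
    warning("no events: median ratio not estimable", call. = FALSE)
    return(structure(
      list(median = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
           conf_level = conf_level, conf_type = "log-log",
           n = length(ratio), n_events = 0L),
      class = "km_summary"
    ))
  }
  km_median_ci(fit_km(ratio, event, conf_level = conf_level), conf_level)
}

#' Compare PFS-ratio distributions between groups (log-rank)
#'
#' Applies the k-sample log-rank test on the ratio axis, e.g. grouping ratios
#' by the subsequent therapy. Censored ratios contribute to the risk sets
#' exactly as censored durations would.
#'
#' @inheritParams km_median_ratio
#' @param group Grouping vector (e.g. therapy 2 label).
#' @return A `logrank_test` object.
#' @export
compare_ratio_groups <- function(ratio, event, group) {
  logrank_test(ratio, event, group)
}

#' Summarize PFS ratios per therapy sequence and subgroup
#'
#' One row per (therapy1, therapy2, subgroup) cell: sample size, naive and
#' Kaplan-Meier median ratios with CI, and the censoring-ignoring percentage
#' of ratios above 1.3. Cells with fewer than `min_n` observations keep their
#' sample size but have all statistics suppressed (`NA`), the minimum-count
#' reporting rule used for sequence heatmaps.
#'
#' @param pairs Pair tibble from [extract_pairs()]; ratios are computed with
#'   [compute_ratios()] if absent.
#' @param group_by Character vector of subgroup columns (default
#'   `"histology"` when present, else none).
#' @param min_n Minimum cell size for reporting statistics (default 4).
#' @param conf_level Confidence level for KM medians.
#' @return A tibble with columns `therapy1`, `therapy2`, the subgroup columns,
#'   `n`, `n_events`, `naive_median`, `km_median`, `km_ci_low`, `km_ci_high`,
#'   `pct_above_1_3`, `suppressed`.
#' @export
summarize_sequences <- function(pairs, group_by = NULL, min_n = 4,
                                conf_level = 0.95) {
  pairs <- tibble::as_tibble(pairs)
  if (!"ratio" %in% names(pairs)) pairs <- compute_ratios(pairs)
  if (is.null(group_by)) {
    group_by <- intersect("histology", names(pairs))
  }
  if (min_n < 1) stop("`min_n` must be >= 1", call. = FALSE)
  keys <- c("therapy1", "therapy2", group_by)
  out <- pairs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(cell, key) {
      km <- suppressWarnings(km_median_ratio(cell$ratio, cell$event, conf_level))
      tibble::tibble(
        n = nrow(cell),
        n_events = sum(cell$event),
        naive_median = naive_median_ratio(cell$ratio),
        km_median = km$median,
        km_ci_low = km$ci_low,
        km_ci_high = km$ci_high,
        pct_above_1_3 = 100 * mean(cell$ratio > 1.3)
      )
    }) |>
    dplyr::ungroup()
  suppressed <- out$n < min_n
  stat_cols <- c("naive_median", "km_median", "km_ci_low", "km_ci_high",
                 "pct_above_1_3")
  out[suppressed, stat_cols] <- NA_real_
  out$suppressed <- suppressed
  out
}
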