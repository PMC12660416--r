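# Cohort table IO, validation, sequence-transition edge lists, and the
# end-to-end report pipeline.

cohort_required_cols <- c("patient_id", "histology", "primary_site",
                          "line_number", "therapy", "pfs_months",
                          "progression_event")
cohort_optional_cols <- c("os_months", "death_event")

#' Read and validate a cohort table
#'
#' Reads a comma-separated, UTF-8 therapy-course table (one row per treatment
#' line; missing token `"NA"`; durations in months) and validates it row by
#' row. Structural problems (a missing required column) are an error;
#' row-level problems (non-numeric or negative PFS, missing event flag,
#' invalid line number, duplicated patient/line) reject the offending rows
#' with a reason, collected in the `"issues"` attribute and summarized in a
#' warning — never silently dropped.
#'
#' @param path Path to a CSV file with columns `patient_id`, `histology`,
#'   `primary_site`, `line_number`, `therapy`, `pfs_months`,
#'   `progression_event` and optionally `os_months`, `death_event`.
#' @return A validated tibble of treatment records, with attribute `"issues"`
#'   (tibble: `row`, `patient_id`, `problem`).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(
    path, na = "NA", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  missing_cols <- setdiff(cohort_required_cols, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  validate_cohort(raw)
}

#' Validate cohort records
#'
#' @param records A data frame of (possibly character-typed) treatment rows.
#' @return The clean, typed records with an `"issues"` attribute; see
#'   [read_cohort()].
#' @export
validate_cohort <- function(records) {
  records <- tibble::as_tibble(records)
  n <- nrow(records)
  issues <- list()
  note <- function(rows, problem) {
    if (length(rows)) {
      issues[[length(issues) + 1L]] <<- tibble::tibble(
        row = rows, patient_id = as.character(records$patient_id[rows]),
        problem = problem
      )
    }
  }

  pfs <- suppressWarnings(as.numeric(records$pfs_months))
  line <- suppressWarnings(as.numeric(records$line_number))
  ev <- parse_flag(records$progression_event)

  note(which(is.na(pfs) | !is.finite(pfs)), "pfs_months missing or non-numeric")
  note(which(!is.na(pfs) & pfs < 0), "pfs_months negative")
  note(which(is.na(line) | line < 1 | line != round(line)),
       "line_number missing or not a positive integer")
  note(which(is.na(ev)), "progression_event missing or not interpretable")
  note(which(is.na(records$patient_id)), "patient_id missing")
  dup <- duplicated(data.frame(records$patient_id, line))
  note(which(dup & !is.na(line)), "duplicated (patient_id, line_number)")

  issues <- if (length(issues)) dplyr::bind_rows(issues) else {
    tibble::tibble(row = integer(0), patient_id = character(0),
                   problem = character(0))
  }
  bad <- unique(issues$row)
  keep <- setdiff(seq_len(n), bad)

  out <- tibble::tibble(
    patient_id = as.character(records$patient_id[keep]),
    histology = as.character(records$histology[keep]),
    primary_site = as.character(records$primary_site[keep]),
    line_number = as.integer(line[keep]),
    therapy = as.character(records$therapy[keep]),
    pfs_months = pfs[keep],
    progression_event = ev[keep]
  )
  for (col in cohort_optional_cols) {
    if (col %in% names(records)) {
      out[[col]] <- if (col == "death_event") {
        parse_flag(records[[col]][keep])
      } else {
        suppressWarnings(as.numeric(records[[col]][keep]))
      }
    }
  }
  out <- dplyr::arrange(out, .data$patient_id, .data$line_number)

  # Contiguity is informational: gaps simply produce no pair at the gap.
  gaps <- out |>
    dplyr::summarise(
      contiguous = all(diff(.data$line_number) == 1L) &&
        .data$line_number[1] == 1L,
      .by = "patient_id"
    ) |>
    dplyr::filter(!.data$contiguous)
  if (nrow(gaps)) {
    issues <- dplyr::bind_rows(issues, tibble::tibble(
      row = NA_integer_, patient_id = gaps$patient_id,
      problem = "line numbers not contiguous from 1 (kept; no pair across gaps)"
    ))
  }
  if (length(bad)) {
    warning(length(bad), " row(s) rejected during validation; see attr(x, \"issues\")",
            call. = FALSE)
  }
  attr(out, "issues") <- issues
  out
}

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Write a cohort table
#'
#' Canonical CSV serialization of treatment records (UTF-8, `.` decimal,
#' missing token `"NA"`); the inverse of [read_cohort()] up to column typing.
#'
#' @param records Cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  readr::write_csv(tibble::as_tibble(records), path, na = "NA")
  invisible(path)
}

#' Therapy-transition edge list (Sankey-ready)
#'
#' Counts consecutive therapy transitions per line position, optionally
#' restricted to a histology subset. The per-line outflow of first-line
#' therapies equals the number of patients with at least two (contiguous)
#' lines in the subset.
#'
#' @param records Validated cohort tibble.
#' @param histology Optional character vector of histologies to keep.
#' @return Tibble with `source`, `target` (label + line, e.g. `"SSA (L1)"`),
#'   `therapy1`, `line1`, `therapy2`, `line2`, `count`.
#' @export
sequence_frequencies <- function(records, histology = NULL) {
  records <- tibble::as_tibble(records)
  if (!is.null(histology)) {
    records <- dplyr::filter(records, .data$histology %in% !!histology)
  }
  empty <- tibble::tibble(source = character(0), target = character(0),
                          therapy1 = character(0), line1 = integer(0),
                          therapy2 = character(0), line2 = integer(0),
                          count = integer(0))
  if (nrow(records) == 0L) return(empty)
  edges <- records |>
    dplyr::arrange(.data$patient_id, .data$line_number) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(next_line = dplyr::lead(.data$line_number),
                  therapy2 = dplyr::lead(.data$therapy)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$next_line),
                  .data$next_line == .data$line_number + 1L) |>
    dplyr::count(.data$therapy, .data$line_number, .data$therapy2,
                 .data$next_line, name = "count")
  if (nrow(edges) == 0L) return(empty)
  tibble::tibble(
    source = sprintf("%s (L%d)", edges$therapy, edges$line_number),
    target = sprintf("%s (L%d)", edges$therapy2, edges$next_line),
    therapy1 = edges$therapy, line1 = as.integer(edges$line_number),
    therapy2 = edges$therapy2, line2 = as.integer(edges$next_line),
    count = as.integer(edges$count)
  ) |>
    dplyr::arrange(.data$line1, dplyr::desc(.data$count))
}

#' Run the full PFS-ratio analysis pipeline
#'
#' Orchestrates the analysis end to end on a validated cohort: sequence pairs
#' and exclusions, ratio observations with benefit classes, per-sequence
#' summaries (naive + Kaplan-Meier medians, exceedance percentages, minimum-n
#' suppression), log-rank comparisons of ratio distributions between
#' subsequent therapies sharing an antecedent, first/second-line PFS1-PFS2
#' correlation estimates (complete-case Spearman and censored copula),
#' per-line KM medians of PFS, overall-survival KM summaries per histology
#' when OS columns are present, the therapy-transition edge list, and a
#' machine-readable run manifest. Reruns on identical input produce
#' byte-identical outputs (the pipeline itself draws no random numbers).
#'
#' @param records Validated cohort tibble (see [read_cohort()] /
#'   [generate_cohort()]).
#' @param mode Pairing mode passed to [extract_pairs()].
#' @param group_by Subgroup columns for [summarize_sequences()].
#' @param min_n Minimum cell size for reported statistics and group tests.
#' @param conf_level Confidence level used throughout.
#' @param out_dir Optional directory; when given, all tables are written as
#'   CSV plus a JSON `manifest.json` (medians that are not estimable are
#'   `NA`/`null` in machine-readable output and printed as `"NE"`).
#' @return An object of class `pfs_ratio_report`: list with elements
#'   `counts`, `pairs`, `exclusions`, `sequence_summaries`,
#'   `sequence_summaries_overall`, `group_tests`, `correlation`,
#'   `km_by_line`, `os_summaries` (or `NULL`), `edges`, `notes`, `manifest`.
#' @export
run_pipeline <- function(records,
                         mode = "consecutive_all_lines",
                         group_by = NULL, min_n = 4, conf_level = 0.95,
                         out_dir = NULL) {
  records <- tibble::as_tibble(records)
  notes <- character(0)

  pairs <- suppressMessages(extract_pairs(records, mode = mode))
  exclusions <- attr(pairs, "exclusions")
  if (nrow(pairs)) {
    pairs <- compute_ratios(pairs)
    cls <- classify_ratio(pairs$ratio)
    pairs$label <- cls$label
    pairs$excellent <- cls$excellent
  } else {
    notes <- c(notes, "no usable sequence pairs")
  }

  summaries <- if (nrow(pairs)) {
    summarize_sequences(pairs, group_by = group_by, min_n = min_n,
                        conf_level = conf_level)
  } else tibble::tibble()
  summaries_overall <- if (nrow(pairs)) {
    summarize_sequences(pairs, group_by = character(0), min_n = min_n,
                        conf_level = conf_level)
  } else tibble::tibble()

  # Ratio-distribution comparisons: subsequent therapies sharing an
  # antecedent, groups of at least min_n, at least one event.
  group_tests <- tibble::tibble(therapy1 = character(0), k = integer(0),
                                n = integer(0), statistic = numeric(0),
                                df = integer(0), p_value = numeric(0))
  if (nrow(pairs)) {
    for (t1 in unique(pairs$therapy1)) {
      sub <- pairs[pairs$therapy1 == t1, ]
      sizes <- table(sub$therapy2)
      keep <- names(sizes)[sizes >= min_n]
      sub <- sub[sub$therapy2 %in% keep, ]
      if (length(keep) >= 2 && any(sub$event)) {
        lr <- logrank_test(sub$ratio, sub$event, sub$therapy2)
        group_tests <- dplyr::bind_rows(group_tests, tibble::tibble(
          therapy1 = t1, k = length(keep), n = nrow(sub),
          statistic = lr$statistic, df = lr$df, p_value = lr$p_value
        ))
      }
    }
    group_tests <- dplyr::arrange(group_tests, .data$therapy1)
    if (nrow(group_tests) == 0L) {
      notes <- c(notes, "no antecedent therapy had >= 2 subsequent-therapy groups for a log-rank comparison")
    }
  }

  # PFS1-PFS2 correlation on first-to-second-line pairs.
  correlation <- NULL
  l12 <- if (nrow(pairs)) pairs[pairs$line1 == 1L & pairs$line2 == 2L, ] else pairs
  if (nrow(l12) >= 10 && sum(l12$event2) >= 3) {
    correlation <- list(
      spearman = spearman_complete(l12$pfs1_months, l12$pfs2_months,
                                   l12$event2, conf_level = conf_level),
      copula = censored_copula_rho(l12$pfs1_months, l12$pfs2_months,
                                   event2 = l12$event2,
                                   conf_level = conf_level)
    )
  } else {
    notes <- c(notes, "too few first/second-line pairs for correlation estimates")
  }

  # Per-(therapy, line) PFS KM medians.
  km_by_line <- records |>
    dplyr::group_by(.data$therapy, .data$line_number) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < min_n || !any(d$progression_event)) {
        return(tibble::tibble(n = nrow(d), n_events = sum(d$progression_event),
                              median = NA_real_, ci_low = NA_real_,
                              ci_high = NA_real_))
      }
      s <- km_median_ci(fit_km(d$pfs_months, d$progression_event, conf_level))
      tibble::tibble(n = s$n, n_events = s$n_events, median = s$median,
                     ci_low = s$ci_low, ci_high = s$ci_high)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$line_number, .data$therapy)

  # Overall survival by histology, when recorded.
  os_summaries <- NULL
  if (all(c("os_months", "death_event") %in% names(records))) {
    os <- records |>
      dplyr::filter(.data$line_number == 1L, !is.na(.data$os_months),
                    !is.na(.data$death_event))
    if (nrow(os) >= min_n && any(os$death_event)) {
      os_summaries <- os |>
        dplyr::group_by(.data$histology) |>
        dplyr::group_modify(function(d, key) {
          if (nrow(d) < min_n || !any(d$death_event)) {
            return(tibble::tibble(n = nrow(d), n_events = sum(d$death_event),
                                  median = NA_real_, ci_low = NA_real_,
                                  ci_high = NA_real_))
          }
          s <- km_median_ci(fit_km(d$os_months, d$death_event, conf_level))
          tibble::tibble(n = s$n, n_events = s$n_events, median = s$median,
                         ci_low = s$ci_low, ci_high = s$ci_high)
        }) |>
        dplyr::ungroup()
      attr(os_summaries, "logrank") <-
        if (length(unique(os$histology)) >= 2) {
          logrank_test(os$os_months, os$death_event, os$histology)
        } else NULL
    }
  }

  edges <- sequence_frequencies(records)

  counts <- list(
    n_patients = length(unique(records$patient_id)),
    n_records = nrow(records),
    n_pairs = nrow(pairs),
    n_excluded = nrow(exclusions)
  )
  if (counts$n_patients == 1L) {
    notes <- c(notes, "single-patient cohort: no group comparisons attempted")
  }
  manifest <- list(
    package = "pfsratio",
    version = as.character(utils::packageVersion("pfsratio")),
    settings = list(mode = mode, min_n = min_n, conf_level = conf_level,
                    median_ci = "log-log (complementary log-log) pointwise inversion",
                    ratio_thresholds = list(high = 1.3, low = 0.77,
                                            excellent = 1.33),
                    naive_median_convention = "midpoint",
                    multiplicity_adjustment = "none (exploratory)"),
    counts = counts,
    notes = notes
  )

  bundle <- structure(
    list(counts = counts, pairs = pairs, exclusions = exclusions,
         sequence_summaries = summaries,
         sequence_summaries_overall = summaries_overall,
         group_tests = group_tests, correlation = correlation,
         km_by_line = km_by_line, os_summaries = os_summaries,
         edges = edges, notes = notes, manifest = manifest),
    class = "pfs_ratio_report"
  )
  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  bundle
}

#' Write a report bundle to a directory
#'
#' @param bundle A `pfs_ratio_report` from [run_pipeline()].
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "pfs_ratio_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    readr::write_csv(tibble::as_tibble(x), file.path(out_dir, name), na = "NA")
  }
  wr(bundle$pairs, "pairs.csv")
  wr(bundle$exclusions, "exclusions.csv")
  wr(bundle$sequence_summaries, "sequence_summaries.csv")
  wr(bundle$sequence_summaries_overall, "sequence_summaries_overall.csv")
  wr(bundle$group_tests, "group_tests.csv")
  wr(bundle$km_by_line, "km_by_line.csv")
  wr(bundle$edges, "edges.csv")
  if (!is.null(bundle$os_summaries)) wr(bundle$os_summaries, "os_summaries.csv")
  if (!is.null(bundle$correlation)) {
    cors <- dplyr::bind_rows(lapply(bundle$correlation, function(e) {
      tibble::tibble(method = e$method, rho = e$rho, ci_low = e$ci_low,
                     ci_high = e$ci_high,
                     p_value = if (is.null(e$p_value)) NA_real_ else e$p_value,
                     n_used = e$n_used)
    }))
    wr(cors, "correlation.csv")
  }
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(out_dir)
}

#' @export
print.pfs_ratio_report <- function(x, ...) {
  cat(sprintf(
    "PFS-ratio report: %d patients, %d lines, %d pairs (%d excluded)\n",
    x$counts$n_patients, x$counts$n_records, x$counts$n_pairs,
    x$counts$n_excluded))
  if (nrow(x$group_tests)) {
    cat("Ratio-distribution comparisons (log-rank):\n")
    print(as.data.frame(x$group_tests))
  }
  if (!is.null(x$correlation)) {
    print(x$correlation$spearman)
    print(x$correlation$copula)
  }
  for (nt in x$notes) cat("note:", nt, "\n")
  invisible(x)
}
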