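cohort_columns <- function() c("case_index", "date", continuous_metrics())

validate_cohort <- function(cohort) {
  if (!"case_index" %in% names(cohort)) {
    stop("Cohort table must contain a `case_index` column.", call. = FALSE)
  }
  idx <- cohort$case_index
  if (anyNA(idx)) stop("`case_index` contains missing values.", call. = FALSE)
  dup <- unique(idx[duplicated(idx)])
  if (length(dup) > 0L) {
    stop("Duplicate case_index value(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (!all(sort(idx) == seq_along(idx))) {
    stop("case_index values must be contiguous from 1.", call. = FALSE)
  }
  reg <- metric_registry()
  for (m in reg$metric) {
    if (!m %in% names(cohort)) next
    v <- cohort[[m]]
    lo <- reg$lower[reg$metric == m]
    hi <- reg$upper[reg$metric == m]
    bad <- which(!is.na(v) & (v < lo | v > hi | (m == "operation_time" & v <= 0)))
    if (length(bad) > 0L) {
      stop("Metric '", m, "' out of valid range [", lo, ", ", hi,
           "] at case_index ", paste(cohort$case_index[bad], collapse = ", "),
           ".", call. = FALSE)
    }
  }
  dplyr::arrange(cohort, .data$case_index)
}

#' Read a per-case cohort table
#'
#' Loads a chronologically ordered surgical case series from a CSV file
#' (comma-separated, UTF-8, header row, decimal point). Expected columns are
#' `case_index` plus any subset of the outcome metrics in [metric_registry()]
#' and an optional ISO-8601 `date`. Empty outcome cells stay missing (`NA`);
#' they are never imputed. An optional `schema` renames non-standard column
#' headers: a named character vector mapping standard name -> file column.
#'
#' @param path CSV file path.
#' @param schema Optional named character vector, e.g.
#'   `c(oss = "oxford_score")`.
#' @return A tibble sorted by `case_index`.
#' @export
load_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("Cohort file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    for (std in names(schema)) {
      src <- schema[[std]]
      if (!src %in% names(raw)) {
        stop("Schema maps '", std, "' to absent column '", src, "'.",
             call. = FALSE)
      }
      names(raw)[names(raw) == src] <- std
    }
  }
  known <- intersect(cohort_columns(), names(raw))
  if (!"case_index" %in% known) {
    stop("Cohort file lacks a `case_index` column (after schema mapping).",
         call. = FALSE)
  }
  out <- raw[, known, drop = FALSE]
  for (m in intersect(continuous_metrics(), names(out))) {
    if (!is.numeric(out[[m]])) {
      bad <- which(!is.na(out[[m]]) & is.na(suppressWarnings(as.numeric(out[[m]]))))
      if (length(bad) > 0L) {
        stop("Malformed value in column '", m, "' at data row ", bad[1],
             ".", call. = FALSE)
      }
      out[[m]] <- suppressWarnings(as.numeric(out[[m]]))
    }
  }
  out$case_index <- as.integer(out$case_index)
  validate_cohort(tibble::as_tibble(out))
}

#' Write a cohort table to CSV
#'
#' Inverse of [load_cohort()]: writes the standard comma-separated dialect so
#' that `load_cohort(write_cohort(x, f))` round-trips exactly.
#'
#' @param cohort Cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  readr::write_csv(cohort, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read or write a long-format complication log
#'
#' Complication events live in a companion CSV with one row per event:
#' `case_index`, `description`, `severity` (`minor`/`major`, may be empty when
#' classification is delegated to [classify_severity()]),
#' `months_from_surgery`, `attributable` (logical; `FALSE` marks events, such
#' as post-operative falls, unrelated to the prosthesis placement and hence
#' excluded from every rate computation), and optional logical annotation
#' columns `revision_surgery`, `long_term_medication`, `outcome_compromised`.
#'
#' @param path CSV file path.
#' @return A tibble of complication events.
#' @export
load_complications <- function(path) {
  if (!file.exists(path)) {
    stop("Complications file not found: ", path, call. = FALSE)
  }
  ev <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("case_index", "description", "severity", "attributable")
  missing_cols <- setdiff(needed, names(ev))
  if (length(missing_cols) > 0L) {
    stop("Complications file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ev$case_index <- as.integer(ev$case_index)
  ev$attributable <- as.logical(ev$attributable)
  bad <- which(!is.na(ev$severity) & !ev$severity %in% c("minor", "major"))
  if (length(bad) > 0L) {
    stop("Invalid severity '", ev$severity[bad[1]], "' at data row ", bad[1],
         "; must be 'minor' or 'major'.", call. = FALSE)
  }
  tibble::as_tibble(ev)
}

#' @rdname load_complications
#' @param events Complication-event tibble.
#' @export
write_complications <- function(events, path) {
  readr::write_csv(events, path, na = "", progress = FALSE)
  invisible(path)
}

#' Extract one metric's observed series
#'
#' Drops cases where the metric is missing and renumbers the remainder with a
#' consecutive `case_position` (1, 2, ...) while keeping the original global
#' `case_index`. The CUSUM x-axis and the trend regressor both use
#' `case_position`, so charts for different metrics stay per-metric
#' consecutive even when missingness differs between metrics.
#'
#' @param cohort Cohort tibble.
#' @param metric A continuous metric id.
#' @return A tibble with `case_position`, `case_index`, `value`.
#' @export
metric_series <- function(cohort, metric) {
  if (!metric %in% continuous_metrics()) {
    stop("Unknown continuous metric '", metric, "'.", call. = FALSE)
  }
  if (!metric %in% names(cohort)) {
    return(tibble::tibble(case_position = integer(), case_index = integer(),
                          value = numeric()))
  }
  cohort <- dplyr::arrange(cohort, .data$case_index)
  keep <- !is.na(cohort[[metric]])
  tibble::tibble(
    case_position = seq_len(sum(keep)),
    case_index = cohort$case_index[keep],
    value = cohort[[metric]][keep]
  )
}

#' Descriptive summary of a cohort
#'
#' Summarizes each outcome metric over its non-missing values by median and
#' interquartile range. The quartile estimator defaults to linear
#' interpolation between order statistics (`type = 7`); other conventions can
#' be selected via `quartile_type` (see [stats::quantile()]). Metrics that are
#' entirely missing or absent are flagged (`n = 0`, `NA` summary entries)
#' rather than reported as zero. The summary ignores chronology: permuting the
#' rows of `cohort` does not change it.
#'
#' @param cohort Cohort tibble.
#' @param quartile_type Integer passed to [stats::quantile()]; default 7.
#' @return A tibble with `metric`, `n`, `median`, `q1`, `q3`.
#' @export
#' @examples
#' co <- tibble::tibble(case_index = 1:5, oss = c(1, 2, 3, 4, 5))
#' summarize_cohort(co)
summarize_cohort <- function(cohort, quartile_type = 7) {
  cohort <- validate_cohort(cohort)
  rows <- lapply(continuous_metrics(), function(m) {
    v <- if (m %in% names(cohort)) cohort[[m]][!is.na(cohort[[m]])] else numeric()
    if (length(v) == 0L) {
      tibble::tibble(metric = m, n = 0L, median = NA_real_,
                     q1 = NA_real_, q3 = NA_real_)
    } else {
      q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = quartile_type))
      tibble::tibble(metric = m, n = length(v), median = q[2],
                     q1 = q[1], q3 = q[3])
    }
  })
  dplyr::bind_rows(rows)
}
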