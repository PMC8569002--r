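#' Registry of outcome metrics
#'
#' The package tracks seven continuous per-case outcome metrics plus a binary
#' complication indicator. Continuous metrics have fixed units and a valid
#' range used for input validation and for clipping simulated draws:
#' the Oxford Shoulder Score (`oss`, 0-48 points), the Constant Shoulder
#' Score (`css`, 0-100 points), four range-of-motion angles in degrees
#' (`flexion`, `extension`, `abduction`, `external_rotation`, 0-180), and
#' `operation_time` in minutes (strictly positive).
#'
#' @return A tibble with columns `metric`, `unit`, `lower`, `upper`.
#' @export
#' @examples
#' metric_registry()
metric_registry <- function() {
  tibble::tibble(
    metric = c(
      "oss", "css", "flexion", "extension", "abduction",
      "external_rotation", "operation_time"
    ),
    unit = c(
      "points", "points", "degrees", "degrees", "degrees",
      "degrees", "minutes"
    ),
    lower = c(0, 0, 0, 0, 0, 0, 0),
    upper = c(48, 100, 180, 180, 180, 180, Inf)
  )
}

continuous_metrics <- function() metric_registry()$metric

#' Construct a target specification for one metric
#'
#' A target specification couples a metric with the performance benchmark the
#' CUSUM chart compares each case against, the direction in which values are
#' "good", and the provenance of the benchmark. Targets with
#' `source = "cohort_mean"` carry no fixed number: they must be resolved
#' against the observed series (see [resolve_cohort_mean()]) before charting.
#'
#' @param metric Metric identifier (see [metric_registry()], plus
#'   `"complication"` for the binary event channel).
#' @param target Numeric target level in the metric's units, or `NA` when the
#'   source defers resolution to the data.
#' @param direction `"higher_better"` or `"lower_better"`.
#' @param source `"literature"`, `"cohort_mean"` or `"cohort_probability"`.
#' @return A one-row tibble of class `target_spec`.
#' @export
#' @examples
#' target_spec("css", 50, "higher_better", "literature")
target_spec <- function(metric, target, direction, source = "literature") {
  direction <- match.arg(direction, c("higher_better", "lower_better"))
  source <- match.arg(source, c("literature", "cohort_mean", "cohort_probability"))
  if (source == "cohort_mean") {
    target <- NA_real_
  } else {
    if (!is.numeric(target) || length(target) != 1L || is.na(target)) {
      stop("`target` must be a single non-missing number for source '",
           source, "'.", call. = FALSE)
    }
    reg <- metric_registry()
    if (metric %in% reg$metric[reg$unit == "degrees"] && target < 0) {
      stop("Negative target for angle metric '", metric, "'.", call. = FALSE)
    }
    if (source == "cohort_probability" && (target <= 0 || target >= 1)) {
      stop("Probability target must lie strictly in (0, 1).", call. = FALSE)
    }
  }
  out <- tibble::tibble(
    metric = as.character(metric),
    target = as.numeric(target),
    direction = direction,
    source = source
  )
  class(out) <- c("target_spec", class(out))
  out
}

#' Default target-level ledger
#'
#' The benchmarks the analysis ships with: OSS 34.5 and CSS 50 points (both
#' literature-derived), range-of-motion targets reflecting the demands of
#' daily activities in an elderly population (forward flexion 105, extension
#' 40, abduction 90, external rotation 15 degrees), operation time benchmarked
#' against the cohort's own mean, and a complication probability of 0.20 for
#' the Bernoulli CUSUM.
#'
#' @return A tibble with one row per metric (columns `metric`, `target`,
#'   `direction`, `source`).
#' @export
#' @examples
#' default_targets()
default_targets <- function() {
  dplyr::bind_rows(
    target_spec("oss", 34.5, "higher_better", "literature"),
    target_spec("css", 50, "higher_better", "literature"),
    target_spec("flexion", 105, "higher_better", "literature"),
    target_spec("extension", 40, "higher_better", "literature"),
    target_spec("abduction", 90, "higher_better", "literature"),
    target_spec("external_rotation", 15, "higher_better", "literature"),
    target_spec("operation_time", NA, "lower_better", "cohort_mean"),
    target_spec("complication", 0.20, "lower_better", "cohort_probability")
  )
}

#' Load a target-level configuration
#'
#' Reads a YAML or JSON file whose entries override the default ledger
#' ([default_targets()]). Each entry needs keys `metric`, `direction`,
#' `source`, and a numeric `target` (omitted for `cohort_mean` sources).
#' Metrics absent from the file keep their defaults; an empty or missing-file
#' path of `NULL` returns the full default ledger.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` config, or `NULL`.
#' @return A tibble like [default_targets()].
#' @export
load_targets <- function(path = NULL) {
  ledger <- default_targets()
  if (is.null(path)) {
    return(ledger)
  }
  if (!file.exists(path)) {
    stop("Target config not found: ", path, call. = FALSE)
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw) || length(raw) == 0L) {
    return(ledger)
  }
  # accept both a list of entries and a named map metric -> entry
  entries <- if (!is.null(names(raw)) && all(nzchar(names(raw)))) {
    lapply(names(raw), function(m) c(list(metric = m), raw[[m]]))
  } else {
    raw
  }
  for (e in entries) {
    if (is.null(e$metric)) {
      stop("Target config entry without a `metric` key.", call. = FALSE)
    }
    i <- match(e$metric, ledger$metric)
    if (is.na(i)) {
      stop("Unknown metric in target config: '", e$metric, "'.", call. = FALSE)
    }
    spec <- target_spec(
      metric = e$metric,
      target = if (is.null(e$target)) ledger$target[i] else e$target,
      direction = if (is.null(e$direction)) ledger$direction[i] else e$direction,
      source = if (is.null(e$source)) ledger$source[i] else e$source
    )
    ledger[i, ] <- spec
  }
  ledger
}

get_target <- function(targets, metric) {
  row <- targets[targets$metric == metric, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("No target specification for metric '", metric, "'.", call. = FALSE)
  }
  out <- row
  class(out) <- c("target_spec", class(tibble::tibble()))
  out
}
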