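new_cusum_series <- function(df, metric, target, direction, source, kind) {
  structure(
    df,
    metric = metric, target = target, direction = direction,
    target_source = source, kind = kind,
    class = c("cusum_series", class(tibble::tibble()))
  )
}

#' @export
print.cusum_series <- function(x, ...) {
  cat(sprintf(
    "<cusum_series> metric: %s | target: %s (%s, %s) | %d cases\n",
    attr(x, "metric"), format(attr(x, "target")), attr(x, "direction"),
    attr(x, "target_source"), nrow(x)
  ))
  NextMethod()
}

#' CUSUM chart for a continuous outcome
#'
#' Builds the cumulative-sum performance series of a chronologically ordered
#' outcome series against a fixed target level. Per case the chart moves by
#' the absolute difference between the observed value and the target: upward
#' when the case performed better than the target, downward when worse, and
#' not at all on a tie. Equivalently, with direction sign `d` (+1 when higher
#' values are better, -1 when lower values are better), the increment at case
#' `k` is `d * (x_k - T)`. The running sum starts from an implicit 0 before
#' the first case; no control limits, resets or burn-in are applied — the
#' chart is read visually, rising toward target-beating performance and
#' falling away from it.
#'
#' @param series Ordered numeric vector (missing values must already be
#'   dropped, e.g. via [metric_series()]), or a tibble with a `value` column
#'   (and optionally `case_position`, `case_index`).
#' @param target A [target_spec()] row with a resolved numeric target.
#' @return A `cusum_series` tibble: `case_position`, `value`, `increment`,
#'   `cumulative` (plus `case_index` when supplied), with the target recorded
#'   in attributes.
#' @export
#' @examples
#' t <- target_spec("css", 50, "higher_better")
#' continuous_cusum(c(40, 60, 55), t)
continuous_cusum <- function(series, target) {
  if (is.data.frame(series)) {
    df <- series
    if (!"value" %in% names(df)) {
      stop("Series data frame must have a `value` column.", call. = FALSE)
    }
  } else {
    df <- tibble::tibble(value = as.numeric(series))
  }
  if (nrow(df) == 0L) stop("Series is empty.", call. = FALSE)
  if (anyNA(df$value)) {
    stop("Series contains missing values; drop them first (metric_series()).",
         call. = FALSE)
  }
  if (is.na(target$target)) {
    stop("Target for '", target$metric, "' is unresolved (source '",
         target$source, "'); resolve it first with resolve_cohort_mean().",
         call. = FALSE)
  }
  if (!"case_position" %in% names(df)) df$case_position <- seq_len(nrow(df))
  d <- if (target$direction == "higher_better") 1 else -1
  inc <- d * (df$value - target$target)
  out <- tibble::tibble(
    case_position = as.integer(df$case_position),
    value = df$value,
    increment = inc,
    cumulative = cumsum(inc)
  )
  if ("case_index" %in% names(df)) {
    out <- dplyr::mutate(out, case_index = as.integer(df$case_index),
                         .after = "case_position")
  }
  new_cusum_series(out, target$metric, target$target, target$direction,
                   target$source, "continuous")
}

#' Resolve a cohort-mean target against observed data
#'
#' Targets with `source = "cohort_mean"` (operation time, by default) are
#' benchmarked against the cohort's own arithmetic mean rather than an
#' external standard. This returns a copy of the spec with the target set to
#' the mean of the non-missing values; the input spec is untouched.
#'
#' @param series Numeric vector of observed values (or tibble with `value`).
#' @param spec A [target_spec()] row with `source = "cohort_mean"`.
#' @return The spec with a resolved numeric target.
#' @export
resolve_cohort_mean <- function(series, spec) {
  if (spec$source != "cohort_mean") {
    stop("resolve_cohort_mean() applies only to source = 'cohort_mean'.",
         call. = FALSE)
  }
  v <- if (is.data.frame(series)) series$value else as.numeric(series)
  v <- v[!is.na(v)]
  if (length(v) == 0L) {
    stop("Cannot resolve cohort-mean target from an empty series.",
         call. = FALSE)
  }
  out <- spec
  out$target <- mean(v)
  out
}

#' Bernoulli CUSUM for complication events
#'
#' Charts binary adverse events against a reference complication probability
#' `p0`. A case without a complication beats expectation and moves the chart
#' up by `p0`; a case with a complication moves it down by `1 - p0`. With
#' these increments the chart is drift-free exactly when complications occur
#' with probability `p0` (the expected increment is
#' `(1 - p0) * p0 - p0 * (1 - p0) = 0`), and it preserves the down-is-worse
#' orientation of the continuous charts. Closed form:
#' `cumulative[n] = p0 * n_false - (1 - p0) * n_true`.
#'
#' @param events Ordered logical vector; `TRUE` means the case had at least
#'   one attributable complication.
#' @param p0 Reference probability, strictly in (0, 1); default 0.20.
#' @return A `cusum_series` tibble (`case_position`, `value` as 0/1,
#'   `increment`, `cumulative`).
#' @export
#' @examples
#' binary_cusum(c(FALSE, TRUE, FALSE), p0 = 0.2)
binary_cusum <- function(events, p0 = 0.20) {
  events <- as.logical(events)
  if (length(events) == 0L) stop("Event series is empty.", call. = FALSE)
  if (anyNA(events)) stop("Event series contains missing values.", call. = FALSE)
  if (!is.numeric(p0) || length(p0) != 1L || is.na(p0) || p0 <= 0 || p0 >= 1) {
    stop("`p0` must be a single probability strictly in (0, 1).", call. = FALSE)
  }
  inc <- ifelse(events, -(1 - p0), p0)
  out <- tibble::tibble(
    case_position = seq_along(events),
    value = as.numeric(events),
    increment = inc,
    cumulative = cumsum(inc)
  )
  new_cusum_series(out, "complication", p0, "lower_better",
                   "cohort_probability", "binary")
}

#' Serialize a CUSUM series to tidy CSV
#'
#' Writes one row per case with columns `metric`, `case_position`, `value`,
#' `increment`, `cumulative`, `target`.
#'
#' @param cusum A `cusum_series`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cusum <- function(cusum, path) {
  df <- tibble::tibble(
    metric = attr(cusum, "metric"),
    case_position = cusum$case_position,
    value = cusum$value,
    increment = cusum$increment,
    cumulative = cusum$cumulative,
    target = attr(cusum, "target")
  )
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
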