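#' Linear trend fit of an outcome on case number
#'
#' Ordinary least-squares regression of a metric's values on the consecutive
#' case position, mirroring the regression line drawn through the outcome
#' scatter plots. Reports slope (outcome units per case), intercept and the
#' coefficient of determination `r_squared = 1 - SSE/SST`. A constant outcome
#' has no variance to explain; such fits get `r_squared = 0` and
#' `degenerate = TRUE` instead of `NaN`, keeping reports machine-readable.
#'
#' @param series Tibble from [metric_series()] (columns `case_position`,
#'   `value`), or a numeric vector (positions taken as `1:n`).
#' @param metric Optional metric id recorded in the result.
#' @return A one-row tibble: `metric`, `slope`, `intercept`, `r_squared`,
#'   `n`, `degenerate`.
#' @export
#' @examples
#' fit_trend(c(1, 3, 2)) # slope 0.5, r_squared 0.25
fit_trend <- function(series, metric = NA_character_) {
  if (is.data.frame(series)) {
    df <- series[!is.na(series$value), , drop = FALSE]
    x <- as.numeric(df$case_position)
    y <- as.numeric(df$value)
  } else {
    y <- as.numeric(series)
    x <- seq_along(y)
    keep <- !is.na(y)
    x <- x[keep]; y <- y[keep]
  }
  if (length(y) < 2L) {
    stop("fit_trend() needs at least 2 non-missing cases.", call. = FALSE)
  }
  if (any(diff(x) <= 0)) {
    stop("Case positions must be strictly increasing.", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  coefs <- stats::coef(fit)
  sst <- sum((y - mean(y))^2)
  degenerate <- sst == 0
  r2 <- if (degenerate) 0 else 1 - sum(stats::residuals(fit)^2) / sst
  tibble::tibble(
    metric = metric,
    slope = if (degenerate) 0 else unname(coefs["x"]),
    intercept = unname(coefs["(Intercept)"]),
    r_squared = r2,
    n = length(y),
    degenerate = degenerate
  )
}

#' Trend fits for every requested metric of a cohort
#'
#' Runs [fit_trend()] per metric on the per-metric renumbered series
#' ([metric_series()]), in the stable order of `metrics`. Metrics with fewer
#' than two observations are omitted with a warning.
#'
#' @param cohort Cohort tibble.
#' @param metrics Character vector of metric ids; defaults to the continuous
#'   metrics present in `cohort`.
#' @return A tibble with one row per fitted metric (columns as [fit_trend()]).
#' @export
trend_report <- function(cohort,
                         metrics = intersect(continuous_metrics(),
                                             names(cohort))) {
  unknown <- setdiff(metrics, continuous_metrics())
  if (length(unknown) > 0L) {
    stop("Unknown metric(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  rows <- list()
  for (m in metrics) {
    s <- metric_series(cohort, m)
    if (nrow(s) < 2L) {
      warning("Metric '", m, "' has fewer than 2 observations; omitted from ",
              "trend report.", call. = FALSE)
      next
    }
    rows[[m]] <- fit_trend(s, metric = m)
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(metric = character(), slope = numeric(),
                          intercept = numeric(), r_squared = numeric(),
                          n = integer(), degenerate = logical()))
  }
  dplyr::bind_rows(rows)
}
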