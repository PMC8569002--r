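#' Segment a CUSUM chart into learning, consolidation and mastering phases
#'
#' Formalizes the three-phase visual reading of a surgical CUSUM chart with
#' two explicit, deterministic rules:
#'
#' * **Learning end** — the position of the global minimum of the cumulative
#'   series (the chart's trough), taking the earliest position on ties so the
#'   claimed learning phase is as short as the data allow. If the running sum
#'   never drops below its starting level of 0 (the chart rises from case 1),
#'   there is no learning phase and `learning_end = 0`.
#' * **Mastering start** — the first position `m` after the learning end such
#'   that every window of `plateau_window` consecutive cases starting at or
#'   after `m` has mean absolute increment at most `plateau_tol`; i.e. the
#'   chart has flattened for good, not just paused. `NA` when no such
#'   position exists. `plateau_tol` defaults to 25% of the series' mean
#'   absolute increment.
#'
#' Cases up to `learning_end` are labelled `learning`, cases from
#' `mastering_start` on are `mastering`, and everything between is
#' `consolidation`. Segmentation is deterministic: identical input always
#' yields identical output.
#'
#' @param cusum A `cusum_series` (or any tibble with `increment` and
#'   `cumulative` columns).
#' @param plateau_window Window length in cases (>= 2); default 10.
#' @param plateau_tol Non-negative plateau tolerance in increment units, or
#'   `NULL` for the 25%-of-mean-|increment| default.
#' @return A list of class `phase_segmentation`: `metric`, `learning_end`,
#'   `mastering_start`, `labels`, `plateau_window`, `plateau_tol`.
#' @export
#' @examples
#' t <- target_spec("css", 50, "higher_better")
#' cs <- continuous_cusum(c(49, 48, 47, 51, 52, 53, 54), t)
#' segment_phases(cs, plateau_window = 2)$learning_end
segment_phases <- function(cusum, plateau_window = 10, plateau_tol = NULL) {
  inc <- cusum$increment
  cum <- cusum$cumulative
  n <- length(cum)
  if (n == 0L) stop("Cannot segment an empty series.", call. = FALSE)
  if (plateau_window < 2) stop("`plateau_window` must be >= 2.", call. = FALSE)
  if (is.null(plateau_tol)) plateau_tol <- 0.25 * mean(abs(inc))
  if (plateau_tol < 0) stop("`plateau_tol` must be >= 0.", call. = FALSE)

  # trough of the path including the implicit S0 = 0 before case 1
  path <- c(0, cum)
  learning_end <- which.min(path) - 1L # earliest position on ties

  mastering_start <- NA_integer_
  w <- as.integer(plateau_window)
  if (w > n) {
    warning("plateau_window (", w, ") exceeds series length (", n,
            "); mastering detection skipped.", call. = FALSE)
  } else {
    starts <- seq_len(n - w + 1L)
    win_mean <- vapply(starts, function(s) mean(abs(inc[s:(s + w - 1L)])),
                       numeric(1))
    ok <- rev(cumprod(rev(win_mean <= plateau_tol))) == 1 # all windows from s on flat
    cand <- starts[ok & starts > learning_end]
    if (length(cand) > 0L) mastering_start <- min(cand)
  }

  labels <- rep("consolidation", n)
  if (learning_end > 0L) labels[seq_len(learning_end)] <- "learning"
  if (!is.na(mastering_start)) labels[mastering_start:n] <- "mastering"

  structure(
    list(
      metric = attr(cusum, "metric") %||% NA_character_,
      learning_end = learning_end,
      mastering_start = mastering_start,
      labels = labels,
      plateau_window = w,
      plateau_tol = plateau_tol
    ),
    class = "phase_segmentation"
  )
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat(sprintf(
    "<phase_segmentation> metric: %s | learning ends at case %d | mastering %s\n",
    x$metric, x$learning_end,
    if (is.na(x$mastering_start)) "not reached"
    else paste("from case", x$mastering_start)
  ))
  invisible(x)
}

#' Tabulate phase cutoffs across metrics
#'
#' Collects the learning-end and mastering-start positions of several
#' segmentations into one table and reports the median learning end across
#' metrics — a single-number summary of how many cases the learning phase
#' took for this cohort.
#'
#' @param segmentations A list of `phase_segmentation` objects.
#' @return A list with `table` (tibble: `metric`, `learning_end`,
#'   `mastering_start`, `plateau_window`, `plateau_tol`) and
#'   `median_learning_end`.
#' @export
summarize_cutoffs <- function(segmentations) {
  if (inherits(segmentations, "phase_segmentation")) {
    segmentations <- list(segmentations)
  }
  if (length(segmentations) == 0L) {
    stop("summarize_cutoffs() needs at least one segmentation.", call. = FALSE)
  }
  tab <- dplyr::bind_rows(lapply(segmentations, function(s) {
    tibble::tibble(
      metric = s$metric,
      learning_end = s$learning_end,
      mastering_start = s$mastering_start,
      plateau_window = s$plateau_window,
      plateau_tol = s$plateau_tol
    )
  }))
  list(table = tab, median_learning_end = median(tab$learning_end))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
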