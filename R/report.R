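#' Run the full learning-curve analysis and write a report bundle
#'
#' End-to-end orchestration: take a cohort (from CSV files or freshly
#' simulated), then write to `out_dir` the descriptive summary, the linear
#' trend report, one tidy CUSUM CSV per continuous metric plus the binary
#' complication CUSUM, the phase-cutoff table, the complication rate table,
#' chart images, and a JSON run manifest recording every parameter needed to
#' re-run the analysis. CSV outputs are deterministic given the same inputs
#' and seed; images and the manifest (which carries a timestamp) are
#' secondary artifacts outside the determinism guarantee.
#'
#' @param out_dir Output directory (created if needed).
#' @param cohort_file,complications_file Input CSVs (cohort mode).
#' @param simulate_params A `learning_params` object (simulate mode).
#'   Exactly one of `cohort_file` and `simulate_params` must be given.
#' @param targets_file Optional YAML/JSON target config; defaults to the
#'   shipped ledger.
#' @param plateau_window,plateau_tol Segmentation parameters, see
#'   [segment_phases()].
#' @param render Draw chart images (default `TRUE`).
#' @param quiet Suppress per-stage log lines (default `TRUE`).
#' @return Invisibly, a list with the in-memory results (`cohort`,
#'   `summary`, `trends`, `cusums`, `segmentations`, `cutoffs`,
#'   `complication_rates`, `manifest`).
#' @export
run_analysis <- function(out_dir,
                         cohort_file = NULL,
                         complications_file = NULL,
                         simulate_params = NULL,
                         targets_file = NULL,
                         plateau_window = 10,
                         plateau_tol = NULL,
                         render = TRUE,
                         quiet = TRUE) {
  if (is.null(cohort_file) == is.null(simulate_params)) {
    stop("Give exactly one of `cohort_file` or `simulate_params`.",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_line <- function(...) if (!quiet) message("[cusumcurve] ", ...)

  if (!is.null(simulate_params)) {
    sim <- simulate_cohort(simulate_params)
    cohort <- sim$cases
    events <- sim$complications
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    write_complications(events, file.path(out_dir, "complications.csv"))
    log_line("simulated cohort: ", nrow(cohort), " cases, ",
             nrow(events), " complication events")
  } else {
    cohort <- load_cohort(cohort_file)
    events <- if (!is.null(complications_file)) {
      load_complications(complications_file)
    } else {
      tibble::tibble(case_index = integer(), description = character(),
                     severity = character(), attributable = logical())
    }
    log_line("loaded cohort: ", nrow(cohort), " cases, ",
             nrow(events), " complication events")
  }

  targets <- load_targets(targets_file)

  summary <- summarize_cohort(cohort)
  readr::write_csv(summary, file.path(out_dir, "cohort_summary.csv"),
                   na = "", progress = FALSE)

  metrics <- intersect(continuous_metrics(), names(cohort))
  metrics <- metrics[vapply(metrics,
                            function(m) nrow(metric_series(cohort, m)) >= 2,
                            logical(1))]
  trends <- trend_report(cohort, metrics)
  readr::write_csv(trends, file.path(out_dir, "trend_report.csv"),
                   progress = FALSE)
  log_line("trend fits: ", nrow(trends), " metrics")

  cusums <- list()
  segmentations <- list()
  fits <- split(trends, trends$metric)
  for (m in metrics) {
    s <- metric_series(cohort, m)
    spec <- get_target(targets, m)
    if (spec$source == "cohort_mean") spec <- resolve_cohort_mean(s, spec)
    cs <- continuous_cusum(s, spec)
    write_cusum(cs, file.path(out_dir, paste0("cusum_", m, ".csv")))
    cusums[[m]] <- cs
    segmentations[[m]] <- segment_phases(cs, plateau_window, plateau_tol)
  }
  log_line("continuous CUSUM charts: ", length(cusums))

  p0 <- get_target(targets, "complication")$target
  rates <- complication_rate(events, n_cohort = nrow(cohort))
  rates$p0_configured <- p0
  rates$differs_from_p0 <- rates$class == "any" &
    abs(rates$pct / 100 - p0) > .Machine$double.eps^0.5
  readr::write_csv(rates, file.path(out_dir, "complication_summary.csv"),
                   progress = FALSE)
  if (any(rates$differs_from_p0)) {
    log_line("note: tabulated complication rate (",
             rates$pct[rates$class == "any"],
             "%) differs from configured p0 = ", p0)
  }

  binary <- binary_cusum(events_to_binary_series(cohort, events), p0 = p0)
  write_cusum(binary, file.path(out_dir, "cusum_complication.csv"))
  segmentations[["complication"]] <- segment_phases(binary, plateau_window,
                                                    plateau_tol)

  cutoffs <- summarize_cutoffs(segmentations)
  readr::write_csv(cutoffs$table, file.path(out_dir, "phase_cutoffs.csv"),
                   na = "", progress = FALSE)
  log_line("phase cutoffs: median learning_end = ",
           cutoffs$median_learning_end)

  if (render) {
    tryCatch(
      render_charts(cusums, fits, segmentations, binary, out_dir),
      error = function(e) {
        warning("Chart rendering failed (CSV outputs unaffected): ",
                conditionMessage(e), call. = FALSE)
      }
    )
  }

  manifest <- list(
    package = "cusumcurve",
    version = as.character(utils::packageVersion("cusumcurve")),
    mode = if (is.null(simulate_params)) "cohort" else "simulate",
    seed = if (is.null(simulate_params)) NA else simulate_params$seed,
    simulate_params = if (is.null(simulate_params)) NULL else
      unclass(simulate_params),
    targets = targets,
    plateau_window = plateau_window,
    plateau_tol = plateau_tol,
    n_cases = nrow(cohort),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, na = "null",
                       digits = NA)

  invisible(list(
    cohort = cohort, events = events, summary = summary, trends = trends,
    cusums = cusums, binary_cusum = binary, segmentations = segmentations,
    cutoffs = cutoffs, complication_rates = rates, manifest = manifest
  ))
}

#' Render scatter and CUSUM charts
#'
#' One scatter plot with its least-squares trend line per continuous metric,
#' one CUSUM line chart per metric (phase boundaries drawn as dashed
#' verticals where present), and the binary complication CUSUM. Filenames are
#' deterministic (`scatter_<metric>.png`, `cusum_<metric>.png`).
#'
#' @param cusums Named list of continuous `cusum_series`.
#' @param fits Named list of one-row [fit_trend()] tibbles.
#' @param segmentations Named list of `phase_segmentation` objects.
#' @param binary The binary `cusum_series`, or `NULL`.
#' @param out_dir Output directory.
#' @return Invisibly, the vector of files written.
#' @export
render_charts <- function(cusums, fits, segmentations, binary = NULL,
                          out_dir = ".") {
  files <- character()
  save_plot <- function(p, file) {
    ggplot2::ggsave(file, p, width = 6, height = 4, dpi = 120)
    files <<- c(files, file)
  }
  cusum_plot <- function(cs, seg, title, ylab) {
    df <- tibble::as_tibble(cs)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$case_position,
                                          y = .data$cumulative)) +
      ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
      ggplot2::geom_line() +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::labs(title = title, x = "Case (chronological)", y = ylab) +
      ggplot2::theme_minimal()
    if (!is.null(seg) && seg$learning_end > 0) {
      p <- p + ggplot2::geom_vline(xintercept = seg$learning_end,
                                   linetype = "dashed", colour = "firebrick")
    }
    if (!is.null(seg) && !is.na(seg$mastering_start)) {
      p <- p + ggplot2::geom_vline(xintercept = seg$mastering_start,
                                   linetype = "dashed", colour = "darkgreen")
    }
    p
  }
  for (m in names(cusums)) {
    cs <- cusums[[m]]
    df <- tibble::as_tibble(cs)
    fit <- fits[[m]]
    ps <- ggplot2::ggplot(df, ggplot2::aes(x = .data$case_position,
                                           y = .data$value)) +
      ggplot2::geom_point() +
      ggplot2::labs(
        title = sprintf("%s vs case number (R² = %.3f)", m,
                        if (is.null(fit)) NA_real_ else fit$r_squared),
        x = "Case (chronological)", y = m
      ) +
      ggplot2::theme_minimal()
    if (!is.null(fit)) {
      ps <- ps + ggplot2::geom_abline(slope = fit$slope,
                                      intercept = fit$intercept,
                                      colour = "steelblue")
    }
    save_plot(ps, file.path(out_dir, paste0("scatter_", m, ".png")))
    save_plot(
      cusum_plot(cs, segmentations[[m]],
                 sprintf("CUSUM: %s (target %s)", m,
                         format(attr(cs, "target"), digits = 4)),
                 "Cumulative performance vs target"),
      file.path(out_dir, paste0("cusum_", m, ".png"))
    )
  }
  if (!is.null(binary)) {
    save_plot(
      cusum_plot(binary, segmentations[["complication"]],
                 sprintf("CUSUM: complications (p0 = %s)",
                         format(attr(binary, "target"))),
                 "Cumulative performance vs p0"),
      file.path(out_dir, "cusum_complication.png")
    )
  }
  invisible(files)
}

#' Simulate-and-analyze demonstration run
#'
#' Simulates a cohort from the shipped calibration
#' ([frsa_learning_params()]) and runs the full analysis on it. Two runs
#' with the same seed produce byte-identical CSV outputs.
#'
#' @param out_dir Output directory.
#' @param seed Simulation seed.
#' @param ... Passed on to [run_analysis()].
#' @return See [run_analysis()].
#' @export
demo_analysis <- function(out_dir, seed = 1L, ...) {
  run_analysis(out_dir, simulate_params = frsa_learning_params(seed = seed),
               ...)
}
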