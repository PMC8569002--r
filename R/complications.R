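#' Classify complication severity from structured annotations
#'
#' Applies the two-class severity rule to structured event annotations: an
#' event is **major** when it required considerable revision surgery, needed
#' long-term medication (e.g. long-term antibiotics), or compromised the
#' surgical outcome; it is **minor** when none of these hold (transient nerve
#' palsies, hardware discomfort resolved by removing a cerclage lock, and the
#' like). Events annotated on none of the criteria are returned as
#' `unclassified` with a warning — they are surfaced for manual review, never
#' silently counted as minor. The ruleset is a character vector of logical
#' annotation columns any one of which implies `major`, so the audit trail is
#' declarative rather than free-text matching.
#'
#' @param events Tibble of complication events carrying logical annotation
#'   columns named in `rules` (`NA` allowed).
#' @param rules Character vector of major-implying annotation columns.
#' @return `events` with the `severity` column filled in
#'   (`minor`/`major`/`unclassified`).
#' @export
classify_severity <- function(events,
                              rules = c("revision_surgery",
                                        "long_term_medication",
                                        "outcome_compromised")) {
  present <- intersect(rules, names(events))
  if (length(present) == 0L) {
    stop("None of the annotation columns (", paste(rules, collapse = ", "),
         ") are present.", call. = FALSE)
  }
  ann <- as.matrix(events[, present, drop = FALSE])
  any_major <- apply(ann, 1, function(r) isTRUE(any(r == TRUE, na.rm = TRUE)))
  all_na <- apply(ann, 1, function(r) all(is.na(r)))
  sev <- ifelse(all_na, "unclassified", ifelse(any_major, "major", "minor"))
  if (any(sev == "unclassified")) {
    warning(sum(sev == "unclassified"), " event(s) lack annotations on every ",
            "severity criterion; flagged 'unclassified' for manual review.",
            call. = FALSE)
  }
  events$severity <- sev
  events
}

#' Complication rates per severity class
#'
#' Counts patients — not events — per severity class among attributable
#' events, as percentages of the cohort size. A patient with two minor events
#' counts once toward the minor rate; a patient can contribute to both the
#' minor and the major count. `any` counts patients with at least one
#' attributable event of either class. Non-attributable events (e.g.
#' post-operative falls) are excluded throughout.
#'
#' @param events Complication-event tibble (see [load_complications()]).
#' @param n_cohort Cohort size (> 0); the rate denominator.
#' @return A tibble: `class` (`minor`, `major`, `any`), `n_patients`, `pct`.
#' @export
#' @examples
#' ev <- tibble::tibble(case_index = c(2L, 2L), description = "x",
#'                      severity = "minor", attributable = TRUE)
#' complication_rate(ev, n_cohort = 10) # minor: 1 patient, 10%
complication_rate <- function(events, n_cohort) {
  if (!is.numeric(n_cohort) || length(n_cohort) != 1L || n_cohort <= 0) {
    stop("`n_cohort` must be a single positive number.", call. = FALSE)
  }
  if (nrow(events) > 0L) {
    bad <- which(is.na(events$case_index) | events$case_index < 1 |
                   events$case_index > n_cohort)
    if (length(bad) > 0L) {
      stop("Event at data row ", bad[1], " references unknown case_index ",
           events$case_index[bad[1]], " (cohort size ", n_cohort, ").",
           call. = FALSE)
    }
  }
  att <- events[!is.na(events$attributable) & events$attributable, ,
                drop = FALSE]
  count <- function(sev) {
    length(unique(att$case_index[att$severity == sev]))
  }
  n_minor <- count("minor")
  n_major <- count("major")
  n_any <- length(unique(att$case_index))
  tibble::tibble(
    class = c("minor", "major", "any"),
    n_patients = c(n_minor, n_major, n_any),
    pct = 100 * c(n_minor, n_major, n_any) / n_cohort
  )
}

#' Per-case binary complication indicator
#'
#' Maps a cohort and its complication log to the ordered logical series the
#' Bernoulli CUSUM charts: one entry per case in chronological order, `TRUE`
#' iff the case has at least one attributable complication of any severity.
#' Cases whose only events are non-attributable (falls and similar) are
#' `FALSE`.
#'
#' @param cohort Cohort tibble (or a single integer, the cohort size).
#' @param events Complication-event tibble.
#' @return Logical vector with one element per case.
#' @export
events_to_binary_series <- function(cohort, events) {
  n <- if (is.data.frame(cohort)) nrow(cohort) else as.integer(cohort)
  idx <- if (is.data.frame(cohort)) sort(cohort$case_index) else seq_len(n)
  att <- events[!is.na(events$attributable) & events$attributable, ,
                drop = FALSE]
  idx %in% att$case_index
}

#' Packaged complication-log fixture
#'
#' Path to (or the contents of) the complication log shipped with the
#' package: the event table of a published 50-case fracture reverse shoulder
#' arthroplasty cohort — six patients with minor complications (three
#' transient nerve palsies, three cerclage-lock complaints), three with major
#' complications (impingement requiring acromioplasty, aseptic humeral stem
#' loosening requiring revision, and a shoulder dislocation requiring open
#' reduction), plus two fall-related events not attributable to the
#' prosthesis placement. Case indices are synthetic: the source table does
#' not disclose which case each event belongs to, so distinct arbitrary
#' indices were assigned (one patient per event).
#'
#' @param load If `TRUE`, return the loaded tibble instead of the path.
#' @return File path, or a tibble when `load = TRUE`.
#' @export
example_complications <- function(load = FALSE) {
  path <- system.file("extdata", "frsa_complications.csv",
                      package = "cusumcurve", mustWork = TRUE)
  if (load) load_complications(path) else path
}
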