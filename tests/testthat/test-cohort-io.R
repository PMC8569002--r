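test_that("cohort CSV round-trips records in chronological order", {
  f <- withr::local_tempfile(fileext = ".csv")
  co <- make_cohort(oss = c(30, 35, 40), css = c(50, NA, 60))
  write_cohort(co, f)
  back <- load_cohort(f)
  expect_equal(nrow(back), 3L)
  expect_equal(back$case_index, 1:3)
  expect_equal(back$oss, c(30, 35, 40))
  # missing cells survive as NA, never imputed
  expect_true(is.na(back$css[2]))
  # full round-trip fixed point
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(back, f2)
  expect_identical(load_cohort(f2), back)
})

test_that("loader rejects duplicate and non-contiguous case indices", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("case_index,oss", "1,30", "1,32", "2,35"), f)
  expect_error(load_cohort(f), "Duplicate case_index")
  writeLines(c("case_index,oss", "1,30", "3,35"), f)
  expect_error(load_cohort(f), "contiguous")
  writeLines(c("case_index,oss", "1,30", "2,not_a_number"), f)
  expect_error(load_cohort(f), "Malformed|out of valid")
})

test_that("schema mapping renames non-standard columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient,oxford", "1,30", "2,35"), f)
  co <- load_cohort(f, schema = c(case_index = "patient", oss = "oxford"))
  expect_equal(co$oss, c(30, 35))
  expect_error(load_cohort(f, schema = c(oss = "nope")), "absent column")
})

test_that("summaries use interpolated quartiles over non-missing values", {
  co <- make_cohort(oss = c(1, 2, 3, 4, 5))
  s <- summarize_cohort(co)
  row <- s[s$metric == "oss", ]
  expect_equal(row$median, 3)
  expect_equal(c(row$q1, row$q3), c(2, 4))
  expect_true(row$q1 <= row$median && row$median <= row$q3)

  # degenerate series: single value and constant series collapse the IQR
  one <- summarize_cohort(make_cohort(css = c(7, NA, NA)))
  expect_equal(unlist(one[one$metric == "css", c("median", "q1", "q3")]),
               c(median = 7, q1 = 7, q3 = 7))
  const <- summarize_cohort(make_cohort(flexion = rep(90, 6)))
  expect_equal(unlist(const[const$metric == "flexion",
                            c("median", "q1", "q3")]),
               c(median = 90, q1 = 90, q3 = 90))

  # all-missing metric flagged absent, not zero
  expect_true(is.na(s$median[s$metric == "css"]))
  expect_equal(s$n[s$metric == "css"], 0L)
})

test_that("summaries ignore chronology", {
  withr::local_seed(11)
  v <- rnorm(20, 100, 15)
  a <- summarize_cohort(make_cohort(flexion = v))
  perm <- sample(20)
  co_b <- tibble::tibble(case_index = (1:20)[perm], flexion = v[perm])
  expect_equal(summarize_cohort(co_b), a)
})

test_that("default target ledger matches the shipped benchmarks", {
  tg <- load_targets(NULL)
  expect_setequal(tg$metric, c(continuous_metrics(), "complication"))
  get <- function(m, col) tg[[col]][tg$metric == m]
  expect_equal(get("oss", "target"), 34.5)
  expect_equal(get("css", "target"), 50)
  expect_equal(get("flexion", "target"), 105)
  expect_equal(get("extension", "target"), 40)
  expect_equal(get("abduction", "target"), 90)
  expect_equal(get("external_rotation", "target"), 15)
  hb <- setdiff(tg$metric, c("operation_time", "complication"))
  expect_true(all(tg$direction[tg$metric %in% hb] == "higher_better"))
  expect_equal(get("operation_time", "source"), "cohort_mean")
  expect_true(is.na(get("operation_time", "target")))
  expect_equal(get("operation_time", "direction"), "lower_better")
  expect_equal(get("complication", "target"), 0.20)
  expect_equal(get("complication", "source"), "cohort_probability")
})

test_that("target config overrides merge onto defaults and are validated", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("- metric: css\n  target: 60", f)
  tg <- load_targets(f)
  expect_equal(tg$target[tg$metric == "css"], 60)
  deft <- default_targets()
  expect_equal(tg[tg$metric != "css", ], deft[deft$metric != "css", ])

  writeLines("- metric: css\n  target: 60\n  direction: sideways", f)
  expect_error(load_targets(f), "higher_better")
  writeLines("- metric: flexion\n  target: -10", f)
  expect_error(load_targets(f), "Negative target")
  writeLines("- metric: nonsense\n  target: 1", f)
  expect_error(load_targets(f), "Unknown metric")
  # empty config falls back to the full default ledger
  writeLines("", f)
  expect_equal(load_targets(f), default_targets())
})

test_that("out-of-range outcome values are rejected with the offending case", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("case_index,oss", "1,30", "2,49"), f)
  expect_error(load_cohort(f), "oss.*case_index 2")
  writeLines(c("case_index,operation_time", "1,120", "2,0"), f)
  expect_error(load_cohort(f), "operation_time")
})
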