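test_that("identical parameters and seed give a bit-identical cohort", {
  p <- frsa_learning_params(seed = 123)
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_identical(a$cases, b$cases)
  expect_identical(a$complications, b$complications)
  other <- simulate_cohort(frsa_learning_params(seed = 124))
  expect_false(identical(a$cases, other$cases))
  # simulation does not disturb the caller's RNG stream
  withr::local_seed(1)
  before <- rnorm(1)
  withr::local_seed(1)
  invisible(simulate_cohort(p))
  expect_identical(rnorm(1), before)
})

test_that("noiseless cohorts follow the exponential learning mean exactly", {
  p <- learning_params(
    metrics = list(flexion = list(start = 80, asymptote = 110, tau = 10,
                                  sd_start = 0, sd_end = 0)),
    complications = list(p_start = 0, p_inf = 0, tau_p = 10),
    n_cases = 20, seed = 1
  )
  sim <- simulate_cohort(p)
  k <- 1:20
  mu <- 110 + (80 - 110) * exp(-(k - 1) / 10)
  expect_equal(sim$cases$flexion, mu)
  expect_equal(sim$cases$flexion[11], 110 - 30 * exp(-1)) # ~98.96
  expect_equal(nrow(sim$complications), 0L)

  # enormous tau freezes the process at the start level
  stationary <- flat_params(level = 95, sd = 0, n_cases = 50)
  expect_equal(simulate_cohort(stationary)$cases$flexion, rep(95, 50))
})

test_that("crossing_case matches a scan of the closed-form mean", {
  p <- learning_params(
    metrics = list(flexion = list(start = 80, asymptote = 110, tau = 10,
                                  sd_start = 0, sd_end = 0)),
    complications = list(p_start = 0.2, p_inf = 0.2, tau_p = 10)
  )
  expect_equal(crossing_case(p, "flexion", 95), 8L)
  p1 <- learning_params(
    metrics = list(flexion = list(start = 80, asymptote = 110, tau = 1,
                                  sd_start = 0, sd_end = 0)),
    complications = list(p_start = 0.2, p_inf = 0.2, tau_p = 10)
  )
  expect_equal(crossing_case(p1, "flexion", 95), 2L)
  expect_error(crossing_case(p, "flexion", 80), "strictly between")
  expect_error(crossing_case(p, "flexion", 111), "strictly between")

  # scan oracle: first case whose mean is at or past the target
  withr::local_seed(3)
  for (i in 1:20) {
    start <- runif(1, 60, 90); asym <- runif(1, 100, 150)
    tau <- runif(1, 2, 30)
    target <- runif(1, start + 0.5, asym - 0.5)
    pp <- learning_params(
      metrics = list(flexion = list(start = start, asymptote = asym,
                                    tau = tau, sd_start = 0, sd_end = 0)),
      complications = list(p_start = 0.2, p_inf = 0.2, tau_p = 10)
    )
    k <- 1:10000
    mu <- asym + (start - asym) * exp(-(k - 1) / tau)
    expect_equal(crossing_case(pp, "flexion", target), min(which(mu >= target)))
  }
})

test_that("replicate means track mu_k and p_k within Monte Carlo error", {
  n_rep <- 600
  p_template <- frsa_learning_params()
  ks <- c(1L, 10L, 30L, 50L)
  draws <- matrix(NA_real_, n_rep, length(ks))
  events <- matrix(NA, n_rep, length(ks))
  for (r in seq_len(n_rep)) {
    sim <- simulate_cohort(frsa_learning_params(seed = 5000 + r))
    draws[r, ] <- sim$cases$css[ks]
    events[r, ] <- ks %in% sim$complications$case_index
  }
  pm <- p_template$metrics$css
  cp <- p_template$complications
  for (j in seq_along(ks)) {
    k <- ks[j]
    mu <- pm$asymptote + (pm$start - pm$asymptote) * exp(-(k - 1) / pm$tau)
    sd_k <- pm$sd_end + (pm$sd_start - pm$sd_end) * exp(-(k - 1) / pm$tau)
    expect_lt(abs(mean(draws[, j]) - mu), 3 * sd_k / sqrt(n_rep))
    p_k <- cp$p_inf + (cp$p_start - cp$p_inf) * exp(-(k - 1) / cp$tau_p)
    se_p <- sqrt(p_k * (1 - p_k) / n_rep)
    expect_lt(abs(mean(events[, j]) - p_k), 3 * se_p)
  }
})

test_that("range clipping touches under 1% of draws at the shipped calibration", {
  n_rep <- 40
  clipped <- 0L; total <- 0L
  reg <- metric_registry()
  for (r in seq_len(n_rep)) {
    p <- frsa_learning_params(seed = 900 + r)
    sim <- simulate_cohort(p)
    for (m in names(p$metrics)) {
      v <- sim$cases[[m]]
      lo <- reg$lower[reg$metric == m]; hi <- reg$upper[reg$metric == m]
      clipped <- clipped + sum(v <= lo | v >= hi)
      total <- total + length(v)
    }
  }
  expect_lt(clipped / total, 0.01)
})

test_that("parameter validation rejects impossible learning models", {
  good_m <- list(flexion = list(start = 80, asymptote = 110, tau = 10,
                                sd_start = 5, sd_end = 2))
  good_c <- list(p_start = 0.3, p_inf = 0.1, tau_p = 5)
  expect_s3_class(learning_params(good_m, good_c), "learning_params")
  bad_tau <- good_m; bad_tau$flexion$tau <- 0
  expect_error(learning_params(bad_tau, good_c), "tau")
  bad_sd <- good_m; bad_sd$flexion$sd_end <- 9
  expect_error(learning_params(bad_sd, good_c), "sd_start")
  expect_error(learning_params(good_m, list(p_start = 0.1, p_inf = 0.3,
                                            tau_p = 5)), "p_inf")
  expect_error(learning_params(list(bogus = good_m$flexion), good_c),
               "named list")
})

test_that("simulated cohorts round-trip through the cohort reader", {
  sim <- simulate_cohort(frsa_learning_params(seed = 7))
  f <- withr::local_tempfile(fileext = ".csv")
  g <- withr::local_tempfile(fileext = ".csv")
  write_cohort(sim$cases, f)
  write_complications(sim$complications, g)
  back <- load_cohort(f)
  expect_equal(back, sim$cases, tolerance = 1e-12)
  expect_equal(load_complications(g)$case_index, sim$complications$case_index)
  s <- summarize_cohort(back)
  expect_true(all(s$n == 50))
})
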