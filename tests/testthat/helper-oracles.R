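# Independent oracles kept deliberately naive: element-wise loops and
# textbook closed forms, never calls into the code paths they check.

# better/worse dichotomy applied one case at a time with absolute differences
oracle_cusum <- function(x, target, direction) {
  inc <- numeric(length(x))
  for (k in seq_along(x)) {
    better <- if (direction == "higher_better") x[k] > target else x[k] < target
    worse <- if (direction == "higher_better") x[k] < target else x[k] > target
    inc[k] <- if (better) abs(x[k] - target) else if (worse) -abs(x[k] - target) else 0
  }
  list(increments = inc, cumulative = cumsum(inc))
}

# normal-equations OLS of y on x
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  sst <- sum((y - mean(y))^2)
  sse <- sum((y - intercept - slope * x)^2)
  list(slope = slope, intercept = intercept, r_squared = 1 - sse / sst)
}

make_cohort <- function(...) {
  cols <- list(...)
  n <- length(cols[[1]])
  tibble::tibble(case_index = seq_len(n), !!!cols)
}

flat_params <- function(level, sd, n_cases = 50L, seed = 1L,
                        metric = "flexion") {
  m <- list(list(start = level, asymptote = level, tau = 1e6,
                 sd_start = sd, sd_end = sd))
  names(m) <- metric
  learning_params(metrics = m,
                  complications = list(p_start = 0.2, p_inf = 0.2, tau_p = 10),
                  n_cases = n_cases, seed = seed)
}
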