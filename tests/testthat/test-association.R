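test_that("2x2 odds ratios reproduce the published cluster-response tables", {
  # counts reconstructed from cluster sizes 10/25/37 and pCR rates 20%/48%/5.4%
  tc2_vs_others <- odds_ratio_2x2(contingency_2x2(12, 13, 4, 43))
  expect_equal(tc2_vs_others$or, 9.923, tolerance = 5e-4)
  expect_equal(tc2_vs_others$ci_lower, 2.730, tolerance = 5e-4)
  expect_equal(tc2_vs_others$ci_upper, 36.066, tolerance = 5e-4)
  expect_lt(tc2_vs_others$p, 0.001)
  expect_equal(odds_ratio_2x2(contingency_2x2(12, 13, 2, 35))$or, 16.154,
               tolerance = 5e-4)
  expect_equal(odds_ratio_2x2(contingency_2x2(2, 8, 2, 35))$or, 4.375,
               tolerance = 5e-4)
})

test_that("degenerate and zero-cell tables are handled as documented", {
  expect_equal(odds_ratio_2x2(contingency_2x2(1, 1, 1, 1))$or, 1.0)
  z <- odds_ratio_2x2(contingency_2x2(0, 5, 3, 7))
  expect_equal(z$method, "2x2+0.5")
  expect_equal(z$or, (0.5 * 7.5) / (5.5 * 3.5))
  expect_error(odds_ratio_2x2(contingency_2x2(0, 0, 3, 7)), "entirely zero")
  expect_error(contingency_2x2(-1, 1, 1, 1), "non-negative")
})

test_that("single-covariate logistic OR matches the closed-form 2x2 OR to 1e-6", {
  tables <- list(c(12, 13, 4, 43), c(8, 12, 5, 25), c(3, 17, 9, 21))
  for (tb in tables) {
    d <- data.frame(
      pcr = rep(c(1, 0, 1, 0), tb),
      x = rep(c(1, 1, 0, 0), tb))
    fit <- logistic_fit(d, outcome = "pcr", covariates = "x")
    closed <- odds_ratio_2x2(contingency_2x2(tb[1], tb[2], tb[3], tb[4]))
    expect_equal(fit$or, closed$or, tolerance = 1e-6)
    expect_false(fit$separation)
  }
})

test_that("degenerate outcomes and separation are flagged, not silently estimated", {
  d <- data.frame(pcr = rep(1, 10), x = rbinom(10, 1, 0.5))
  expect_error(logistic_fit(d, covariates = "x"), "degenerate")
  sep <- data.frame(pcr = c(rep(1, 10), rep(0, 10)), x = c(rep(1, 10), rep(0, 10)))
  fit <- logistic_fit(sep, covariates = "x")
  expect_true(fit$separation)
})

test_that("a null covariate yields OR near 1 with calibrated type-I error", {
  set.seed(99)
  n <- 200; reps <- 200
  ps <- numeric(reps); ors <- numeric(reps)
  for (i in seq_len(reps)) {
    d <- data.frame(pcr = rbinom(n, 1, 0.3), x = rbinom(n, 1, 0.5))
    f <- logistic_fit(d, covariates = "x")
    ps[i] <- f$p; ors[i] <- f$or
  }
  expect_equal(mean(log(ors)), 0, tolerance = 0.1)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)
})

test_that("chi-square proportions test matches the closed form and MedCalc-style layout", {
  g <- rep(c("A", "B"), each = 20)
  trait <- c(rep(1, 10), rep(0, 10), rep(1, 20))
  res <- proportions_test(g, trait)
  expect_equal(res$statistic, 40 * (10 * 0 - 10 * 20)^2 / (20 * 20 * 30 * 10),
               tolerance = 1e-10)
  expect_equal(res$df, 1)
  # identical proportions -> statistic 0
  res0 <- proportions_test(rep(c("A", "B"), each = 10),
                           rep(c(1, 0, 1, 0), c(5, 5, 5, 5)))
  expect_equal(res0$statistic, 0)
})

test_that("Ki67-like cluster proportions are declared different as published", {
  g <- rep(c("I", "II", "III"), c(10, 25, 37))
  k <- c(rep(1, 8), rep(0, 2), rep(1, 16), rep(0, 9), rep(1, 12), rep(0, 25))
  res <- proportions_test(g, k)
  expect_lt(res$p, 0.013)
})

test_that("the product-limit estimator matches the hand-computed table", {
  d <- data.frame(dfs_months = c(5, 10, 15, 20), event = c(1, 1, 1, 1))
  km <- km_logrank(d)
  s <- summary(km$fit, times = c(5, 10))
  expect_equal(s$surv, c(0.75, 0.50))
  # no censoring: KM equals the empirical survival function
  expect_equal(summary(km$fit, times = c(15, 20))$surv, c(0.25, 0))
})

test_that("a cohort without events yields the explicit no-events result", {
  d <- data.frame(dfs_months = c(10, 20, 30, 40), event = rep(0, 4))
  km <- km_logrank(d, group = rep(c("a", "b"), 2))
  expect_true(km$no_events)
  expect_true(is.na(km$logrank_p))
  expect_true(all(km$fit$surv == 1))
})

test_that("the log-rank test rejects a planted hazard ratio 5", {
  set.seed(1)
  n <- 200
  g <- rep(0:1, each = n / 2)
  t_true <- rexp(n, rate = ifelse(g == 1, 0.05, 0.01))
  cens <- runif(n, 20, 60)
  d <- data.frame(dfs_months = pmin(t_true, cens),
                  event = as.integer(t_true <= cens))
  km <- km_logrank(d, group = g)
  expect_lt(km$logrank_p, 0.001)
})

test_that("Cox recovery: HR 1 centers at 0 and a no-event stratum is flagged monotone", {
  set.seed(2)
  est <- replicate(30, {
    n <- 150
    g <- rbinom(n, 1, 0.5)
    t_true <- rexp(n, 0.03)
    cens <- runif(n, 10, 50)
    d <- data.frame(dfs_months = pmin(t_true, cens),
                    event = as.integer(t_true <= cens), x = g)
    cox_fit(d, "x")$hr
  })
  expect_equal(mean(log(est)), 0, tolerance = 0.12)
  # monotone likelihood: all events in one stratum
  d <- data.frame(dfs_months = c(rexp(30, 0.1), runif(30, 20, 40)),
                  event = rep(c(1, 0), each = 30), x = rep(c(1, 0), each = 30))
  fit <- cox_fit(d, "x")
  expect_true(fit$monotone)
  expect_error(cox_fit(data.frame(dfs_months = 1:5, event = rep(0, 5), x = rnorm(5)), "x"),
               "no events")
})

test_that("two-group exponential data yields an HR near the event-rate ratio", {
  set.seed(3)
  n <- 2000
  g <- rep(0:1, each = n / 2)
  t_true <- rexp(n, rate = ifelse(g == 1, 0.09, 0.03))
  d <- data.frame(dfs_months = t_true, event = rep(1L, n), x = g)
  fit <- cox_fit(d, "x")
  expect_equal(fit$hr, 3, tolerance = 0.15)
})
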