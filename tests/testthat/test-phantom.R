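test_that("noise-free phantom carries exactly the base SUV inside the tumor", {
  p <- make_tumor_phantom(phantom_spec(c(10, 10, 10), base_suv = 8,
                                       heterogeneity_sd = 0, seed = 1))
  expect_true(all(p$volume$values[p$mask$flags] == 8))
  expect_true(all(p$volume$values[!p$mask$flags] < 2.5))
})

test_that("planted ellipsoid volume matches the analytic value within 5%", {
  p <- make_tumor_phantom(phantom_spec(c(25, 25, 25), base_suv = 8,
                                       voxel_spacing = c(3.91, 3.91, 3.27),
                                       seed = 2))
  analytic <- 4 / 3 * pi * 25^3                      # mm3
  voxel <- sum(p$mask$flags) * prod(c(3.91, 3.91, 3.27))
  expect_lt(abs(voxel - analytic) / analytic, 0.05)
})

test_that("phantom generation is deterministic for a fixed seed and leaves the global RNG alone", {
  spec <- phantom_spec(c(12, 14, 10), base_suv = 6, heterogeneity_sd = 0.4, seed = 99)
  set.seed(123); before <- .Random.seed
  p1 <- make_tumor_phantom(spec)
  expect_identical(.Random.seed, before)
  p2 <- make_tumor_phantom(spec)
  expect_identical(p1$volume$values, p2$volume$values)
})

test_that("an ellipsoid larger than the grid is rejected with a sizing error", {
  expect_error(
    make_tumor_phantom(phantom_spec(c(40, 40, 40), base_suv = 6,
                                    grid_shape = c(10, 10, 10))),
    "exceeds")
})

test_that("phantom spec validates its invariants", {
  expect_error(phantom_spec(c(-1, 5, 5), base_suv = 5), "positive")
  expect_error(phantom_spec(c(5, 5, 5), base_suv = 0.2, background_suv = 0.5),
               "exceed")
  expect_error(phantom_spec(c(5, 5, 5), base_suv = 5, heterogeneity_sd = -0.1),
               ">= 0")
})

test_that("expected pCR count in the default cohort follows the Bernoulli model", {
  sim <- make_cohort(n_per_archetype = c(10, 25, 37), seed = 7)
  expect_equal(nrow(sim$cohort), 72)
  # E = 0.2*10 + 0.48*25 + 0.054*37 = 16; binomial 95% band ~ +/- 6.2
  expect_gte(sum(sim$cohort$pcr), 10)
  expect_lte(sum(sim$cohort$pcr), 22)
  expect_identical(table(sim$cohort$archetype)[c("I", "II", "III")],
                   table(factor(rep(c("I", "II", "III"), c(10, 25, 37))))[c("I", "II", "III")])
})

test_that("zero recurrence hazard yields a fully censored cohort", {
  om <- outcome_model(recurrence_hazard_per_cluster = c(0, 0, 0))
  sim <- make_cohort(n_per_archetype = c(3, 3, 3), outcomes = om, seed = 5)
  expect_true(all(sim$cohort$event == 0))
  expect_true(all(sim$cohort$dfs_months > 0))
})

test_that("unit pCR probabilities give a pCR in every patient", {
  om <- outcome_model(pcr_prob_per_cluster = c(1, 1, 1))
  sim <- make_cohort(n_per_archetype = c(3, 3, 3), outcomes = om, seed = 5)
  expect_true(all(sim$cohort$pcr == 1))
})

test_that("empty archetype list and zero counts are rejected", {
  expect_error(make_cohort(archetypes = list(), n_per_archetype = integer(0)),
               "empty")
  expect_error(make_cohort(n_per_archetype = c(0, 5, 5)), ">= 1")
})

test_that("expected tumor CV increases with heterogeneity_sd", {
  mean_cv <- function(het) {
    cvs <- vapply(1:20, function(s) {
      p <- make_tumor_phantom(phantom_spec(c(12, 12, 12), base_suv = 6,
                                           heterogeneity_sd = het, seed = s))
      x <- p$volume$values[p$mask$flags]
      stats::sd(x) / mean(x)
    }, numeric(1))
    mean(cvs)
  }
  cv_low <- mean_cv(0.1); cv_mid <- mean_cv(0.25); cv_high <- mean_cv(0.45)
  expect_lt(cv_low, cv_mid)
  expect_lt(cv_mid, cv_high)
})

test_that("archetype MTV distributions have non-overlapping IQRs; small archetype separates in SUVmax", {
  sim <- make_cohort(n_per_archetype = c(12, 12, 12), seed = 31)
  mtv <- vapply(sim$volumes, function(v)
    segment_fixed_threshold(v)$mtv_cm3, numeric(1))
  smax <- vapply(seq_along(sim$volumes), function(i)
    max(sim$volumes[[i]]$values[sim$masks[[i]]$flags]), numeric(1))
  arch <- sim$cohort$archetype
  iqr <- function(x) stats::quantile(x, c(0.25, 0.75))
  m1 <- iqr(mtv[arch == "I"]); m2 <- iqr(mtv[arch == "II"]); m3 <- iqr(mtv[arch == "III"])
  expect_gt(m1[1], m2[2])   # I sits wholly above II
  expect_gt(m2[1], m3[2])   # II sits wholly above III
  s12 <- iqr(smax[arch != "III"]); s3 <- iqr(smax[arch == "III"])
  expect_gt(s12[1], s3[2])  # hot archetypes separate from the mild one
})

test_that("cohort volumes and table round-trip through NIfTI and CSV", {
  sim <- make_cohort(n_per_archetype = c(1, 1, 1), seed = 3)
  td <- withr::local_tempdir()
  f <- file.path(td, "p1.nii.gz")
  write_volume(sim$volumes[[1]], f)
  back <- read_volume(f)
  expect_equal(back$values, sim$volumes[[1]]$values, tolerance = 0)
  csv <- file.path(td, "cohort.csv")
  write_cohort(sim$cohort, csv)
  back_tab <- read.csv(csv, stringsAsFactors = FALSE)
  expect_identical(back_tab$patient_id, sim$cohort$patient_id)
  expect_identical(names(back_tab),
                   c("patient_id", "archetype", "er", "pgr", "her2",
                     "ki67_high", "stage", "pcr", "dfs_months", "event"))
})
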