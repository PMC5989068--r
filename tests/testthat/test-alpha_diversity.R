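test_that("alpha_metrics computes richness, Shannon, and Pielou evenness", {
  u <- alpha_metrics(c(10, 10, 10, 10))
  expect_equal(u$richness, 4)
  expect_equal(u$shannon, log(4))
  expect_equal(u$evenness, 1)

  single <- alpha_metrics(c(7, 0, 0))
  expect_equal(single$richness, 1)
  expect_equal(single$shannon, 0)
  expect_equal(single$evenness, 0)

  mix <- alpha_metrics(c(2, 1, 1))
  expect_equal(mix$shannon,
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)), tolerance = 1e-12)
  expect_equal(mix$shannon, 1.0397, tolerance = 1e-4)
  expect_equal(mix$evenness, mix$shannon / log(3))
  expect_equal(mix$evenness, 0.9464, tolerance = 1e-4)

  expect_error(alpha_metrics(c(0, 0)), "all-zero")
  expect_error(alpha_metrics(c(-1, 2)), "non-negative")
})

test_that("H and J are invariant to scaling counts by an integer constant", {
  set.seed(1)
  for (i in 1:5) {
    x <- rpois(20, 5)
    x[1] <- x[1] + 1
    a <- alpha_metrics(x)
    b <- alpha_metrics(x * 7L)
    expect_equal(a$shannon, b$shannon)
    expect_equal(a$evenness, b$evenness)
    expect_equal(a$richness, b$richness)
  }
})

test_that("tukey_transform recovers normality on the ladder of powers", {
  set.seed(101)
  x <- rnorm(200, 10, 1)
  raw_w <- shapiro.test(x)$statistic
  res <- tukey_transform(x)
  expect_gte(res$lambda, 0.5)
  expect_lte(res$lambda, 2.0)
  expect_gte(res$shapiro_w, raw_w - 0.01)

  y <- exp(rnorm(200))
  res2 <- tukey_transform(y)
  expect_lte(abs(res2$lambda), 0.25)
  expect_gte(shapiro.test(res2$values)$p.value, 0.01)

  expect_error(tukey_transform(rep(3, 10)), "constant")
  # non-positive input is shifted, not rejected
  res3 <- tukey_transform(c(0, exp(rnorm(50))))
  expect_gt(res3$shift, 0)
})

test_that("zscore normalizes to mean 0 and sample sd 1", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(2)
  z <- zscore(runif(30))
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sd(z) - 1), 1e-9)
  expect_error(zscore(c(5, 5)), "constant")
})

test_that("severity_lmm detects an injected monotone trend across studies", {
  make_df <- function(seed, effect) {
    set.seed(seed)
    rows <- do.call(rbind, lapply(1:8, function(st) {
      sev <- rep(0:2, each = 10)
      data.frame(value = effect * sev + rnorm(1) + rnorm(30),
                 diagnosis = c("control", "adenoma", "carcinoma")[sev + 1],
                 study_id = paste0("s", st), region = "V4",
                 subject_id = paste0("s", st, "_", 1:30))
    }))
    rows
  }
  # power at effect -0.5 SD per severity step (20 seeds, scaled from 100)
  hits <- vapply(1:20, function(seed) {
    r <- severity_lmm(make_df(seed, -0.5))
    r$coefficient < 0 && r$p < 0.05
  }, TRUE)
  expect_gte(sum(hits), 17)
  # type-I behavior under the null
  null_hits <- vapply(1:20, function(seed) {
    severity_lmm(make_df(1000 + seed, 0))$p < 0.05
  }, TRUE)
  expect_lte(sum(null_hits), 4)
  # coefficient invariant to study listing order
  df <- make_df(7, -0.5)
  shuffled <- df[order(df$study_id, decreasing = TRUE), ]
  expect_equal(severity_lmm(df)$coefficient,
               severity_lmm(shuffled)$coefficient, tolerance = 1e-6)
  expect_error(severity_lmm(data.frame(value = 1:5, diagnosis = "control",
                                       study_id = "one", region = "V4",
                                       subject_id = letters[1:5])),
               "per study")
})

test_that("severity_test runs end to end on a synthetic collection", {
  g <- generate_collection(small_config(seed = 8, n_adenoma = 15))
  res <- severity_test(g$collection, "evenness", "feces")
  expect_true(res$p >= 0 && res$p <= 1)
  expect_type(res$coefficient, "double")
  expect_match(res$model, "study_id")
})

test_that("median_split_or reproduces hand-computed diversity ORs", {
  # cases (1, 2), controls (3, 4): median 2.5; below-median is exposure
  r <- median_split_or(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE), "low")
  expect_equal(c(r$a, r$b, r$c, r$d), c(2, 0, 0, 2))
  expect_true(r$corrected)
  expect_equal(r$or, 25)  # Haldane: (2.5 * 2.5) / (0.5 * 0.5)

  # flipping the direction flag inverts the OR
  hi <- median_split_or(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE), "high")
  expect_equal(hi$or, 1 / r$or)

  # all values equal: degenerate, flagged excluded
  same <- median_split_or(rep(2, 6), rep(c(TRUE, FALSE), 3))
  expect_true(same$excluded)
})

test_that("diversity_or contrasts exactly the two compared groups", {
  s <- toy_study("d", n_control = 6, n_case = 6)
  r <- diversity_or(s, "shannon", "carcinoma")
  expect_s3_class(r, "or_result")
  expect_equal(r$a + r$c, 6)
  expect_equal(r$b + r$d, 6)
  expect_error(diversity_or(s, "shannon", "adenoma"), "empty group")
})

test_that("pooled diversity ORs on null collections cover 1.0", {
  # 20-seed scaled version of the 200-seed coverage statement
  covered <- vapply(1:20, function(seed) {
    g <- generate_collection(null_config(seed = 400 + seed))
    p <- diversity_or_pooled(g$collection, "shannon", "carcinoma")$pooled
    p$ci_lo <= 1 && p$ci_hi >= 1
  }, TRUE)
  expect_gte(sum(covered), 16)
})
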