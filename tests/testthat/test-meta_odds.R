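test_that("dichotomize uses strict above-median exposure with ties unexposed", {
  expect_equal(dichotomize(c(0, 0, 0.1, 0.2)), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(dichotomize(rep(0, 5)), rep(FALSE, 5))
  expect_equal(dichotomize(c(0.3, 0.3, 0.3)), rep(FALSE, 3))
  expect_error(dichotomize(0.5), ">= 2")
})

test_that("odds_ratio reproduces hand-computed Woolf arithmetic", {
  r <- odds_ratio(10, 10, 10, 10)
  expect_equal(r$or, 1)
  expect_equal(r$log_or, 0)
  expect_equal(r$se, sqrt(0.4))
  expect_equal(r$ci_lo, exp(-qnorm(0.975) * sqrt(0.4)))
  expect_equal(r$ci_lo, 0.29, tolerance = 0.01)
  expect_equal(r$ci_hi, 3.45, tolerance = 0.01)
  expect_false(r$corrected)

  r2 <- odds_ratio(20, 5, 10, 15)
  expect_equal(r2$or, 6)
  expect_equal(r2$se, sqrt(1 / 20 + 1 / 5 + 1 / 10 + 1 / 15))
  expect_equal(r2$se, 0.6455, tolerance = 1e-4)
  expect_equal(r2$ci_lo, 1.69, tolerance = 0.01)
  expect_equal(r2$ci_hi, 21.27, tolerance = 0.01)

  # Haldane-Anscombe correction on a zero cell
  r3 <- odds_ratio(5, 0, 3, 7)
  expect_true(r3$corrected)
  expect_equal(r3$or, (5.5 * 7.5) / (0.5 * 3.5))
  expect_equal(r3$or, 23.57, tolerance = 0.01)

  # CI always brackets the point estimate
  expect_true(r2$ci_lo < r2$or && r2$or < r2$ci_hi)
})

test_that("odds_ratio flags degenerate margins and rejects bad cells", {
  deg <- odds_ratio(0, 0, 10, 10)
  expect_true(deg$excluded)
  expect_true(is.na(deg$or))
  expect_error(odds_ratio(-1, 2, 3, 4), "non-negative")
  expect_error(odds_ratio(0, 5, 0, 5), "at least one case")
})

test_that("the chi-square p matches stats::chisq.test without correction", {
  set.seed(4)
  for (i in 1:10) {
    cells <- rpois(4, 15) + 1
    r <- odds_ratio(cells[1], cells[2], cells[3], cells[4])
    ref <- suppressWarnings(stats::chisq.test(
      matrix(cells, 2, byrow = TRUE), correct = FALSE))
    expect_equal(r$p_chisq, ref$p.value, tolerance = 1e-12)
  }
})

test_that("pool_dl reproduces the DerSimonian-Laird worked example", {
  # homogeneous replicates: tau2 = 0, pooled = common value
  hom <- pool_dl(rep(0.5, 3), rep(0.2, 3))
  expect_equal(hom$pooled_log_or, 0.5)
  expect_equal(hom$tau2, 0)
  expect_equal(hom$q, 0)

  # k = 2 hand-computed case: y = (0, 1), se = (0.5, 0.5)
  r <- pool_dl(c(0, 1), c(0.5, 0.5))
  expect_equal(r$q, 2)
  expect_equal(r$tau2, 0.25)
  expect_equal(r$pooled_log_or, 0.5)
  expect_equal(r$pooled_se, 0.5)
  expect_equal(r$p, 2 * pnorm(-1))

  expect_error(pool_dl(0.5, 0.2), ">= 2")
})

test_that("pool_dl output is a convex combination of study estimates", {
  set.seed(8)
  for (i in 1:10) {
    k <- sample(2:8, 1)
    y <- rnorm(k)
    se <- runif(k, 0.1, 1)
    r <- pool_dl(y, se)
    expect_gte(r$pooled_log_or, min(y) - 1e-12)
    expect_lte(r$pooled_log_or, max(y) + 1e-12)
    expect_gte(r$tau2, 0)
    # equal standard errors and tau2 = 0 reduce to the arithmetic mean
  }
  y <- c(0.2, 0.21, 0.19)
  eq <- pool_dl(y, rep(0.5, 3))
  expect_equal(eq$tau2, 0)
  expect_equal(eq$pooled_log_or, mean(y))
})

test_that("bh_adjust implements the step-up rule exactly", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(bh_adjust(c(0.001, 0.5)), c(0.002, 0.5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_equal(bh_adjust(numeric(0)), numeric(0))

  set.seed(3)
  for (i in 1:25) {
    p <- runif(sample(1:20, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_equal(adj, stats::p.adjust(p, "BH"))
    expect_true(all(adj >= p - 1e-15))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
})

test_that("study_feature_or dichotomizes relative abundance per study", {
  counts <- rbind(c(10, 90), c(20, 80), c(30, 70), c(40, 60),
                  c(50, 50), c(60, 40), c(70, 30), c(80, 20))
  s <- toy_study("m", n_control = 4, n_case = 4, counts = counts)
  r <- study_feature_or(s, "tax1", "carcinoma")
  # cases (rows 5-8) hold the 4 highest tax1 proportions
  expect_equal(c(r$a, r$b, r$c, r$d), c(4, 0, 0, 4))
  expect_error(study_feature_or(s, "nope", "carcinoma"), "not in study")
})

test_that("transposing case and control negates every pooled log-OR", {
  g <- generate_collection(small_config(seed = 14))
  res <- significant_features(g$collection, "carcinoma")
  flipped_studies <- lapply(g$collection$studies, function(s) {
    m <- s$meta
    m$diagnosis <- c(control = "carcinoma",
                     carcinoma = "control")[m$diagnosis]
    study_table(s$study_id, s$counts, s$feature_level, m)
  })
  res_f <- significant_features(as_meta_collection(flipped_studies),
                                "carcinoma")
  shared <- intersect(res$feature, res_f$feature)
  expect_gt(length(shared), 0)
  expect_equal(res_f$log_or[match(shared, res_f$feature)],
               -res$log_or[match(shared, res$feature)], tolerance = 1e-12)
})

test_that("significant_features pools eligible features and applies BH", {
  g <- generate_collection(small_config(seed = 15))
  res <- significant_features(g$collection, "carcinoma", alpha = 0.05)
  expect_true(all(res$p_bh >= res$p - 1e-15))
  expect_true(all(res$k >= 2))
  expect_true(all(res$tau2 >= 0))
  long <- attr(res, "per_study")
  expect_true(all(c("feature", "study", "a", "b", "c", "d", "p_chisq")
                  %in% names(long)))
  # alpha = 0 never selects anything
  res0 <- significant_features(g$collection, "carcinoma", alpha = 0)
  expect_equal(sum(res0$significant), 0)
})

test_that("features non-degenerate in fewer than 2 studies are ineligible", {
  s1 <- toy_study("a")
  s2 <- toy_study("b")
  # tax5 absent everywhere in study b and constant-zero in study a cases
  s1$counts[, 5] <- 0
  s1$counts[1, 5] <- 0
  s2$counts[, 5] <- 0
  s1 <- study_table("a", s1$counts, "taxon", s1$meta)
  s2 <- study_table("b", s2$counts, "taxon", s2$meta)
  res <- significant_features(harmonize(list(s1, s2)), "carcinoma")
  expect_true("tax5" %in% attr(res, "ineligible"))
  expect_false("tax5" %in% res$feature)
})

test_that("a null collection yields no significant features after BH", {
  n_sig <- vapply(1:5, function(seed) {
    g <- generate_collection(null_config(seed = 800 + seed))
    sum(significant_features(g$collection, "carcinoma")$significant)
  }, 0)
  expect_gte(sum(n_sig == 0), 4)
})
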