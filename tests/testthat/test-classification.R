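test_that("auc is the midrank Mann-Whitney statistic", {
  expect_equal(auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(auc(rep(1, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_equal(auc(c(0.9, 0.4, 0.5, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_error(auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("auc equals the pair-enumeration oracle and is rank-invariant", {
  set.seed(6)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    scores <- sample(seq(0, 1, 0.25), n, replace = TRUE)  # with ties
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    expect_equal(auc(scores, labels), oracle_auc(scores, labels))
    # strictly monotone transforms leave the AUC unchanged
    expect_equal(auc(exp(3 * scores), labels), auc(scores, labels))
    expect_equal(auc(rank(scores, ties.method = "average"), labels),
                 auc(scores, labels))
  }
})

test_that("single_taxon_auc scores relative abundance in raw orientation", {
  counts <- rbind(c(10, 90), c(20, 80), c(30, 70), c(40, 60),
                  c(50, 50), c(60, 40), c(70, 30), c(80, 20))
  s <- toy_study("a", 4, 4, counts = counts)
  expect_equal(single_taxon_auc(s, "tax1", "carcinoma"), 1)
  expect_equal(single_taxon_auc(s, "tax2", "carcinoma"), 0)

  # absent feature: constant zero abundance scores exactly 0.5
  z <- counts
  z[, 2] <- 0
  z[, 1] <- 100
  s0 <- toy_study("z", 4, 4, counts = z)
  expect_equal(single_taxon_auc(s0, "tax2", "carcinoma"), 0.5)
  expect_error(single_taxon_auc(s, "ghost", "carcinoma"), "not in study")
})

test_that("train_rf honors the mtry convention and is seed-deterministic", {
  set.seed(9)
  x <- matrix(rnorm(40 * 8), 40, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- rep(c(TRUE, FALSE), 20)
  fit <- train_rf(x, y, seed = 3, ntree = 31)
  expect_equal(fit$mtry, 2)  # floor(sqrt(8))
  expect_equal(train_rf(x[, 1, drop = FALSE], y, seed = 1, ntree = 5)$mtry, 1)

  fit2 <- train_rf(x, y, seed = 3, ntree = 31)
  expect_identical(fit$oob_prob, fit2$oob_prob)
  expect_identical(predict(fit, x), predict(fit2, x))
  expect_error(train_rf(x, rep(TRUE, 40)), "single class")
})

test_that("the forest separates signal and ranks informative features", {
  set.seed(10)
  n <- 80
  y <- rep(c(TRUE, FALSE), each = n / 2)
  x <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("f", 1:10)))
  x[, 1] <- x[, 1] + 2 * y
  x[, 2] <- x[, 2] - 1.5 * y
  fit <- train_rf(x, y, seed = 1, ntree = 200)
  expect_gt(auc(predict(fit, x), y), 0.95)
  oob_ok <- !is.na(fit$oob_prob)
  expect_gt(auc(fit$oob_prob[oob_ok], y[oob_ok]), 0.85)
  # the two informative features carry the largest importances
  expect_setequal(names(sort(fit$importance, decreasing = TRUE))[1:2],
                  c("f1", "f2"))
})

test_that("predict.crc_rf aligns features by name and zero-fills", {
  set.seed(11)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rep(c(TRUE, FALSE), 10)
  fit <- train_rf(x, y, seed = 1, ntree = 21)
  wide <- cbind(x[, c("c", "a", "b")],
                matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("x", "y"))))
  expect_equal(predict(fit, wide), predict(fit, x))
})

test_that("make_folds stratifies and partitions", {
  y <- rep(c(TRUE, FALSE), c(20, 30))
  f <- make_folds(y, 5, seed = 2)
  expect_equal(sort(unique(f)), 1:5)
  for (k in 1:5) expect_equal(sum(f == k & y), 4)
  expect_identical(f, make_folds(y, 5, seed = 2))
  expect_error(make_folds(y, 1), "k must")
})

test_that("cv_auc pools out-of-fold scores and applies the small-study rule", {
  cfg <- small_config(seed = 17, n_studies = 1, n_control = 30,
                      n_carcinoma = 30,
                      enriched = data.frame(index = c(10, 20), lfc = 2,
                                            patchiness = 0),
                      protective = NULL)
  s <- generate_study(cfg, 1)
  cv <- cv_auc(s, "all_taxa", "carcinoma", k = 5, seed = 1, ntree = 100)
  expect_true(cv$auc > 0.5 && cv$auc <= 1)
  expect_length(cv$per_repeat, 1)
  expect_length(cv$importances, 60)
  # repeats average
  cv3 <- cv_auc(s, "otu", "carcinoma", k = 5, repeats = 3, seed = 1,
                ntree = 50)
  expect_length(cv3$per_repeat, 3)
  expect_equal(cv3$auc, mean(cv3$per_repeat))
  # k larger than the smallest class falls back to 2 with a warning
  tiny <- generate_study(small_config(seed = 18, n_studies = 1,
                                      n_control = 5, n_carcinoma = 5), 1)
  expect_warning(cvt <- cv_auc(tiny, "all_taxa", "carcinoma", k = 10,
                               seed = 1, ntree = 50), "falling back to k = 2")
  expect_equal(cvt$k, 2)
  expect_error(cv_auc(toy_study("t", 1, 1), "all_taxa", "carcinoma"),
               ">= 2 samples")
})

test_that("mda_zscores ranks features by mean Z across studies", {
  mk <- function(id, imp) {
    structure(list(study_id = id, regime = "sig_or_taxa",
                   comparison = "carcinoma", auc = 0.8, per_repeat = 0.8,
                   k = 10, importances = imp), class = "cv_result")
  }
  one <- mda_zscores(list(mk("a", c(f1 = 3, f2 = 2, f3 = 1))))
  expect_equal(one$feature, c("f1", "f2", "f3"))
  expect_equal(one$rank, 1:3)

  multi <- mda_zscores(list(
    mk("a", c(f1 = 5, f2 = 1, f3 = 2)),
    mk("b", c(f1 = 9, f2 = 3, f3 = 1)),
    mk("c", c(f1 = 2, f2 = 1, f3 = 0))))
  expect_equal(multi$feature[1], "f1")  # top MDA everywhere: rank 1
  expect_equal(multi$n_studies, rep(3L, 3))

  expect_warning(
    part <- mda_zscores(list(mk("a", c(f1 = 2, f2 = 1)),
                             mk("b", c(f1 = 1, f2 = 1)))),
    "constant MDA")
  expect_equal(part$n_studies, rep(1L, 2))
})

test_that("compare_models runs the one-tailed paired t convention", {
  same <- compare_models(rep(0.7, 5), rep(0.7, 5))
  expect_equal(same$t, 0)
  expect_equal(same$p, 0.5)

  shifted <- compare_models(rep(0.7, 5) + 0.1, rep(0.7, 5))
  expect_true(shifted$degenerate)
  expect_equal(shifted$p, 0)
  expect_equal(shifted$mean_diff, 0.1)

  set.seed(12)
  a <- runif(7, 0.6, 0.9)
  b <- a - rnorm(7, 0.05, 0.02)
  r <- compare_models(a, b)
  expect_equal(r$t, stats::t.test(a, b, paired = TRUE,
                                  alternative = "greater")$statistic[[1]])
  expect_equal(r$p, stats::t.test(a, b, paired = TRUE,
                                  alternative = "greater")$p.value)
  expect_equal(r$mean_pct_diff, mean((a - b) / b) * 100)
  expect_error(compare_models(1:2 / 2, 1:2 / 2), ">= 3")
})

test_that("compare_models rejection rate matches analytic t-test power", {
  k <- 7
  mu <- 0.08
  sdd <- 0.06
  nsim <- 300
  set.seed(20)
  rej <- mean(vapply(seq_len(nsim), function(i) {
    d <- rnorm(k, mu, sdd)
    b <- runif(k, 0.5, 0.8)
    compare_models(b + d, b)$p < 0.05
  }, TRUE))
  power <- stats::power.t.test(n = k, delta = mu, sd = sdd,
                               sig.level = 0.05, type = "one.sample",
                               alternative = "one.sided")$power
  expect_lt(abs(rej - power), 2.58 * sqrt(power * (1 - power) / nsim) + 0.01)
})

test_that("transfer_evaluate produces a complete train-by-test grid", {
  g <- generate_collection(small_config(seed = 23, n_studies = 3,
                                        n_control = 15, n_carcinoma = 15))
  tm <- transfer_evaluate(g$collection, "all_taxa", "carcinoma", seed = 1,
                          ntree = 50, diagonal = FALSE)
  expect_equal(dim(tm$auc), c(3, 3))
  expect_true(all(is.na(diag(tm$auc))))
  off <- tm$auc[row(tm$auc) != col(tm$auc)]
  expect_equal(sum(!is.na(off)), 6)
  expect_true(all(off >= 0 & off <= 1, na.rm = TRUE))
  expect_length(tm$median_test, 3)

  with_diag <- transfer_evaluate(g$collection, "sig_or_taxa", "carcinoma",
                                 seed = 1, k = 5, ntree = 50)
  expect_true(all(!is.na(diag(with_diag$auc))))
})

test_that("transfer to a study with no disease effect stays near chance", {
  cfg <- small_config(seed = 29, n_studies = 2, n_control = 25,
                      n_carcinoma = 25,
                      enriched = data.frame(index = 20, lfc = 2,
                                            patchiness = 0),
                      protective = NULL)
  g1 <- generate_study(cfg, 1)
  null_cfg <- null_config(seed = 30, n_studies = 1, n_control = 25,
                          n_carcinoma = 25)
  g2 <- generate_study(null_cfg, 1)
  g2$study_id <- "nullstudy"
  g2$meta$study_id <- "nullstudy"
  coll <- as_meta_collection(list(g1, g2))
  tm <- transfer_evaluate(coll, "all_taxa", "carcinoma", seed = 1,
                          ntree = 100, diagonal = FALSE)
  expect_lt(abs(tm$auc["st1", "nullstudy"] - 0.5), 0.2)
})
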