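test_that("generation is deterministic under (seed, study_index)", {
  cfg <- small_config(seed = 11)
  a <- generate_study(cfg, 2)
  b <- generate_study(cfg, 2)
  expect_identical(a$counts, b$counts)
  expect_identical(a$meta, b$meta)
  cfg2 <- small_config(seed = 12)
  expect_false(identical(generate_study(cfg2, 2)$counts, a$counts))
})

test_that("generated studies respect the configured design", {
  cfg <- small_config(seed = 3, n_adenoma = 10)
  s <- generate_study(cfg, 1)
  tab <- table(factor(s$meta$diagnosis, c("control", "adenoma", "carcinoma")))
  expect_equal(as.vector(tab), c(25, 10, 25))
  expect_true(all(rowSums(s$counts) > 0))
  expect_equal(ncol(s$counts), 60)
  expect_error(generate_study(cfg, 99), "out of range")
})

test_that("default configurations reproduce the published cohort sizes", {
  fec <- generate_collection(default_fecal_config(seed = 1))
  expect_equal(length(fec$collection$studies), 8)
  expect_equal(sum(vapply(fec$collection$studies,
                          function(s) nrow(s$counts), 0)), 1737)
  tis <- generate_collection(default_tissue_config(seed = 1))
  expect_equal(length(tis$collection$studies), 7)
  expect_equal(sum(vapply(tis$collection$studies,
                          function(s) nrow(s$counts), 0)), 492)
  # fecal studies without adenomas, as published
  n_ad <- vapply(fec$collection$studies,
                 function(s) sum(s$meta$diagnosis == "adenoma"), 0)
  expect_equal(unname(n_ad == 0),
               c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE))
})

test_that("matched tissue designs pair tumor and normal by subject", {
  tis <- generate_collection(default_tissue_config(seed = 2))$collection
  for (id in c("chen", "geng", "lu")) {
    s <- tis$studies[[id]]
    expect_true(any(s$meta$matched))
    pairs <- table(s$meta$subject_id[s$meta$matched])
    expect_true(all(pairs == 2))
  }
  expect_false(any(tis$studies$burns$meta$matched))
})

test_that("ground truth matches the configuration", {
  gen <- generate_collection(small_config(seed = 5))
  expect_equal(nrow(gen$truth), 60)
  expect_equal(sum(gen$truth$label == "enriched"), 2)
  expect_equal(sum(gen$truth$label == "protective"), 1)
  expect_equal(gen$truth$lfc[gen$truth$label == "null"],
               rep(0, 57))
  u <- attr(gen$truth, "study_effects")
  expect_equal(dim(u), c(60, 4))
  # signal taxa are exempt from study effects (shared across cohorts)
  expect_equal(unname(u[c(20, 30, 3), ]), matrix(0, 3, 4))

  one <- generate_collection(small_config(seed = 5, n_studies = 1))
  expect_equal(length(one$collection$studies), 1)
  expect_equal(nrow(one$truth), 60)
})

test_that("a null configuration produces only sampling-noise differences", {
  cfg <- null_config(seed = 21, n_studies = 1, n_control = 40,
                     n_carcinoma = 40, n_taxa = 100, study_effect_sd = 0)
  s <- generate_study(cfg, 1)
  rel <- to_relative_abundance(s)
  case <- s$meta$diagnosis == "carcinoma"
  pvals <- apply(rel, 2, function(v) {
    if (sd(v) == 0) return(1)
    stats::t.test(log(v[case] + 1e-6), log(v[!case] + 1e-6))$p.value
  })
  # 99% binomial bound on the false-positive fraction at alpha = 0.05
  bound <- 0.05 + 2.58 * sqrt(0.05 * 0.95 / length(pvals))
  expect_lt(mean(pvals < 0.05), bound)
})

test_that("an enriched taxon raises case abundance in nearly all seeds", {
  hits <- vapply(1:25, function(seed) {
    cfg <- small_config(
      seed = 300 + seed, n_studies = 1, n_control = 80, n_carcinoma = 80,
      enriched = data.frame(index = 20, lfc = 2, patchiness = 0),
      protective = NULL)
    s <- generate_study(cfg, 1)
    rel <- to_relative_abundance(s)
    case <- s$meta$diagnosis == "carcinoma"
    mean(rel[case, 20]) > mean(rel[!case, 20])
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("dichotomized ORs respond monotonically to the stated effect", {
  # 8 seeds per level (scaled down from the 50-seed statement for runtime)
  mean_or <- vapply(c(0.5, 1, 1.5), function(lfc) {
    mean(vapply(1:8, function(seed) {
      cfg <- small_config(
        seed = 700 + seed, n_studies = 1, n_control = 60, n_carcinoma = 60,
        enriched = data.frame(index = 20, lfc = lfc, patchiness = 0.2),
        protective = NULL)
      s <- generate_study(cfg, 1)
      r <- study_feature_or(s, "taxon_020", "carcinoma")
      r$log_or
    }, 0))
  }, 0)
  expect_true(all(diff(mean_or) > 0))
})

test_that("study effects dominate pooled community structure", {
  cfg <- small_config(seed = 9, n_studies = 2, n_control = 15,
                      n_carcinoma = 15, study_effect_sd = 1.5)
  g <- generate_collection(cfg)$collection
  pooled <- rbind(g$studies$st1$counts, g$studies$st2$counts)
  labels <- rep(c("st1", "st2"), each = 30)
  d <- bray_curtis_matrix(pooled)
  res <- permanova(d, labels, n_perm = 999, seed = 1)
  expect_lte(res$p, 0.001)
})

test_that("configuration validation catches inconsistent effect sets", {
  expect_error(small_config(
    enriched = data.frame(index = 3, lfc = 1, patchiness = 0.2)),
    "disjoint")
  expect_error(small_config(
    enriched = data.frame(index = 20, lfc = 1, patchiness = 1)),
    "patchiness")
  expect_error(small_config(
    enriched = data.frame(index = 999, lfc = 1, patchiness = 0)),
    "exceeds n_taxa")
})

test_that("scale_config shrinks cohorts but keeps the design pattern", {
  cfg <- scale_config(default_fecal_config(1), 0.5)
  gs <- cfg$group_sizes
  expect_equal(unname(gs["baxter", ]), c(86, 99, 60))
  expect_equal(unname(gs["ahn", "adenoma"]), 0)   # zero groups stay zero
  expect_true(all(gs[default_fecal_config(1)$group_sizes > 0] >= 6))
})
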