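# Random Forest classification of diagnosis: per-study cross-validated AUC
# under three feature regimes, importance aggregation across studies, paired
# model comparison, and cross-study transfer evaluation.

#' Rank-based AUC
#'
#' Mann-Whitney AUC with midrank tie handling: the probability that a
#' randomly chosen case scores above a randomly chosen control (ties count
#' one half). Higher score is oriented toward the case class.
#'
#' @param scores Numeric scores.
#' @param labels Logical or 0/1 vector; `TRUE`/1 = case.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC of a single feature's relative abundance
#'
#' The feature's relative abundance is the classification score, in its raw
#' orientation (no flipping toward AUC >= 0.5), contrasting one tumor group
#' against controls within one study. A feature with constant abundance
#' scores 0.5 by the midrank convention.
#'
#' @param study A `study_table` with metadata.
#' @param feature Feature id.
#' @param comparison `"adenoma"` or `"carcinoma"`.
#' @return AUC in `[0, 1]`.
#' @export
single_taxon_auc <- function(study, feature,
                             comparison = c("carcinoma", "adenoma")) {
  comparison <- match.arg(comparison)
  if (!feature %in% study$feature_ids)
    stop("feature '", feature, "' not in study '", study$study_id, "'")
  keep <- study$meta$diagnosis %in% c("control", comparison)
  rel <- to_relative_abundance(study$counts[keep, , drop = FALSE])[, feature]
  is_case <- study$meta$diagnosis[keep] == comparison
  if (sum(is_case) == 0 || sum(!is_case) == 0)
    stop("empty group for '", comparison, "'")
  auc(rel, is_case)
}

#' Fit a Random Forest classifier
#'
#' An ensemble of `ntree` CART trees grown on bootstrap resamples with
#' `mtry = floor(sqrt(p))` candidate features per split (the convention of
#' the standard forest implementation) and Gini splitting, exposing
#' class-probability scores and permutation-based mean-decrease-in-accuracy
#' importances computed on the out-of-bag samples. Deterministic under
#' `seed`.
#'
#' @param features Samples-by-features numeric matrix.
#' @param labels Logical or 0/1 vector (`TRUE`/1 = case); both classes must
#'   be present.
#' @param seed Integer seed.
#' @param ntree Number of trees (default 500).
#' @param mtry Candidate features per split; default `floor(sqrt(p))`.
#' @param importance Compute permutation importances (default `TRUE`).
#' @return Object of class `crc_rf` with elements `trees`, `oob_prob`,
#'   `importance` (named by feature), `mtry`, `ntree`, `feature_ids`.
#' @export
train_rf <- function(features, labels, seed = 1, ntree = 500, mtry = NULL,
                     importance = TRUE) {
  features <- as.matrix(features)
  y <- as.integer(as.logical(labels))
  if (length(unique(y)) < 2) stop("labels contain a single class")
  if (ncol(features) < 1) stop("need at least one feature")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(features))))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  fit <- rf_fit_cpp(features, y, ntree = as.integer(ntree),
                    mtry = as.integer(mtry), min_node = 1L,
                    importance = importance)
  structure(list(trees = fit$trees,
                 oob_prob = stats::setNames(fit$oob_prob, rownames(features)),
                 importance = if (importance)
                   stats::setNames(fit$importance, colnames(features))
                 else NULL,
                 mtry = mtry, ntree = ntree,
                 feature_ids = colnames(features)),
            class = "crc_rf")
}

#' Predict case probabilities from a fitted forest
#' @param object A `crc_rf`.
#' @param newdata Samples-by-features matrix; columns are matched to the
#'   training features by name when named, with absent features zero-filled.
#' @param ... Unused.
#' @return Vector of class probabilities.
#' @export
predict.crc_rf <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) && !is.null(object$feature_ids)) {
    aligned <- matrix(0, nrow(newdata), length(object$feature_ids),
                      dimnames = list(rownames(newdata), object$feature_ids))
    shared <- intersect(object$feature_ids, colnames(newdata))
    aligned[, shared] <- newdata[, shared]
    newdata <- aligned
  }
  rf_predict_cpp(object$trees, newdata)
}

#' Seeded (stratified) fold assignment
#'
#' @param labels Class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param stratified Keep class proportions balanced across folds (default).
#' @return Integer fold assignment per sample.
#' @export
make_folds <- function(labels, k, seed = 1, stratified = TRUE) {
  n <- length(labels)
  if (k < 2 || k > n) stop("k must lie in [2, n]")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  fold <- integer(n)
  if (stratified) {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    fold <- sample(rep_len(seq_len(k), n))
  }
  fold
}

regime_features <- function(study, regime, features = NULL) {
  switch(regime,
         all_taxa = , otu = study$feature_ids,
         sig_or_taxa = {
           if (is.null(features))
             stop("regime 'sig_or_taxa' requires a feature list ",
                  "(from significant_features())")
           intersect(study$feature_ids, features)
         },
         stop("unknown regime '", regime, "'"))
}

#' Cross-validated Random Forest AUC for one study
#'
#' Stratified k-fold cross-validation; out-of-fold class probabilities are
#' pooled across folds into one ROC per repeat, and the reported AUC is the
#' mean over repeats (1 repeat for taxon regimes; the OTU regime
#' conventionally uses 100 repeats of 10-fold CV). When `k` exceeds the
#' smallest class size it falls back to `k = 2` with a warning, mirroring
#' the handling of very small cohorts. Importances come from a final fit on
#' all samples.
#'
#' @param study A `study_table` with metadata.
#' @param regime `"sig_or_taxa"`, `"all_taxa"`, or `"otu"`.
#' @param comparison `"adenoma"` or `"carcinoma"`.
#' @param k Folds (fecal convention 10, tissue 5).
#' @param repeats CV repetitions; default 1, or 100 when `regime = "otu"`.
#' @param seed Integer seed.
#' @param ntree Trees per forest.
#' @param features Feature ids for the `sig_or_taxa` regime.
#' @return List of class `cv_result`: `study_id`, `regime`, `comparison`,
#'   `auc`, `per_repeat`, `k`, `importances`.
#' @export
cv_auc <- function(study, regime = c("all_taxa", "sig_or_taxa", "otu"),
                   comparison = c("carcinoma", "adenoma"), k = 10,
                   repeats = NULL, seed = 1, ntree = 500, features = NULL) {
  regime <- match.arg(regime)
  comparison <- match.arg(comparison)
  if (is.null(repeats)) repeats <- if (regime == "otu") 100 else 1
  keep <- study$meta$diagnosis %in% c("control", comparison)
  counts <- study$counts[keep, , drop = FALSE]
  is_case <- study$meta$diagnosis[keep] == comparison
  if (sum(is_case) < 2 || sum(!is_case) < 2)
    stop("need >= 2 samples per class in study '", study$study_id, "'")
  feats <- regime_features(study, regime, features)
  if (length(feats) == 0) stop("no usable features for regime '", regime, "'")
  x <- to_relative_abundance(counts)[, feats, drop = FALSE]
  min_class <- min(sum(is_case), sum(!is_case))
  if (k > min_class) {
    warning("k = ", k, " exceeds smallest class size (", min_class,
            "); falling back to k = 2")
    k <- 2
  }
  per_repeat <- vapply(seq_len(repeats), function(r) {
    fold <- make_folds(is_case, k, seed = derive_seed(seed, "folds", r))
    oof <- rep(NA_real_, length(is_case))
    for (f in seq_len(k)) {
      test <- fold == f
      fit <- train_rf(x[!test, , drop = FALSE], is_case[!test],
                      seed = derive_seed(seed, "rf", r * 1000 + f),
                      ntree = ntree, importance = FALSE)
      oof[test] <- predict(fit, x[test, , drop = FALSE])
    }
    auc(oof, is_case)
  }, 0)
  final <- train_rf(x, is_case, seed = derive_seed(seed, "rf_final"),
                    ntree = ntree, importance = TRUE)
  structure(list(study_id = study$study_id, regime = regime,
                 comparison = comparison, auc = mean(per_repeat),
                 per_repeat = per_repeat, k = k,
                 importances = final$importance),
            class = "cv_result")
}

#' Cross-study importance ranking from Z-scored MDA values
#'
#' Within each study the mean-decrease-in-accuracy vector is Z-scored across
#' features; features are then ranked by their mean Z across studies.
#' Studies with constant MDA are skipped with a warning; features missing
#' from a study contribute nothing to their mean (the number of contributing
#' studies is reported).
#'
#' @param cv_results List of `cv_result` objects (one per study).
#' @return Data frame `feature`, `mean_z`, `n_studies`, `rank`, ordered by
#'   decreasing mean Z.
#' @export
mda_zscores <- function(cv_results) {
  stopifnot(length(cv_results) >= 1)
  zs <- list()
  for (cv in cv_results) {
    imp <- cv$importances
    if (length(unique(imp)) < 2) {
      warning("constant MDA in study '", cv$study_id, "'; skipped")
      next
    }
    zs[[cv$study_id]] <- zscore(imp)
  }
  if (length(zs) == 0) stop("no study with non-constant importances")
  feats <- unique(unlist(lapply(zs, names)))
  mean_z <- vapply(feats, function(f) {
    v <- unlist(lapply(zs, function(z) unname(z[f])))
    mean(v, na.rm = TRUE)
  }, 0)
  n_studies <- vapply(feats, function(f) {
    sum(vapply(zs, function(z) f %in% names(z) && !is.na(z[f]), TRUE))
  }, 0L)
  out <- data.frame(feature = feats, mean_z = unname(mean_z),
                    n_studies = unname(n_studies), stringsAsFactors = FALSE)
  out <- out[order(-out$mean_z), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' One-tailed paired t comparison of per-study AUCs
#'
#' Tests whether model A's AUCs exceed model B's on average across studies
#' (`mean(a - b) > 0`). Identical vectors give t = 0 and p = 0.5 by the
#' convention of the t distribution; a constant non-zero difference (zero
#' variance) is flagged degenerate with p taken to its limit (0 for a
#' positive mean, 1 for a negative one). Also reports the mean percent
#' difference relative to model B.
#'
#' @param aucs_a,aucs_b Per-study AUC vectors, paired by study, length >= 3.
#' @return List: `t`, `df`, `p`, `mean_diff`, `mean_pct_diff`, `degenerate`.
#' @export
compare_models <- function(aucs_a, aucs_b) {
  if (length(aucs_a) != length(aucs_b)) stop("vectors must be paired")
  if (length(aucs_a) < 3) stop("need >= 3 paired studies")
  d <- aucs_a - aucs_b
  mean_pct <- mean(d / aucs_b) * 100
  if (sd(d) == 0) {
    p <- if (mean(d) > 0) 0 else if (mean(d) < 0) 1 else 0.5
    return(list(t = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                df = length(d) - 1, p = p, mean_diff = mean(d),
                mean_pct_diff = mean_pct, degenerate = mean(d) != 0))
  }
  tstat <- mean(d) / (sd(d) / sqrt(length(d)))
  list(t = tstat, df = length(d) - 1,
       p = pt(tstat, df = length(d) - 1, lower.tail = FALSE),
       mean_diff = mean(d), mean_pct_diff = mean_pct, degenerate = FALSE)
}

# Biomarker panel for the transfer evaluation, selected by pooled
# meta-analysis over a subset of studies (the held-out test study is always
# excluded, so no test information reaches feature selection). When nothing
# survives BH, falls back to the `fallback` smallest pooled p values so a
# model can always be trained (the canonical panel size is 8 taxa).
select_panel <- function(collection, exclude, comparison, alpha = 0.05,
                         fallback = 8) {
  keep <- Filter(function(s) s$study_id != exclude, collection$studies)
  res <- suppressWarnings(
    significant_features(as_meta_collection(keep), comparison,
                         alpha = alpha))
  if (nrow(res) == 0) return(character(0))
  sel <- res$feature[res$significant]
  if (length(sel) < 2)
    sel <- res$feature[order(res$p)][seq_len(min(fallback, nrow(res)))]
  sel
}

#' Cross-study transfer evaluation
#'
#' Trains a forest on all samples of each study in turn and scores every
#' other study, recording the AUC grid (train studies in rows). The diagonal
#' holds the training study's own cross-validated AUC. For the
#' `sig_or_taxa` regime the biomarker panel for each test study is selected
#' by pooled meta-analysis over all studies except that test study, so no
#' test-study information reaches feature selection; the diagonal likewise
#' uses a leave-self-out panel. Cells whose test study lacks one of the
#' classes are `NA`.
#'
#' @param collection A `meta_collection`.
#' @param regime `"all_taxa"` or `"sig_or_taxa"`.
#' @param comparison `"adenoma"` or `"carcinoma"`.
#' @param k Folds for the diagonal CV.
#' @param seed Integer seed.
#' @param ntree Trees per forest.
#' @param alpha Selection threshold for the `sig_or_taxa` regime.
#' @param diagonal Fill the diagonal with the training study's own CV AUC
#'   (default); `FALSE` leaves it `NA` and skips the extra cross-validation.
#' @return List of class `transfer_matrix`: `auc` (train x test matrix),
#'   `median_test` (per train study, the median held-out AUC), `regime`,
#'   `comparison`.
#' @export
transfer_evaluate <- function(collection,
                              regime = c("sig_or_taxa", "all_taxa"),
                              comparison = c("carcinoma", "adenoma"),
                              k = 10, seed = 1, ntree = 500, alpha = 0.05,
                              diagonal = TRUE) {
  regime <- match.arg(regime)
  comparison <- match.arg(comparison)
  usable <- Filter(function(s) {
    tab <- table(factor(s$meta$diagnosis, DIAGNOSIS_LEVELS))
    tab[["control"]] >= 2 && tab[[comparison]] >= 2
  }, collection$studies)
  if (length(usable) < 2) stop("need >= 2 studies with both classes")
  ids <- vapply(usable, `[[`, "", "study_id")
  grid <- matrix(NA_real_, length(ids), length(ids),
                 dimnames = list(train = ids, test = ids))
  # per-test-study biomarker panels, each selected without that study
  panels <- if (regime == "sig_or_taxa") {
    stats::setNames(lapply(ids, function(te)
      select_panel(collection, exclude = te, comparison, alpha)), ids)
  } else NULL
  study_xy <- lapply(usable, function(s) {
    keep <- s$meta$diagnosis %in% c("control", comparison)
    list(x = to_relative_abundance(s$counts[keep, , drop = FALSE]),
         case = s$meta$diagnosis[keep] == comparison)
  })
  for (tr in ids) {
    s <- usable[[tr]]
    xy <- study_xy[[tr]]
    for (te in ids) {
      if (te == tr) next
      feats <- if (regime == "sig_or_taxa") panels[[te]] else s$feature_ids
      feats <- intersect(s$feature_ids, feats)
      if (length(feats) == 0) next
      fit <- train_rf(xy$x[, feats, drop = FALSE], xy$case,
                      seed = derive_seed(seed, "transfer_fit",
                                         match(tr, ids) * 100 +
                                           match(te, ids)),
                      ntree = ntree, importance = FALSE)
      xy_t <- study_xy[[te]]
      if (sum(xy_t$case) == 0 || sum(!xy_t$case) == 0) next
      grid[tr, te] <- auc(predict(fit, xy_t$x), xy_t$case)
    }
    if (diagonal) {
      feats_self <- if (regime == "sig_or_taxa")
        intersect(s$feature_ids, panels[[tr]]) else NULL
      if (regime == "all_taxa" || length(feats_self) > 0) {
        diag_cv <- suppressWarnings(
          cv_auc(s, regime = regime, comparison = comparison, k = k,
                 seed = derive_seed(seed, "transfer_cv", match(tr, ids)),
                 ntree = ntree, features = feats_self))
        grid[tr, tr] <- diag_cv$auc
      }
    }
  }
  med <- vapply(ids, function(tr)
    median(grid[tr, setdiff(ids, tr)], na.rm = TRUE), 0)
  structure(list(auc = grid, median_test = med, regime = regime,
                 comparison = comparison),
            class = "transfer_matrix")
}

#' @method print cv_result
#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("CV AUC [%s, %s, %s]: %.3f (k = %d, %d repeat%s)\n",
              x$study_id, x$regime, x$comparison, x$auc, x$k,
              length(x$per_repeat), if (length(x$per_repeat) > 1) "s" else ""))
  invisible(x)
}

#' @method print transfer_matrix
#' @export
print.transfer_matrix <- function(x, ...) {
  cat(sprintf("Transfer AUC grid (%s, %s); train studies in rows\n",
              x$regime, x$comparison))
  print(round(x$auc, 3))
  invisible(x)
}
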