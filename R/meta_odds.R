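# Per-taxon median-dichotomized odds ratios, chi-square testing,
# DerSimonian-Laird random-effects pooling, and Benjamini-Hochberg selection
# of significant biomarkers. This is the pipeline's core biomarker statistic.

#' Median-dichotomize abundances into an exposure indicator
#'
#' A sample is exposed when its value is strictly greater than the median
#' over all included samples; ties at the median count as unexposed.
#'
#' @param values Numeric vector (length >= 2), e.g. one taxon's relative
#'   abundances in one study.
#' @return Logical vector of exposure indicators.
#' @export
dichotomize <- function(values) {
  if (length(values) < 2) stop("need >= 2 samples to dichotomize")
  values > median(values)
}

#' Odds ratio for a 2x2 exposure-by-disease table
#'
#' Cells: `a` exposed cases, `b` exposed controls, `c` unexposed cases, `d`
#' unexposed controls. When any cell is zero the Haldane-Anscombe correction
#' (0.5 added to all four cells) is applied for the estimate and Woolf
#' interval; the chi-square test (1 df, no continuity correction) is always
#' computed on the uncorrected table. A table with an empty exposure margin
#' (`a + b = 0` or `c + d = 0`) is degenerate: it is returned flagged
#' `excluded` rather than as a number.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return List of class `or_result`: the cells plus `or`, `log_or`, `se`
#'   (Woolf), `ci_lo`, `ci_hi` (95%), `p_chisq`, `corrected`, `excluded`.
#' @export
odds_ratio <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != floor(cells)))
    stop("cells must be non-negative integers")
  if (a + c < 1 || b + d < 1)
    stop("need at least one case and one control")
  out <- list(a = a, b = b, c = c, d = d, corrected = FALSE,
              excluded = FALSE)
  if (a + b == 0 || c + d == 0) {
    out[c("or", "log_or", "se", "ci_lo", "ci_hi", "p_chisq")] <- NA_real_
    out$excluded <- TRUE
    class(out) <- "or_result"
    return(out)
  }
  aa <- a; bb <- b; cc <- c; dd <- d
  if (any(cells == 0)) {
    aa <- a + 0.5; bb <- b + 0.5; cc <- c + 0.5; dd <- d + 0.5
    out$corrected <- TRUE
  }
  out$log_or <- log(aa * dd / (bb * cc))
  out$se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  out$or <- exp(out$log_or)
  out$ci_lo <- exp(out$log_or - qnorm(0.975) * out$se)
  out$ci_hi <- exp(out$log_or + qnorm(0.975) * out$se)
  # Pearson chi-square on the uncorrected table
  n <- a + b + c + d
  num <- n * (a * d - b * c)^2
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  out$p_chisq <- pchisq(num / den, df = 1, lower.tail = FALSE)
  class(out) <- "or_result"
  out
}

#' @method print or_result
#' @export
print.or_result <- function(x, ...) {
  if (x$excluded) {
    cat(sprintf("OR: degenerate table (a=%d b=%d c=%d d=%d), excluded\n",
                x$a, x$b, x$c, x$d))
  } else {
    cat(sprintf("OR = %.3f [%.3f, %.3f], chi-square p = %.3g%s\n",
                x$or, x$ci_lo, x$ci_hi, x$p_chisq,
                if (x$corrected) " (Haldane-corrected)" else ""))
  }
  invisible(x)
}

#' DerSimonian-Laird random-effects pooling of per-study log odds ratios
#'
#' Fixed-effect weights `w_i = 1/se_i^2` give the heterogeneity statistic
#' `Q = sum(w_i (y_i - ybar_FE)^2)`; the between-study variance is
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`; random-effects
#' weights `1/(se_i^2 + tau2)` yield the pooled estimate, its standard
#' error, and a two-sided Wald p value.
#'
#' @param log_ors Per-study log odds ratios.
#' @param ses Per-study Woolf standard errors.
#' @return List of class `pooled_or`: `k`, `pooled_log_or`, `pooled_se`,
#'   `tau2`, `q`, `or`, `ci_lo`, `ci_hi`, `p`.
#' @export
pool_dl <- function(log_ors, ses) {
  stopifnot(length(log_ors) == length(ses))
  keep <- is.finite(log_ors) & is.finite(ses) & ses > 0
  y <- log_ors[keep]
  se <- ses[keep]
  k <- length(y)
  if (k < 2) stop("pooling requires >= 2 eligible studies")
  w <- 1 / se^2
  ybar <- sum(w * y) / sum(w)
  q <- sum(w * (y - ybar)^2)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (se^2 + tau2)
  pooled <- sum(wr * y) / sum(wr)
  pooled_se <- sqrt(1 / sum(wr))
  structure(list(
    k = k, pooled_log_or = pooled, pooled_se = pooled_se, tau2 = tau2,
    q = q, or = exp(pooled),
    ci_lo = exp(pooled - qnorm(0.975) * pooled_se),
    ci_hi = exp(pooled + qnorm(0.975) * pooled_se),
    p = 2 * pnorm(-abs(pooled / pooled_se))
  ), class = "pooled_or")
}

#' @method print pooled_or
#' @export
print.pooled_or <- function(x, ...) {
  cat(sprintf(
    "Pooled OR = %.3f [%.3f, %.3f], k = %d, tau2 = %.4f, p = %.3g\n",
    x$or, x$ci_lo, x$ci_hi, x$k, x$tau2, x$p))
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `adjusted_(i) = min over j >= i of (p_(j) * m / j)`, capped at 1,
#' returned in the input order.
#'
#' @param pvals Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  m <- length(pvals)
  if (m == 0) return(numeric(0))
  o <- order(pvals, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * pvals[o]))[ro]
}

#' Median-dichotomized odds ratio of one feature in one study
#'
#' Relative abundance of the feature among the compared samples (controls
#' plus one tumor group) is dichotomized at its median across those samples;
#' the resulting 2x2 goes through [odds_ratio()].
#'
#' @param study A `study_table` with metadata.
#' @param feature Feature id.
#' @param comparison `"adenoma"` or `"carcinoma"`.
#' @return An `or_result`.
#' @export
study_feature_or <- function(study, feature,
                             comparison = c("carcinoma", "adenoma")) {
  comparison <- match.arg(comparison)
  if (!feature %in% study$feature_ids)
    stop("feature '", feature, "' not in study '", study$study_id, "'")
  keep <- study$meta$diagnosis %in% c("control", comparison)
  counts <- study$counts[keep, , drop = FALSE]
  is_case <- study$meta$diagnosis[keep] == comparison
  if (sum(is_case) == 0 || sum(!is_case) == 0)
    stop("empty group for '", comparison, "' in study '", study$study_id, "'")
  rel <- to_relative_abundance(counts)[, feature]
  exposed <- dichotomize(rel)
  odds_ratio(a = sum(exposed & is_case), b = sum(exposed & !is_case),
             c = sum(!exposed & is_case), d = sum(!exposed & !is_case))
}

# Vectorized inner loop over all features of a collection: returns the long
# per-(feature, study) table of 2x2s and OR results.
all_feature_ors <- function(collection, comparison) {
  rows <- list()
  for (s in collection$studies) {
    keep <- s$meta$diagnosis %in% c("control", comparison)
    if (!any(keep)) next
    is_case <- s$meta$diagnosis[keep] == comparison
    if (sum(is_case) == 0 || sum(!is_case) == 0) next
    rel <- to_relative_abundance(s$counts[keep, , drop = FALSE])
    med <- apply(rel, 2, median)
    exposed <- sweep(rel, 2, med, ">")
    a <- colSums(exposed & is_case)
    b <- colSums(exposed & !is_case)
    cc <- colSums(!exposed & is_case)
    d <- colSums(!exposed & !is_case)
    ors <- lapply(seq_along(a), function(j)
      odds_ratio(a[j], b[j], cc[j], d[j]))
    rows[[s$study_id]] <- data.frame(
      feature = colnames(rel), study = s$study_id,
      a = a, b = b, c = cc, d = d,
      log_or = vapply(ors, `[[`, 0, "log_or"),
      se = vapply(ors, `[[`, 0, "se"),
      or = vapply(ors, `[[`, 0, "or"),
      p_chisq = vapply(ors, `[[`, 0, "p_chisq"),
      corrected = vapply(ors, `[[`, TRUE, "corrected"),
      excluded = vapply(ors, `[[`, TRUE, "excluded"),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Pooled per-taxon odds ratios with BH-corrected biomarker selection
#'
#' For every feature in the harmonized namespace: per-study median
#' dichotomization, 2x2 odds ratio, DerSimonian-Laird pooling over the
#' studies with non-degenerate tables (eligibility requires k >= 2), then
#' Benjamini-Hochberg correction of the pooled Wald p values across all
#' pooled features. A feature is significant when its adjusted p falls below
#' `alpha`.
#'
#' @param collection A harmonized taxon-level `meta_collection`.
#' @param comparison `"adenoma"` or `"carcinoma"`.
#' @param alpha Significance threshold on the BH-adjusted p (default 0.05).
#' @return Data frame, one row per eligible feature: `feature`, `k`,
#'   `log_or`, `or`, `ci_lo`, `ci_hi`, `tau2`, `p`, `p_bh`, `significant`.
#'   The per-(feature, study) long table is attached as attribute
#'   `"per_study"`; ineligible features as attribute `"ineligible"`.
#' @export
significant_features <- function(collection,
                                 comparison = c("carcinoma", "adenoma"),
                                 alpha = 0.05) {
  comparison <- match.arg(comparison)
  long <- all_feature_ors(collection, comparison)
  if (is.null(long) || nrow(long) == 0) {
    warning("no eligible features for comparison '", comparison, "'")
    return(structure(data.frame(), per_study = long, ineligible = character()))
  }
  eligible <- long[!long$excluded, , drop = FALSE]
  ks <- table(eligible$feature)
  pooled_feats <- names(ks)[ks >= 2]
  ineligible <- setdiff(unique(long$feature), pooled_feats)
  if (length(pooled_feats) == 0) {
    warning("no feature is non-degenerate in >= 2 studies")
    return(structure(data.frame(), per_study = long,
                     ineligible = ineligible))
  }
  res <- do.call(rbind, lapply(pooled_feats, function(f) {
    e <- eligible[eligible$feature == f, , drop = FALSE]
    p <- pool_dl(e$log_or, e$se)
    data.frame(feature = f, k = p$k, log_or = p$pooled_log_or, or = p$or,
               ci_lo = p$ci_lo, ci_hi = p$ci_hi, tau2 = p$tau2, p = p$p,
               stringsAsFactors = FALSE)
  }))
  res$p_bh <- bh_adjust(res$p)
  res$significant <- res$p_bh < alpha
  res <- res[order(res$p_bh, res$p), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, per_study = long, ineligible = ineligible)
}
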