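# Alpha diversity: richness, Shannon diversity, Pielou evenness, the
# power-transform / Z-normalization preprocessing, study-adjusted severity
# tests, and median-dichotomized diversity odds ratios.

#' Alpha-diversity metrics for one sample
#'
#' Richness S is the number of observed features, Shannon diversity
#' `H = -sum(p_i log p_i)` in nats over the non-zero proportions, and
#' evenness is Pielou's `J = H / log(S)` (defined as 0 when S = 1).
#'
#' @param counts Non-negative integer vector with positive total.
#' @return List with `richness`, `shannon`, `evenness`.
#' @export
alpha_metrics <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("all-zero count vector")
  p <- counts[counts > 0] / total
  s <- length(p)
  h <- -sum(p * log(p))
  j <- if (s >= 2) h / log(s) else 0
  list(richness = s, shannon = h, evenness = j)
}

#' Per-sample alpha-diversity table for a study
#'
#' @param study A `study_table`.
#' @param subsample_depth Optional common depth: each sample is rarefied to
#'   this depth (without replacement, seeded) before computing metrics;
#'   samples below the depth are dropped with a message. `NULL` (default)
#'   computes metrics on the full counts.
#' @param seed Seed for the optional rarefaction.
#' @return Data frame: sample metadata plus `richness`, `shannon`,
#'   `evenness`.
#' @export
alpha_table <- function(study, subsample_depth = NULL, seed = 1) {
  stopifnot(inherits(study, "study_table"))
  counts <- study$counts
  meta <- study$meta
  if (!is.null(subsample_depth)) {
    keep <- rowSums(counts) >= subsample_depth
    if (!all(keep)) {
      message("dropped ", sum(!keep), " sample(s) below subsample depth")
      counts <- counts[keep, , drop = FALSE]
      meta <- meta[keep, , drop = FALSE]
    }
    set.seed(derive_seed(seed, "rarefy"))
    counts <- t(apply(counts, 1, function(x) {
      drawn <- sample(rep.int(seq_along(x), x), subsample_depth)
      tabulate(drawn, nbins = length(x))
    }))
  }
  m <- t(apply(counts, 1, function(x) unlist(alpha_metrics(x))))
  cbind(meta, as.data.frame(m))
}

#' Tukey ladder-of-powers transform toward normality
#'
#' Chooses lambda on a grid to maximize the Shapiro-Wilk W statistic of the
#' transformed values. The transform is `x^lambda` for `lambda > 0`,
#' `log(x)` for `lambda = 0`, and `-x^lambda` for `lambda < 0` (negation
#' keeps the transform monotone increasing). Values are shifted to be
#' strictly positive first if any are `<= 0`, so that the log and negative
#' branches are defined.
#'
#' @param values Finite numeric vector, length >= 3, not constant.
#' @param grid Candidate lambdas (default -5 to 5 in steps of 0.05).
#' @return List: `values` (transformed), `lambda`, `shapiro_w`, `shift`.
#' @export
tukey_transform <- function(values, grid = seq(-5, 5, by = 0.05)) {
  if (any(!is.finite(values))) stop("values must be finite")
  if (length(values) < 3) stop("need at least 3 values")
  if (length(unique(values)) == 1)
    stop("constant vector: no transform defined")
  shift <- 0
  if (min(values) <= 0) {
    shift <- -min(values) + 1e-6 * max(1, diff(range(values)))
    values <- values + shift
  }
  # Shapiro-Wilk is defined for n in [3, 5000]; subsample deterministically
  # above that (it is a selection criterion, not an inference).
  w_of <- function(x) {
    if (length(unique(x)) == 1) return(-Inf)
    if (length(x) > 5000) x <- x[round(seq(1, length(x), length.out = 5000))]
    suppressWarnings(shapiro.test(x)$statistic)
  }
  best_w <- -Inf
  best_lambda <- NA_real_
  best_vals <- NULL
  for (lam in grid) {
    tv <- if (lam > 0) values^lam else if (lam == 0) log(values) else
      -(values^lam)
    w <- w_of(tv)
    if (is.finite(w) && w > best_w) {
      best_w <- w
      best_lambda <- lam
      best_vals <- tv
    }
  }
  if (!is.finite(best_w)) stop("no transform achieved a finite Shapiro W")
  list(values = unname(best_vals), lambda = best_lambda,
       shapiro_w = unname(best_w), shift = shift)
}

#' Z-score normalization
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @return Vector with mean 0 and sample standard deviation 1.
#' @export
zscore <- function(values) {
  if (length(unique(values)) < 2) stop("constant vector cannot be Z-scored")
  (values - mean(values)) / sd(values)
}

#' Linear mixed-effects test of an ordinal severity trend
#'
#' Fits `value ~ severity + region + (1 | study)` (plus `(1 | subject)` when
#' requested, for repeat-sampled tissue designs) with severity coded 0 / 1 /
#' 2 for control / adenoma / carcinoma. Values are expected to be
#' power-transformed and Z-normalized per study before entry. The p value is
#' a Wald normal approximation on the severity coefficient.
#'
#' @param df Data frame with columns `value`, `diagnosis`, `study_id`,
#'   `region`, `subject_id`.
#' @param subject_effect Include a random subject intercept.
#' @return List: `coefficient`, `se`, `p`, `model` descriptor.
#' @export
severity_lmm <- function(df, subject_effect = FALSE) {
  if (length(unique(df$study_id)) < 2)
    stop("severity test requires >= 2 studies; test per study instead")
  df$severity <- match(df$diagnosis, DIAGNOSIS_LEVELS) - 1
  if (anyNA(df$severity)) stop("unknown diagnosis token")
  if (sd(df$value) == 0) stop("no variance in values: model unfillable")
  terms <- "value ~ severity + (1 | study_id)"
  if (length(unique(df$region)) > 1)
    terms <- sub("~ severity", "~ severity + region", terms)
  if (subject_effect) terms <- paste(terms, "+ (1 | subject_id)")
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(as.formula(terms), data = df,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  cf <- summary(fit)$coefficients
  est <- cf["severity", "Estimate"]
  se <- cf["severity", "Std. Error"]
  p <- 2 * pnorm(-abs(est / se))
  list(coefficient = est, se = se, p = p, model = terms)
}

#' Study-adjusted severity test of an alpha-diversity metric
#'
#' Computes the metric per sample, power-transforms and Z-normalizes it
#' within each study, and fits the mixed model of [severity_lmm()] across
#' studies (random study intercept, fixed region; random subject intercept
#' for tissue).
#'
#' @param collection A `meta_collection` with metadata attached.
#' @param metric `"richness"`, `"shannon"`, or `"evenness"`.
#' @param site Restrict to one site; tissue adds the subject random effect.
#' @return List: `metric`, `coefficient`, `se`, `p`, `model`.
#' @export
severity_test <- function(collection, metric = c("evenness", "shannon",
                                                 "richness"),
                          site = c("feces", "tissue")) {
  metric <- match.arg(metric)
  site <- match.arg(site)
  collection <- subset_site(collection, site)
  if (length(collection$studies) < 2)
    stop("severity test requires >= 2 studies; test per study instead")
  rows <- lapply(collection$studies, function(s) {
    at <- alpha_table(s)
    v <- at[[metric]]
    v <- zscore(tukey_transform(v)$values)
    data.frame(value = v, diagnosis = at$diagnosis, study_id = at$study_id,
               region = at$region, subject_id = at$subject_id,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  res <- severity_lmm(df, subject_effect = (site == "tissue"))
  c(list(metric = metric), res)
}

#' Median-dichotomized odds ratio for an alpha-diversity metric
#'
#' Builds the 2x2 table contrasting one tumor group against controls within
#' one study: the metric's median is taken over the two compared groups
#' only, and a sample counts as exposed when its value falls strictly below
#' the median (`direction = "low"`, the default, so that OR > 1 means low
#' diversity is associated with disease; `direction = "high"` preserves the
#' literal above-median reading and inverts the OR).
#'
#' @param study A `study_table`.
#' @param metric `"richness"`, `"shannon"`, or `"evenness"`.
#' @param comparison `"adenoma"` or `"carcinoma"`.
#' @param direction `"low"` or `"high"`: which side of the median is the
#'   exposure.
#' @return An `or_result` (see [odds_ratio()]) with the 2x2 cells attached.
#' @export
diversity_or <- function(study, metric = c("evenness", "shannon", "richness"),
                         comparison = c("carcinoma", "adenoma"),
                         direction = c("low", "high")) {
  metric <- match.arg(metric)
  comparison <- match.arg(comparison)
  direction <- match.arg(direction)
  at <- alpha_table(study)
  keep <- at$diagnosis %in% c("control", comparison)
  at <- at[keep, , drop = FALSE]
  is_case <- at$diagnosis == comparison
  if (sum(is_case) == 0 || sum(!is_case) == 0)
    stop("empty group for comparison '", comparison, "' in study '",
         study$study_id, "'")
  median_split_or(at[[metric]], is_case, direction)
}

#' Median-split odds ratio of a continuous marker
#'
#' Core of [diversity_or()]: dichotomizes `values` at their median (over all
#' supplied samples, i.e. the two compared groups) and builds the 2x2
#' against case status. `direction = "low"` counts values strictly below the
#' median as exposed, so OR > 1 means low values associate with disease;
#' `direction = "high"` inverts the table (and hence the OR).
#'
#' @param values Numeric marker values.
#' @param is_case Logical case indicator, aligned with `values`.
#' @param direction `"low"` or `"high"`.
#' @return An `or_result`.
#' @export
median_split_or <- function(values, is_case, direction = c("low", "high")) {
  direction <- match.arg(direction)
  med <- median(values)
  exposed <- if (direction == "low") values < med else values > med
  odds_ratio(a = sum(exposed & is_case), b = sum(exposed & !is_case),
             c = sum(!exposed & is_case), d = sum(!exposed & !is_case))
}

#' Pooled diversity odds ratios across a collection
#'
#' Per-study [diversity_or()] results pooled with DerSimonian-Laird random
#' effects ([pool_dl()]); studies with degenerate tables are excluded.
#'
#' @inheritParams diversity_or
#' @param collection A `meta_collection`.
#' @return List with `per_study` (data frame) and `pooled` (a `pooled_or`),
#'   or `NULL` pooled result when fewer than 2 studies are eligible.
#' @export
diversity_or_pooled <- function(collection,
                                metric = c("evenness", "shannon", "richness"),
                                comparison = c("carcinoma", "adenoma"),
                                direction = c("low", "high")) {
  metric <- match.arg(metric)
  comparison <- match.arg(comparison)
  direction <- match.arg(direction)
  per <- list()
  for (s in collection$studies) {
    tab <- table(factor(s$meta$diagnosis, DIAGNOSIS_LEVELS))
    if (tab[["control"]] == 0 || tab[[comparison]] == 0) next
    per[[s$study_id]] <- diversity_or(s, metric, comparison, direction)
  }
  if (length(per) == 0) stop("no study has both groups for ", comparison)
  per_df <- do.call(rbind, lapply(names(per), function(id) {
    r <- per[[id]]
    data.frame(study = id, metric = metric, comparison = comparison,
               a = r$a, b = r$b, c = r$c, d = r$d,
               or = r$or, ci_lo = r$ci_lo, ci_hi = r$ci_hi,
               p = r$p_chisq, excluded = r$excluded,
               stringsAsFactors = FALSE)
  }))
  eligible <- Filter(function(r) !r$excluded, per)
  pooled <- if (length(eligible) >= 2) {
    pool_dl(vapply(eligible, `[[`, 0, "log_or"),
            vapply(eligible, `[[`, 0, "se"))
  } else NULL
  list(per_study = per_df, pooled = pooled)
}
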