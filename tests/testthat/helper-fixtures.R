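# Shared fixtures: all synthetic, built in code at test time.

# Tiny hand-built study: counts plus attached metadata.
toy_study <- function(study_id = "toy", n_control = 4, n_case = 4,
                      counts = NULL, diagnosis = NULL, site = "feces") {
  if (is.null(diagnosis))
    diagnosis <- rep(c("control", "carcinoma"), c(n_control, n_case))
  n <- length(diagnosis)
  if (is.null(counts)) {
    set.seed(42)
    counts <- matrix(rpois(n * 5, 20), n, 5)
  }
  rownames(counts) <- sprintf("%s_s%02d", study_id, seq_len(n))
  colnames(counts) <- paste0("tax", seq_len(ncol(counts)))
  meta <- data.frame(
    sample_id = rownames(counts), study_id = study_id,
    diagnosis = diagnosis, site = site,
    subject_id = rownames(counts), matched = FALSE, region = "V4",
    stringsAsFactors = FALSE)
  study_table(study_id, counts, "taxon", meta)
}

# Small multi-study synthetic config for fast end-to-end tests.
small_config <- function(seed = 1, n_studies = 4, n_control = 25,
                         n_adenoma = 0, n_carcinoma = 25, n_taxa = 60,
                         enriched = data.frame(index = c(20, 30),
                                               lfc = 1, patchiness = 0.3),
                         protective = data.frame(index = 3, lfc = -0.5),
                         study_effect_sd = 1, ...) {
  synthetic_config(
    study_ids = paste0("st", seq_len(n_studies)),
    group_sizes = matrix(rep(c(n_control, n_adenoma, n_carcinoma),
                             each = n_studies), ncol = 3),
    n_taxa = n_taxa, enriched_taxa = enriched, protective_taxa = protective,
    study_effect_sd = study_effect_sd, seed = seed, ...)
}

null_config <- function(seed = 1, n_studies = 4, n_control = 25,
                        n_carcinoma = 25, n_taxa = 60, ...) {
  small_config(seed = seed, n_studies = n_studies, n_control = n_control,
               n_carcinoma = n_carcinoma, n_taxa = n_taxa,
               enriched = NULL, protective = NULL, ...)
}

# Independent pseudo-F implementation used as the PERMANOVA oracle: direct
# evaluation of the sums-of-squares decomposition, no shared code with the
# package internals.
oracle_pseudo_f <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- unique(labels)
  a <- length(groups)
  ss_t <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) ss_t <- ss_t + d[i, j]^2
  ss_t <- ss_t / n
  ss_w <- 0
  for (g in groups) {
    idx <- which(labels == g)
    if (length(idx) >= 2) {
      s <- 0
      for (i in idx) for (j in idx) if (i < j) s <- s + d[i, j]^2
      ss_w <- ss_w + s / length(idx)
    }
  }
  ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
}

# Pair-enumeration AUC oracle.
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Benjamini-Hochberg min-over-suffix oracle.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}
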