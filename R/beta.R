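# Bray-Curtis dissimilarity and one-way permutation-based PERMANOVA.

#' Bray-Curtis dissimilarity between two samples
#'
#' `BC = sum(|x - y|) / sum(x + y)`; 0 for identical profiles, 1 for
#' disjoint supports.
#'
#' @param x,y Non-negative numeric vectors of equal length.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) stop("entries must be non-negative")
  denom <- sum(x + y)
  if (denom == 0) stop("both samples are all-zero")
  sum(abs(x - y)) / denom
}

#' Pairwise Bray-Curtis distance matrix for a study
#'
#' @param x A `study_table` or samples-by-features matrix.
#' @param relative Compute on per-sample relative abundances (default); set
#'   `FALSE` to use raw counts.
#' @return Symmetric matrix with zero diagonal, entries in `[0, 1]`, sample
#'   ids as dimnames.
#' @export
bray_curtis_matrix <- function(x, relative = TRUE) {
  m <- if (inherits(x, "study_table")) x$counts else as.matrix(x)
  if (relative) m <- to_relative_abundance(m)
  manhattan <- as.matrix(stats::dist(m, method = "manhattan"))
  totals <- rowSums(m)
  d <- manhattan / outer(totals, totals, "+")
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

# Within-group sum of squares from the squared-distance matrix for a set of
# group index vectors: SS_W = sum_g (1_g' D2 1_g) / (2 n_g).
ss_within <- function(d2, groups) {
  sum(vapply(groups, function(idx) {
    sum(d2[idx, idx]) / (2 * length(idx))
  }, 0))
}

#' One-way PERMANOVA on a distance matrix
#'
#' Pseudo-F is computed from sums of squared distances:
#' `SS_T = sum(d^2)/n` over all pairs, `SS_W` summed within groups, and
#' `F = (SS_T - SS_W)/(a - 1) / (SS_W/(n - a))`. Significance comes from
#' seeded label permutations: `p = (1 + #(F_perm >= F_obs)) / (1 + n_perm)`,
#' so p is never 0 and has resolution `1/(n_perm + 1)`.
#'
#' @param dist_matrix Symmetric dissimilarity matrix.
#' @param labels Group labels aligned with the matrix rows.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @param strata Optional vector of stratum ids (e.g. subject for matched
#'   tissue pairs); permutations then shuffle labels only within strata.
#' @return List of class `permanova_result`: `f`, `p`, `n_perm`, `groups`,
#'   `n`.
#' @export
permanova <- function(dist_matrix, labels, n_perm = 999, seed = 1,
                      strata = NULL) {
  d <- as.matrix(dist_matrix)
  if (any(!is.finite(d))) stop("non-finite distances")
  n <- nrow(d)
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels do not align with the matrix")
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least two groups")
  if (any(tab < 3)) stop("each group needs >= 3 samples (smallest has ",
                         min(tab), ")")
  a <- length(tab)
  d2 <- d^2
  ss_t <- sum(d2) / (2 * n)
  groups_of <- function(lab) split(seq_len(n), lab)
  ss_w <- ss_within(d2, groups_of(labels))
  f_of <- function(ssw) ((ss_t - ssw) / (a - 1)) / (ssw / (n - a))
  f_obs <- f_of(ss_w)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(derive_seed(seed, "permanova"))

  permute_labels <- function() {
    if (is.null(strata)) return(sample(labels))
    out <- labels
    for (idx in split(seq_len(n), strata))
      out[idx] <- labels[idx][sample(length(idx))]
    out
  }
  # All permuted labelings as group-indicator matrices; SS_W for every
  # permutation then comes from one matrix product per group:
  # 1_g' D2 1_g = colSums(Z_g * (D2 %*% Z_g)).
  perm_labels <- vapply(seq_len(n_perm), function(b) permute_labels(),
                        character(n))
  ss_w_perm <- numeric(n_perm)
  for (g in names(tab)) {
    z <- (perm_labels == g) * 1
    ss_w_perm <- ss_w_perm + colSums(z * (d2 %*% z)) / (2 * tab[[g]])
  }
  n_ge <- sum(f_of(ss_w_perm) >= f_obs - 1e-12)
  structure(list(f = f_obs, p = (1 + n_ge) / (1 + n_perm), n_perm = n_perm,
                 groups = names(tab), n = n),
            class = "permanova_result")
}

#' @method print permanova_result
#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: F = %.4f, p = %.4g (%d permutations, n = %d; %s)\n",
              x$f, x$p, x$n_perm, x$n, paste(x$groups, collapse = " vs ")))
  invisible(x)
}

#' Per-study PERMANOVA of community structure versus diagnosis
#'
#' Bray-Curtis on relative abundances, control versus one tumor group. For
#' matched designs the permutations are restricted to within-subject
#' exchanges.
#'
#' @param study A `study_table` with metadata.
#' @param comparison `"adenoma"` or `"carcinoma"`.
#' @param n_perm,seed Permutation settings.
#' @param relative Use relative abundances (default) or raw counts.
#' @return A `permanova_result`.
#' @export
study_permanova <- function(study, comparison = c("carcinoma", "adenoma"),
                            n_perm = 999, seed = 1, relative = TRUE) {
  comparison <- match.arg(comparison)
  keep <- study$meta$diagnosis %in% c("control", comparison)
  counts <- study$counts[keep, , drop = FALSE]
  meta <- study$meta[keep, , drop = FALSE]
  d <- bray_curtis_matrix(counts, relative = relative)
  strata <- if (any(meta$matched)) meta$subject_id else NULL
  permanova(d, meta$diagnosis, n_perm = n_perm, seed = seed, strata = strata)
}
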