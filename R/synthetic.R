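# Dirichlet-multinomial multi-study generator.
#
# The generator stands in for the sequence-processing stage: it emits the
# count tables and metadata a mothur-style workflow would produce, with the
# statistical structure the downstream analysis assumes -- strong study-level
# composition effects, a small set of carcinoma-enriched taxa whose presence
# is patchy across individuals, and consistently present protective taxa with
# reduced abundance in cases.

#' Configuration for the synthetic multi-study generator
#'
#' @param study_ids Character vector of study labels.
#' @param group_sizes Integer matrix (studies x 3) of control / adenoma /
#'   carcinoma sample counts per study.
#' @param site `"feces"` or `"tissue"` recorded in the metadata.
#' @param regions 16S variable-region tag per study (recycled if length 1).
#' @param matched Logical per study: if `TRUE` control and carcinoma (or
#'   adenoma) samples are paired by subject, emulating matched-tissue designs.
#' @param n_taxa Number of taxa in the shared namespace.
#' @param depth_mean,depth_dispersion Negative-binomial sequencing-depth
#'   model: `depth ~ NB(mu = depth_mean, size = depth_dispersion)`.
#' @param base_concentration Concentration scale of the community draw.
#'   Per-sample abundance components are independent gammas with common
#'   shape `base_concentration / n_taxa` and means following a Zipf-like
#'   (1/rank) base composition, then normalized (a generalized Dirichlet:
#'   the common shape decouples a taxon's overdispersion from its mean
#'   abundance, as observed in real surveys where rare taxa are not
#'   automatically absent at deep sequencing). Smaller values give noisier
#'   communities.
#' @param study_effect_sd Standard deviation (log scale) of per-study,
#'   per-taxon multiplicative effects; drives the between-study composition
#'   differences that motivate per-study analysis.
#' @param enriched_taxa Data frame `index`, `lfc`, `patchiness`: taxa
#'   enriched in carcinoma samples. `lfc` is stated on the log odds-ratio
#'   scale of the downstream median-dichotomized analysis and is translated
#'   internally into a log-abundance shift (see [generate_study()]);
#'   presence is zeroed with probability `patchiness` in every sample
#'   (diagnosis-independent patchy carriage; the abundance effect applies
#'   only when present).
#' @param protective_taxa Data frame `index`, `lfc` (negative, log
#'   odds-ratio scale): consistently present taxa with reduced abundance in
#'   cases.
#' @param adenoma_attenuation Multiplier in `[0,1]` applied to all disease
#'   effects for adenoma samples (default 0.25: adenomas carry little
#'   signal).
#' @param seed Integer seed; generation is deterministic under
#'   `(seed, study_index)`.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(study_ids, group_sizes, site = "feces",
                             regions = "V4", matched = FALSE,
                             n_taxa = 200, depth_mean = 10000,
                             depth_dispersion = 5, base_concentration = 150,
                             study_effect_sd = 1,
                             enriched_taxa = NULL, protective_taxa = NULL,
                             adenoma_attenuation = 0.25, seed = 1) {
  group_sizes <- matrix(as.integer(group_sizes), ncol = 3,
                        dimnames = list(study_ids,
                                        c("control", "adenoma", "carcinoma")))
  if (any(group_sizes < 0)) stop("group sizes must be non-negative")
  if (n_taxa < 1) stop("need at least one taxon")
  site <- match.arg(site, SITE_LEVELS)
  if (is.null(enriched_taxa))
    enriched_taxa <- data.frame(index = integer(), lfc = numeric(),
                                patchiness = numeric())
  if (is.null(protective_taxa))
    protective_taxa <- data.frame(index = integer(), lfc = numeric())
  stopifnot(all(c("index", "lfc", "patchiness") %in% names(enriched_taxa)),
            all(c("index", "lfc") %in% names(protective_taxa)))
  if (any(enriched_taxa$patchiness < 0 | enriched_taxa$patchiness >= 1))
    stop("patchiness must lie in [0, 1)")
  if (!all(is.finite(enriched_taxa$lfc)) || !all(is.finite(protective_taxa$lfc)))
    stop("fold changes must be finite")
  if (length(intersect(enriched_taxa$index, protective_taxa$index)) > 0)
    stop("enriched and protective taxon sets must be disjoint")
  if (any(c(enriched_taxa$index, protective_taxa$index) > n_taxa))
    stop("effect taxon index exceeds n_taxa")
  if (adenoma_attenuation < 0 || adenoma_attenuation > 1)
    stop("adenoma_attenuation must lie in [0, 1]")
  structure(list(
    study_ids = study_ids, group_sizes = group_sizes, site = site,
    regions = rep_len(regions, length(study_ids)),
    matched = rep_len(matched, length(study_ids)),
    n_taxa = as.integer(n_taxa), depth_mean = depth_mean,
    depth_dispersion = depth_dispersion,
    base_concentration = base_concentration,
    study_effect_sd = study_effect_sd,
    enriched_taxa = enriched_taxa, protective_taxa = protective_taxa,
    adenoma_attenuation = adenoma_attenuation, seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Default fecal-cohort configuration
#'
#' Eight fecal case-control cohorts with the published per-study control /
#' adenoma / carcinoma sample counts (1,737 samples in total), a 200-taxon
#' namespace, four rare patchy carcinoma-enriched taxa (log odds ratio 1.0,
#' patchiness 0.3), and two abundant protective taxa (log odds ratio -0.5).
#'
#' @param seed Integer seed.
#' @return A `synthetic_config`.
#' @export
default_fecal_config <- function(seed = 1) {
  ids <- c("ahn", "baxter", "brim", "flemer", "hale", "wang", "weir", "zeller")
  sizes <- rbind(
    c(148, 0, 62), c(172, 198, 120), c(6, 6, 0), c(37, 0, 43),
    c(473, 214, 17), c(56, 0, 46), c(4, 0, 7), c(50, 37, 41))
  regions <- c("V3-V4", "V4", "V1-V3", "V3-V4", "V3-V5", "V3", "V4", "V4")
  synthetic_config(
    study_ids = ids, group_sizes = sizes, site = "feces", regions = regions,
    matched = FALSE, n_taxa = 200,
    enriched_taxa = data.frame(index = c(60, 70, 80, 90), lfc = 1.0,
                               patchiness = 0.3),
    protective_taxa = data.frame(index = c(5, 8), lfc = -0.5),
    seed = seed)
}

#' Default tissue-cohort configuration
#'
#' Seven tissue cohorts with the published group sizes (492 samples). The
#' three cohorts with exactly equal control and case counts are generated as
#' matched designs (tumor and unaffected tissue from the same subject).
#'
#' @param seed Integer seed.
#' @return A `synthetic_config`.
#' @export
default_tissue_config <- function(seed = 1) {
  ids <- c("burns", "chen", "dejea", "flemer_t", "geng", "lu", "sanapareddy")
  sizes <- rbind(
    c(18, 0, 16), c(9, 0, 9), c(31, 0, 32), c(103, 37, 94),
    c(16, 0, 16), c(20, 20, 0), c(38, 0, 33))
  regions <- c("V5-V6", "V1-V3", "V3-V5", "V3-V4", "V1-V2", "V3-V4", "V1-V2")
  matched <- c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE)
  synthetic_config(
    study_ids = ids, group_sizes = sizes, site = "tissue", regions = regions,
    matched = matched, n_taxa = 200,
    enriched_taxa = data.frame(index = c(60, 70, 80, 90), lfc = 1.0,
                               patchiness = 0.3),
    protective_taxa = data.frame(index = c(5, 8), lfc = -0.5),
    seed = seed)
}

#' Scale a configuration's cohort sizes down
#'
#' Used to keep simulation-based tests inside a compute budget while
#' preserving the design (zero-group pattern, effect structure). Non-zero
#' groups never fall below `floor_size`.
#'
#' @param config A `synthetic_config`.
#' @param factor Multiplier applied to every group size.
#' @param floor_size Minimum size of a non-zero group after scaling.
#' @return The scaled `synthetic_config`.
#' @export
scale_config <- function(config, factor, floor_size = 6) {
  gs <- config$group_sizes
  scaled <- round(gs * factor)
  scaled[gs > 0 & scaled < floor_size] <- floor_size
  config$group_sizes <- matrix(as.integer(scaled), ncol = 3,
                               dimnames = dimnames(gs))
  config
}

# Zipf-like base composition shared by all studies: proportions ~ 1/rank.
base_composition <- function(n_taxa) {
  m <- 1 / seq_len(n_taxa)
  m / sum(m)
}

taxon_names <- function(n_taxa) sprintf("taxon_%03d", seq_len(n_taxa))

#' Translate a target dichotomized log odds ratio into a log-abundance shift
#'
#' The generator's disease effects are stated on the log odds-ratio scale of
#' the downstream median-dichotomized analysis. For a taxon whose abundance
#' component is gamma(`alpha`) with presence probability `1 - patchiness`,
#' this solves (for a balanced two-group design) for the log-abundance shift
#' `Delta` applied to cases such that, with the exposure threshold at the
#' pooled median, `logit P(case exposed) - logit P(control exposed)` equals
#' the stated `lfc`. When the target is unreachable (e.g. `patchiness >=
#' 0.5`, where the pooled median collapses onto the zero mass), it falls
#' back to the logistic-scale approximation
#' `Delta = lfc * sqrt(3 * trigamma(alpha)) / pi`.
#'
#' The translation ignores multinomial sampling noise and between-study
#' effects, so realized pooled log-ORs recover `lfc` only approximately;
#' that residual attenuation is part of the emulated world.
#'
#' @param lfc Target log odds ratio (sign gives direction).
#' @param alpha Gamma shape of the taxon's abundance component.
#' @param patchiness Probability the taxon is absent from a sample.
#' @return Log-abundance shift to apply to case samples.
#' @export
dichotomized_shift <- function(lfc, alpha, patchiness = 0) {
  if (lfc == 0) return(0)
  q <- 1 - patchiness
  fallback <- lfc * sqrt(3 * trigamma(alpha)) / pi
  if (q <= 0.5) return(fallback)
  surv <- function(logx, shift = 0)
    pgamma(exp(logx - shift), shape = alpha, lower.tail = FALSE)
  log_or_of <- function(delta) {
    # pooled median threshold m: 0.5 q S(m - delta) + 0.5 q S(m) = 0.5
    m <- tryCatch(
      uniroot(function(m) 0.5 * q * surv(m, delta) + 0.5 * q * surv(m) - 0.5,
              lower = -60, upper = 60, tol = 1e-10)$root,
      error = function(e) NA_real_)
    if (is.na(m)) return(NA_real_)
    eps <- 1e-12  # keep logits finite at the search bounds
    pc <- min(1 - eps, max(eps, q * surv(m, delta)))
    p0 <- min(1 - eps, max(eps, q * surv(m)))
    log(pc / (1 - pc)) - log(p0 / (1 - p0))
  }
  root <- tryCatch(
    uniroot(function(d) log_or_of(d) - lfc,
            lower = -40 * abs(lfc), upper = 40 * abs(lfc),
            tol = 1e-8)$root,
    error = function(e) NA_real_)
  if (is.na(root)) fallback else root
}

# Deterministic seed derivation: one global seed expands into per-stage,
# per-index streams so that any study can be regenerated in isolation.
#' Derive a per-stage seed from a global seed
#' @param seed Global integer seed.
#' @param stage Stage name (string; hashed).
#' @param index Integer index within the stage.
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage, index = 0) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + h * 10007 + index * 2531) %% 2147483646 + 1)
}

#' Generate one synthetic study
#'
#' For each sample: a sequencing depth is drawn from a negative binomial;
#' expected proportions are a per-sample generalized-Dirichlet community
#' draw (common-shape gammas with Zipf means) times the study's
#' multiplicative effect times the diagnosis effect (attenuated for
#' adenomas), with each patchy enriched taxon independently zeroed with its
#' patchiness probability in all samples; proportions are renormalized and
#' counts drawn multinomially. Deterministic under `(seed, study_index)`.
#'
#' @param config A `synthetic_config`.
#' @param study_index Which study (1-based).
#' @return A `study_table` with metadata attached.
#' @export
generate_study <- function(config, study_index) {
  stopifnot(inherits(config, "synthetic_config"))
  if (study_index < 1 || study_index > length(config$study_ids))
    stop("study_index out of range")
  sizes <- config$group_sizes[study_index, ]
  n <- sum(sizes)
  if (n == 0) stop("study has zero samples")
  p <- config$n_taxa
  sid <- config$study_ids[study_index]

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(derive_seed(config$seed, "generate_study", study_index))

  diagnosis <- rep(DIAGNOSIS_LEVELS, times = sizes)
  severity <- rep(c(0, 1, 2), times = sizes)

  # Per-study multiplicative composition effect (log scale). Disease-
  # associated taxa are exempt: the emulated world has signal taxa whose
  # behavior is shared across cohorts while null taxa are study-
  # idiosyncratic (the reason a small consistent panel transfers between
  # cohorts better than full-community models).
  u <- rnorm(p, 0, config$study_effect_sd)
  u[c(config$enriched_taxa$index, config$protective_taxa$index)] <- 0

  # Disease effects are stated on the log odds-ratio scale of the
  # median-dichotomized analysis and translated into log-abundance shifts
  # under the generator's own analytic model (see dichotomized_shift).
  shape0 <- config$base_concentration / p
  delta <- numeric(p)
  if (nrow(config$enriched_taxa) > 0)
    delta[config$enriched_taxa$index] <- mapply(
      dichotomized_shift, config$enriched_taxa$lfc, shape0,
      config$enriched_taxa$patchiness)
  if (nrow(config$protective_taxa) > 0)
    delta[config$protective_taxa$index] <- mapply(
      dichotomized_shift, config$protective_taxa$lfc, shape0, 0)
  eff <- outer(ifelse(severity == 2, 1,
                      ifelse(severity == 1, config$adenoma_attenuation, 0)),
               delta)                       # n x p log disease effect

  depth <- pmax(1, rnbinom(n, mu = config$depth_mean,
                           size = config$depth_dispersion))

  # community draw: common-shape gammas with Zipf means, normalized below
  m_base <- base_composition(p)
  g <- matrix(rgamma(n * p, shape = shape0, rate = 1), n, p)
  g <- sweep(g, 2, m_base / shape0, "*")

  # patchy presence for enriched taxa, independent of diagnosis
  present <- matrix(1, n, p)
  if (nrow(config$enriched_taxa) > 0) {
    for (r in seq_len(nrow(config$enriched_taxa))) {
      j <- config$enriched_taxa$index[r]
      present[, j] <- rbinom(n, 1, 1 - config$enriched_taxa$patchiness[r])
    }
  }

  w <- g * matrix(exp(u), n, p, byrow = TRUE) * exp(eff) * present
  rs <- rowSums(w)
  rs[rs == 0] <- 1
  probs <- w / rs

  counts <- matrix(0, n, p)
  for (i in seq_len(n))
    counts[i, ] <- rmultinom(1, depth[i], probs[i, ])
  # multinomial can in principle return a zero row only if depth = 0; depth
  # is clamped to >= 1 above, so every sample has positive total.
  sample_ids <- sprintf("%s_s%03d", sid, seq_len(n))
  rownames(counts) <- sample_ids
  colnames(counts) <- taxon_names(p)

  subject_id <- sample_ids
  if (config$matched[study_index]) {
    # pair controls with cases by subject where the design allows
    case_col <- if (sizes["carcinoma"] > 0) "carcinoma" else "adenoma"
    n_pair <- min(sizes["control"], sizes[case_col])
    ctrl_idx <- which(diagnosis == "control")[seq_len(n_pair)]
    case_idx <- which(diagnosis == case_col)[seq_len(n_pair)]
    pair_ids <- sprintf("%s_subj%03d", sid, seq_len(n_pair))
    subject_id[ctrl_idx] <- pair_ids
    subject_id[case_idx] <- pair_ids
  }
  matched_flag <- config$matched[study_index] &
    subject_id %in% subject_id[duplicated(subject_id)]

  meta <- data.frame(
    sample_id = sample_ids, study_id = sid, diagnosis = diagnosis,
    site = config$site, subject_id = subject_id, matched = matched_flag,
    region = config$regions[study_index], stringsAsFactors = FALSE)
  out <- study_table(sid, counts, "taxon", meta)
  attr(out, "study_effect") <- stats::setNames(u, colnames(counts))
  out
}

#' Generate a full synthetic collection plus ground truth
#'
#' @param config A `synthetic_config`.
#' @return A list with `collection` (a `meta_collection`) and `truth` (a
#'   `data.frame` with per-taxon association labels and true log fold
#'   changes, plus a `study_effects` attribute holding the realized
#'   per-study log-scale effects).
#' @export
generate_collection <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  studies <- lapply(seq_along(config$study_ids),
                    function(i) generate_study(config, i))
  collection <- as_meta_collection(studies)

  label <- rep("null", config$n_taxa)
  lfc <- numeric(config$n_taxa)
  patchiness <- numeric(config$n_taxa)
  label[config$enriched_taxa$index] <- "enriched"
  lfc[config$enriched_taxa$index] <- config$enriched_taxa$lfc
  patchiness[config$enriched_taxa$index] <- config$enriched_taxa$patchiness
  label[config$protective_taxa$index] <- "protective"
  lfc[config$protective_taxa$index] <- config$protective_taxa$lfc
  truth <- data.frame(feature = taxon_names(config$n_taxa), label = label,
                      lfc = lfc, patchiness = patchiness,
                      stringsAsFactors = FALSE)
  attr(truth, "study_effects") <-
    do.call(cbind, lapply(studies, attr, "study_effect"))
  list(collection = collection, truth = truth)
}
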