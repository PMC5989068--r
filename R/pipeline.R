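# Configuration-driven orchestration: simulate (or load) a collection, then
# run diversity, PERMANOVA, pooled ORs, single-taxon AUCs, CV models, MDA
# ranking, and transfer evaluation, writing one TSV per analysis plus a
# machine-readable manifest.

#' Build a pipeline configuration
#'
#' @param mode `"simulate"` (generate a synthetic collection) or `"load"`
#'   (read a collection directory).
#' @param out_dir Output directory.
#' @param site `"feces"` or `"tissue"`; selects defaults (fold counts, the
#'   default generator) as well as the metadata subset analyzed.
#' @param comparisons Tumor groups to contrast against controls.
#' @param collection_dir Input directory for `mode = "load"`.
#' @param config Optional `synthetic_config` for `mode = "simulate"`
#'   (default: the site's default generator).
#' @param alpha BH significance threshold.
#' @param folds Cross-validation folds (default 10 for feces, 5 for tissue).
#' @param otu_repeats CV repeats for the OTU regime (default 100).
#' @param n_perm PERMANOVA permutations.
#' @param ntree Trees per forest.
#' @param seed Global seed, expanded deterministically into per-stage seeds.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("simulate", "load"), out_dir,
                            site = "feces",
                            comparisons = c("adenoma", "carcinoma"),
                            collection_dir = NULL, config = NULL,
                            alpha = 0.05, folds = NULL, otu_repeats = 100,
                            n_perm = 999, ntree = 500, seed = 1) {
  mode <- match.arg(mode)
  site <- match.arg(site, SITE_LEVELS)
  if (mode == "load" && (is.null(collection_dir) ||
                         !dir.exists(collection_dir)))
    stop("mode 'load' requires an existing collection_dir")
  if (is.null(folds)) folds <- if (site == "feces") 10 else 5
  structure(list(mode = mode, out_dir = out_dir, site = site,
                 comparisons = match.arg(comparisons, several.ok = TRUE),
                 collection_dir = collection_dir, config = config,
                 alpha = alpha, folds = folds, otu_repeats = otu_repeats,
                 n_perm = n_perm, ntree = ntree, seed = as.integer(seed)),
            class = "pipeline_config")
}

log_stage <- function(...) {
  message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

#' Run the full meta-analysis pipeline
#'
#' Emits, per comparison: the per-sample diversity table with pooled
#' diversity ORs, per-study PERMANOVA results, the pooled per-taxon OR
#' table (long per-study companion included), single-taxon AUCs for the
#' significant biomarkers, CV AUCs for the feature regimes, the MDA Z-score
#' ranking, and the cross-study transfer matrix; plus `manifest.json`
#' recording versions, seeds, and per-stage status. Any stage failure aborts
#' with the stage name; a `FAILED` marker file preserves partial output.
#'
#' @param cfg A `pipeline_config`.
#' @return Invisibly, a list of the result objects.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "crcmeta",
                   version = as.character(packageVersion("crcmeta")),
                   seed = cfg$seed, mode = cfg$mode, site = cfg$site,
                   stages = list())
  results <- list()
  stage <- function(name, expr) {
    log_stage("stage: ", name)
    out <- tryCatch(expr, error = function(e) {
      writeLines(paste("FAILED at stage:", name, "-", conditionMessage(e)),
                 file.path(cfg$out_dir, "FAILED"))
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- "ok"
    out
  }

  collection <- stage("input", {
    if (cfg$mode == "simulate") {
      gen_cfg <- cfg$config
      if (is.null(gen_cfg)) {
        gen_cfg <- if (cfg$site == "feces")
          default_fecal_config(seed = derive_seed(cfg$seed, "simulate"))
        else default_tissue_config(seed = derive_seed(cfg$seed, "simulate"))
      }
      gen <- generate_collection(gen_cfg)
      sim_dir <- file.path(cfg$out_dir, "collection")
      write_collection(gen$collection, sim_dir)
      write_result_tsv(gen$truth, file.path(cfg$out_dir, "truth.tsv"),
                       seed = cfg$seed)
      gen$collection
    } else {
      read_collection(cfg$collection_dir)
    }
  })
  collection <- subset_site(collection, cfg$site)
  manifest$n_studies <- length(collection$studies)
  manifest$studies <- names(collection$studies)

  has_groups <- function(s, comparison) {
    tab <- table(factor(s$meta$diagnosis, DIAGNOSIS_LEVELS))
    tab[["control"]] >= 2 && tab[[comparison]] >= 2
  }

  for (comparison in cfg$comparisons) {
    tag <- paste0(cfg$site, "_", comparison)
    studies <- Filter(function(s) has_groups(s, comparison),
                      collection$studies)
    skipped <- setdiff(names(collection$studies), names(studies))
    if (length(skipped) > 0)
      log_stage("comparison ", comparison, ": skipping ",
                paste(skipped, collapse = ", "), " (missing group)")
    if (length(studies) < 2) {
      log_stage("comparison ", comparison, ": fewer than 2 usable studies; ",
                "skipped entirely")
      next
    }
    sub <- as_meta_collection(studies)

    results[[paste0("diversity_", tag)]] <- stage(paste0("diversity_", tag), {
      per_sample <- do.call(rbind, lapply(studies, alpha_table))
      write_result_tsv(per_sample,
                       file.path(cfg$out_dir, paste0("alpha_", tag, ".tsv")),
                       seed = cfg$seed)
      or_rows <- do.call(rbind, lapply(
        c("richness", "shannon", "evenness"), function(metric) {
          r <- diversity_or_pooled(sub, metric, comparison)
          df <- r$per_study
          if (!is.null(r$pooled))
            df <- rbind(df, data.frame(
              study = "pooled", metric = metric, comparison = comparison,
              a = NA, b = NA, c = NA, d = NA, or = r$pooled$or,
              ci_lo = r$pooled$ci_lo, ci_hi = r$pooled$ci_hi,
              p = r$pooled$p, excluded = FALSE))
          df
        }))
      write_result_tsv(or_rows,
                       file.path(cfg$out_dir,
                                 paste0("diversity_or_", tag, ".tsv")),
                       seed = cfg$seed)
      or_rows
    })

    results[[paste0("permanova_", tag)]] <- stage(paste0("permanova_", tag), {
      rows <- do.call(rbind, lapply(studies, function(s) {
        r <- study_permanova(s, comparison, n_perm = cfg$n_perm,
                             seed = derive_seed(cfg$seed, "permanova",
                                                match(s$study_id,
                                                      names(studies))))
        data.frame(study = s$study_id, comparison = comparison, f = r$f,
                   p = r$p, n_perm = r$n_perm, n = r$n,
                   matched = any(s$meta$matched))
      }))
      write_result_tsv(rows, file.path(cfg$out_dir,
                                       paste0("permanova_", tag, ".tsv")),
                       seed = cfg$seed)
      rows
    })

    sig <- stage(paste0("meta_or_", tag), {
      res <- significant_features(sub, comparison, alpha = cfg$alpha)
      write_result_tsv(res, file.path(cfg$out_dir,
                                      paste0("pooled_or_", tag, ".tsv")),
                       seed = cfg$seed)
      write_result_tsv(attr(res, "per_study"),
                       file.path(cfg$out_dir,
                                 paste0("per_study_or_", tag, ".tsv")),
                       seed = cfg$seed)
      res
    })
    results[[paste0("meta_or_", tag)]] <- sig
    sig_taxa <- if (nrow(sig) > 0) sig$feature[sig$significant] else
      character(0)
    manifest[[paste0("n_significant_", tag)]] <- length(sig_taxa)

    results[[paste0("single_auc_", tag)]] <-
      stage(paste0("single_auc_", tag), {
        rows <- if (length(sig_taxa) == 0) {
          data.frame(feature = character(), study = character(),
                     auc = numeric())
        } else {
          do.call(rbind, lapply(sig_taxa, function(f) {
            do.call(rbind, lapply(studies, function(s)
              data.frame(feature = f, study = s$study_id,
                         auc = single_taxon_auc(s, f, comparison))))
          }))
        }
        write_result_tsv(rows, file.path(cfg$out_dir,
                                         paste0("single_auc_", tag, ".tsv")),
                         seed = cfg$seed)
        rows
      })

    regimes <- if (length(sig_taxa) > 0) c("sig_or_taxa", "all_taxa") else
      "all_taxa"
    cv_rows <- list()
    cv_results <- list()
    results[[paste0("cv_", tag)]] <- stage(paste0("cv_", tag), {
      for (regime in regimes) {
        for (s in studies) {
          cv <- suppressWarnings(cv_auc(
            s, regime = regime, comparison = comparison, k = cfg$folds,
            seed = derive_seed(cfg$seed, "cv", match(s$study_id,
                                                     names(studies))),
            ntree = cfg$ntree,
            features = if (regime == "sig_or_taxa") sig_taxa else NULL))
          cv_rows[[paste(regime, s$study_id)]] <-
            data.frame(study = s$study_id, regime = regime,
                       comparison = comparison, auc = cv$auc, k = cv$k)
          if (regime == if (length(sig_taxa) > 0) "sig_or_taxa" else
              "all_taxa")
            cv_results[[s$study_id]] <- cv
        }
      }
      df <- do.call(rbind, cv_rows)
      write_result_tsv(df, file.path(cfg$out_dir,
                                     paste0("cv_auc_", tag, ".tsv")),
                       seed = cfg$seed)
      df
    })

    results[[paste0("mda_", tag)]] <- stage(paste0("mda_", tag), {
      rk <- suppressWarnings(mda_zscores(cv_results))
      write_result_tsv(rk, file.path(cfg$out_dir,
                                     paste0("mda_rank_", tag, ".tsv")),
                       seed = cfg$seed)
      rk
    })

    results[[paste0("transfer_", tag)]] <- stage(paste0("transfer_", tag), {
      tm <- transfer_evaluate(sub, regime = regimes[1],
                              comparison = comparison, k = cfg$folds,
                              seed = derive_seed(cfg$seed, "transfer"),
                              ntree = cfg$ntree, alpha = cfg$alpha)
      df <- data.frame(train = rownames(tm$auc),
                       as.data.frame(tm$auc),
                       median_test = tm$median_test, check.names = FALSE)
      write_result_tsv(df, file.path(cfg$out_dir,
                                     paste0("transfer_", tag, ".tsv")),
                       seed = cfg$seed)
      tm
    })
  }

  jsonlite::write_json(manifest,
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_stage("pipeline complete: ", cfg$out_dir)
  invisible(results)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `diversity`, `permanova`, `meta-or`, `classify`,
#' `transfer`, `run`. Invoked by the `crcmeta` script shipped under
#' `inst/cli/`; call directly as `crcmeta_main(c("simulate", "--out", dir))`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
crcmeta_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: crcmeta <simulate|diversity|permanova|meta-or|classify|",
        "transfer|run> [options]\n", sep = "")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- parse_cli_options(args[-1])
  seed <- as.integer(opts$seed %||% 1)
  site <- opts$site %||% "feces"
  comparison <- opts$comparison %||% "carcinoma"
  get_collection <- function()
    read_collection(opts$collection,
                    min_total = as.numeric(opts$`min-total` %||% 100))
  switch(cmd,
    simulate = {
      cfg <- if (site == "feces") default_fecal_config(seed) else
        default_tissue_config(seed)
      gen <- generate_collection(cfg)
      write_collection(gen$collection, opts$out)
      write_result_tsv(gen$truth, file.path(opts$out, "truth.tsv"), seed)
      message("wrote ", length(gen$collection$studies), " studies to ",
              opts$out)
    },
    diversity = {
      coll <- subset_site(get_collection(), site)
      rows <- do.call(rbind, lapply(
        c("richness", "shannon", "evenness"), function(m)
          diversity_or_pooled(coll, m, comparison)$per_study))
      write_result_tsv(rows, opts$out, seed)
    },
    permanova = {
      tab <- read_feature_table(opts$study, "tsv")
      tab <- attach_metadata(tab, opts$metadata)
      r <- study_permanova(tab, comparison,
                           n_perm = as.integer(opts$permutations %||% 999),
                           seed = seed)
      write_result_tsv(data.frame(f = r$f, p = r$p, n_perm = r$n_perm,
                                  n = r$n), opts$out, seed)
    },
    `meta-or` = {
      coll <- subset_site(get_collection(), site)
      res <- significant_features(coll, comparison,
                                  alpha = as.numeric(opts$alpha %||% 0.05))
      write_result_tsv(res, opts$out, seed)
    },
    classify = {
      coll <- subset_site(get_collection(), site)
      regime <- opts$regime %||% "all_taxa"
      feats <- NULL
      if (regime == "sig_or_taxa") {
        sig <- significant_features(coll, comparison)
        feats <- sig$feature[sig$significant]
      }
      rows <- do.call(rbind, lapply(coll$studies, function(s) {
        cv <- suppressWarnings(cv_auc(
          s, regime = regime, comparison = comparison,
          k = as.integer(opts$folds %||% 10),
          repeats = if (!is.null(opts$repeats))
            as.integer(opts$repeats) else NULL,
          seed = seed, features = feats))
        data.frame(study = s$study_id, regime = regime, auc = cv$auc,
                   k = cv$k)
      }))
      write_result_tsv(rows, opts$out, seed)
    },
    transfer = {
      coll <- subset_site(get_collection(), site)
      tm <- transfer_evaluate(coll, regime = opts$regime %||% "sig_or_taxa",
                              comparison = comparison, seed = seed)
      df <- data.frame(train = rownames(tm$auc), as.data.frame(tm$auc),
                       median_test = tm$median_test, check.names = FALSE)
      write_result_tsv(df, opts$out, seed)
    },
    run = {
      cfg_list <- jsonlite::read_json(opts$config, simplifyVector = TRUE)
      cfg <- pipeline_config(
        mode = cfg_list$mode %||% "simulate",
        out_dir = cfg_list$out_dir %||% opts$out,
        site = cfg_list$site %||% "feces",
        comparisons = cfg_list$comparisons %||% c("adenoma", "carcinoma"),
        collection_dir = cfg_list$collection_dir,
        alpha = cfg_list$alpha %||% 0.05,
        folds = cfg_list$folds, n_perm = cfg_list$n_perm %||% 999,
        ntree = cfg_list$ntree %||% 500, seed = cfg_list$seed %||% seed)
      run_pipeline(cfg)
    },
    stop("unknown subcommand '", cmd, "'")
  )
  invisible(0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_cli_options <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3)
      if (i < length(args) && !startsWith(args[i + 1], "--")) {
        opts[[key]] <- args[i + 1]
        i <- i + 2
      } else {
        opts[[key]] <- TRUE
        i <- i + 1
      }
    } else {
      stop("unexpected argument '", a, "'")
    }
  }
  opts
}
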