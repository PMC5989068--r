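#' @useDynLib crcmeta, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median qnorm pnorm pchisq pt rgamma rnbinom rnorm rbinom
#'   rmultinom runif sd shapiro.test as.formula complete.cases
#' @importFrom utils read.table write.table packageVersion
"_PACKAGE"

# Closed vocabularies for sample annotation. Diagnosis doubles as an ordinal
# severity scale (control < adenoma < carcinoma) in the mixed-effects tests.
DIAGNOSIS_LEVELS <- c("control", "adenoma", "carcinoma")
SITE_LEVELS <- c("feces", "tissue")

PLACEHOLDER <- "unattached"

#' Construct a per-study feature table
#'
#' A `study_table` bundles one cohort's samples-by-features count matrix with
#' per-sample metadata and provenance (site, 16S region). Counts are stored
#' samples-in-rows; this orientation is fixed throughout the package.
#'
#' @param study_id Cohort identifier.
#' @param counts Non-negative integer matrix, samples in rows, features in
#'   columns. Row names are sample ids, column names feature ids.
#' @param feature_level Either `"taxon"` (RDP-style coarse labels, poolable
#'   across studies) or `"otu"` (97% similarity clusters, study-specific).
#' @param meta Data frame with one row per sample: `sample_id`, `study_id`,
#'   `diagnosis`, `site`, `subject_id`, `matched`, `region`. May be `NULL`
#'   before [attach_metadata()] has been called.
#' @return An object of class `study_table`.
#' @export
study_table <- function(study_id, counts, feature_level = c("taxon", "otu"),
                        meta = NULL) {
  feature_level <- match.arg(feature_level)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(meta)) {
    meta <- data.frame(
      sample_id = rownames(counts),
      study_id = study_id,
      diagnosis = PLACEHOLDER,
      site = PLACEHOLDER,
      subject_id = rownames(counts),
      matched = FALSE,
      region = PLACEHOLDER,
      stringsAsFactors = FALSE
    )
    attached <- FALSE
  } else {
    attached <- TRUE
  }
  x <- structure(
    list(study_id = study_id, feature_ids = colnames(counts),
         feature_level = feature_level, counts = counts, meta = meta,
         metadata_attached = attached),
    class = "study_table"
  )
  validate_study_table(x)
  x
}

validate_study_table <- function(x) {
  counts <- x$counts
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix must carry sample ids (rows) and feature ids (columns)")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate feature ids in study '", x$study_id, "'")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids in study '", x$study_id, "'")
  bad <- which(counts < 0 | counts != floor(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf(
      "negative or non-integer count at sample '%s', feature '%s'",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  zt <- rowSums(counts) == 0
  if (any(zt))
    stop("sample(s) with zero total counts: ",
         paste(rownames(counts)[zt], collapse = ", "))
  if (nrow(x$meta) != nrow(counts))
    stop("metadata row count does not match sample count")
  if (!identical(x$meta$sample_id, rownames(counts)))
    stop("metadata sample ids out of sync with count matrix rows")
  if (x$metadata_attached) {
    if (!all(x$meta$diagnosis %in% DIAGNOSIS_LEVELS))
      stop("unknown diagnosis token(s): ",
           paste(setdiff(x$meta$diagnosis, DIAGNOSIS_LEVELS), collapse = ", "),
           " (allowed: ", paste(DIAGNOSIS_LEVELS, collapse = ", "), ")")
    if (!all(x$meta$site %in% SITE_LEVELS))
      stop("unknown site token(s): ",
           paste(setdiff(x$meta$site, SITE_LEVELS), collapse = ", "),
           " (allowed: ", paste(SITE_LEVELS, collapse = ", "), ")")
    # matched samples must actually come in within-study subject groups
    if (any(x$meta$matched)) {
      tab <- table(x$meta$subject_id[x$meta$matched])
      if (any(tab < 2))
        stop("matched=true samples whose subject_id occurs only once: ",
             paste(names(tab)[tab < 2], collapse = ", "))
    }
  }
  invisible(x)
}

#' @method print study_table
#' @export
print.study_table <- function(x, ...) {
  cat(sprintf("<study_table> %s: %d samples x %d %s features\n",
              x$study_id, nrow(x$counts), ncol(x$counts), x$feature_level))
  if (x$metadata_attached) {
    tab <- table(factor(x$meta$diagnosis, DIAGNOSIS_LEVELS))
    cat("  diagnosis:", paste(names(tab), tab, sep = "=", collapse = " "),
        "| site:", paste(unique(x$meta$site), collapse = ","), "\n")
  } else {
    cat("  metadata not attached\n")
  }
  invisible(x)
}

#' Read a per-study feature table from disk
#'
#' Two dialects are supported: plain TSV (header row of feature ids, first
#' column `sample_id`) and the mothur `.shared` dialect (columns `label`,
#' `Group`, `numOtus`, then one column per OTU).
#'
#' @param path Path to the table.
#' @param dialect `"tsv"` or `"mothur_shared"`.
#' @param study_id Study identifier; defaults to the file name without
#'   extension.
#' @param feature_level `"taxon"` or `"otu"`.
#' @param min_total Samples whose total count falls strictly below this
#'   threshold are dropped with a message. The default (1) only enforces the
#'   hard rule that zero-total samples are rejected; the command-line
#'   interface passes 100, mirroring the exclusion of cohorts whose case
#'   samples retained 100 or fewer sequences.
#' @return A `study_table` with placeholder metadata (see
#'   [attach_metadata()]).
#' @export
read_feature_table <- function(path, dialect = c("tsv", "mothur_shared"),
                               study_id = NULL, feature_level = "taxon",
                               min_total = 1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(study_id))
    study_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("parse error: '", path, "' is empty")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (dialect == "tsv") {
    if (length(header) < 2 || header[1] != "sample_id")
      stop("parse error at line 1: expected header 'sample_id<TAB>feature...'")
    feature_ids <- header[-1]
    body <- strsplit(lines[-1], "\t", fixed = TRUE)
    nf <- lengths(body)
    if (any(nf != length(header)))
      stop("parse error at line ", which(nf != length(header))[1] + 1,
           ": wrong number of fields")
    sample_ids <- vapply(body, `[[`, "", 1L)
    counts <- do.call(rbind, lapply(body, function(r) {
      suppressWarnings(as.numeric(r[-1]))
    }))
  } else {
    if (length(header) < 3 || !identical(tolower(header[1:3]),
                                         c("label", "group", "numotus")))
      stop("parse error at line 1: expected mothur shared header ",
           "'label<TAB>Group<TAB>numOtus<TAB>...'")
    feature_ids <- header[-(1:3)]
    body <- strsplit(lines[-1], "\t", fixed = TRUE)
    nf <- lengths(body)
    if (any(nf != length(header)))
      stop("parse error at line ", which(nf != length(header))[1] + 1,
           ": wrong number of fields")
    sample_ids <- vapply(body, `[[`, "", 2L)
    num_otus <- suppressWarnings(as.integer(vapply(body, `[[`, "", 3L)))
    if (any(is.na(num_otus)) || any(num_otus != length(feature_ids)))
      stop("validation error: numOtus column disagrees with header (",
           length(feature_ids), " OTU columns)")
    counts <- do.call(rbind, lapply(body, function(r) {
      suppressWarnings(as.numeric(r[-(1:3)]))
    }))
  }
  bad <- which(is.na(counts) | counts < 0 | counts != floor(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf(
      "validation error: negative or non-integer count at sample '%s', feature '%s'",
      sample_ids[bad[1, 1]], feature_ids[bad[1, 2]]))
  if (anyDuplicated(sample_ids))
    stop("validation error: duplicate sample id '",
         sample_ids[duplicated(sample_ids)][1], "'")
  rownames(counts) <- sample_ids
  colnames(counts) <- feature_ids
  if (min_total > 1) {
    low <- rowSums(counts) < min_total
    if (any(low)) {
      message("dropped ", sum(low), " sample(s) with total count < ",
              min_total)
      counts <- counts[!low, , drop = FALSE]
    }
    if (nrow(counts) == 0) stop("all samples fell below min_total")
  }
  study_table(study_id, counts, feature_level)
}

#' Attach sample metadata to a study table
#'
#' Metadata rows are matched by `sample_id`. Samples missing from the
#' metadata are dropped (with a message stating how many); metadata rows
#' without a matching sample are ignored (also reported).
#'
#' @param table A `study_table`.
#' @param meta A data frame, or path to a TSV, with columns `sample_id`,
#'   `diagnosis`, `site`, `subject_id`, `matched`, `region`.
#' @return The `study_table` with validated metadata attached.
#' @export
attach_metadata <- function(table, meta) {
  stopifnot(inherits(table, "study_table"))
  if (is.character(meta)) {
    meta <- read.table(meta, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE, comment.char = "#",
                       colClasses = "character")
  }
  need <- c("sample_id", "diagnosis", "site", "subject_id", "matched", "region")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols) > 0)
    stop("metadata missing column(s): ", paste(missing_cols, collapse = ", "))
  meta$matched <- as.logical(meta$matched)
  if (anyNA(meta$matched)) stop("matched column must be true/false")
  if ("study_id" %in% names(meta))
    meta <- meta[meta$study_id == table$study_id | meta$study_id == "", ,
                 drop = FALSE]
  keep <- rownames(table$counts) %in% meta$sample_id
  n_dropped <- sum(!keep)
  if (all(!keep)) stop("zero samples overlap between counts and metadata")
  if (n_dropped > 0)
    message("dropped ", n_dropped, " sample(s) without metadata")
  n_ignored <- sum(!(meta$sample_id %in% rownames(table$counts)))
  if (n_ignored > 0)
    message("ignored ", n_ignored, " metadata row(s) without samples")
  counts <- table$counts[keep, , drop = FALSE]
  meta <- meta[match(rownames(counts), meta$sample_id), , drop = FALSE]
  meta2 <- data.frame(
    sample_id = meta$sample_id, study_id = table$study_id,
    diagnosis = meta$diagnosis, site = meta$site,
    subject_id = meta$subject_id, matched = meta$matched,
    region = meta$region, stringsAsFactors = FALSE
  )
  rownames(meta2) <- NULL
  study_table(table$study_id, counts, table$feature_level, meta2)
}

#' Convert counts to per-sample relative abundances
#'
#' @param x A `study_table` or a samples-by-features count matrix.
#' @return A matrix of proportions; every row sums to one.
#' @export
to_relative_abundance <- function(x) {
  counts <- if (inherits(x, "study_table")) x$counts else as.matrix(x)
  totals <- rowSums(counts)
  if (any(totals <= 0))
    stop("zero-total sample(s): ",
         paste(rownames(counts)[totals <= 0], collapse = ", "))
  counts / totals
}

#' Harmonize taxon-level studies onto a shared feature namespace
#'
#' Reindexes every table onto the union of taxon labels, filling absent taxa
#' with explicit zeros. Matching is exact-string on the classifier's output
#' label; no fuzzy matching is attempted, because pooling across studies is
#' only meaningful for identical labels. OTU namespaces are study-specific by
#' construction and cannot be harmonized.
#'
#' @param studies List of `study_table` objects sharing
#'   `feature_level = "taxon"`.
#' @return A `meta_collection`: the reindexed studies plus the union
#'   namespace.
#' @export
harmonize <- function(studies) {
  stopifnot(length(studies) >= 1)
  levels <- unique(vapply(studies, `[[`, "", "feature_level"))
  if (length(levels) != 1)
    stop("mixed feature levels: ", paste(levels, collapse = ", "))
  if (levels != "taxon")
    stop("harmonization is defined for taxon-level tables only")
  union_ids <- unique(unlist(lapply(studies, `[[`, "feature_ids")))
  studies <- lapply(studies, function(s) {
    newc <- matrix(0, nrow(s$counts), length(union_ids),
                   dimnames = list(rownames(s$counts), union_ids))
    newc[, s$feature_ids] <- s$counts
    study_table(s$study_id, newc, s$feature_level,
                if (s$metadata_attached) s$meta else NULL)
  })
  names(studies) <- vapply(studies, `[[`, "", "study_id")
  structure(list(studies = studies, feature_level = levels,
                 feature_union = union_ids),
            class = "meta_collection")
}

#' Bundle studies that already share a namespace into a collection
#'
#' Lighter-weight sibling of [harmonize()] for OTU-level studies (whose
#' namespaces are intentionally per-study) or taxon tables already aligned.
#' @param studies List of `study_table` objects.
#' @return A `meta_collection`.
#' @export
as_meta_collection <- function(studies) {
  levels <- unique(vapply(studies, `[[`, "", "feature_level"))
  if (length(levels) != 1)
    stop("mixed feature levels: ", paste(levels, collapse = ", "))
  names(studies) <- vapply(studies, `[[`, "", "study_id")
  structure(list(studies = studies, feature_level = levels,
                 feature_union = unique(unlist(lapply(studies, `[[`,
                                                      "feature_ids")))),
            class = "meta_collection")
}

#' @method print meta_collection
#' @export
print.meta_collection <- function(x, ...) {
  cat(sprintf("<meta_collection> %d studies, %s level, %d features in union\n",
              length(x$studies), x$feature_level, length(x$feature_union)))
  for (s in x$studies) print(s)
  invisible(x)
}

#' Subset a collection's samples to one site
#' @param collection A `meta_collection`.
#' @param site `"feces"` or `"tissue"`.
#' @return A `meta_collection` containing only studies with samples at the
#'   site.
#' @export
subset_site <- function(collection, site) {
  site <- match.arg(site, SITE_LEVELS)
  kept <- list()
  for (s in collection$studies) {
    keep <- s$meta$site == site
    if (!any(keep)) next
    kept[[s$study_id]] <- study_table(
      s$study_id, s$counts[keep, , drop = FALSE], s$feature_level,
      s$meta[keep, , drop = FALSE])
  }
  if (length(kept) == 0) stop("no studies with site = ", site)
  structure(list(studies = kept, feature_level = collection$feature_level,
                 feature_union = collection$feature_union),
            class = "meta_collection")
}

# ---- writers -----------------------------------------------------------

result_header <- function(seed = NULL) {
  paste0("# crcmeta ", as.character(packageVersion("crcmeta")),
         if (!is.null(seed)) paste0(" seed=", seed),
         " orientation=samples-in-rows")
}

#' Write a result data frame as TSV with a commented provenance header
#' @param df Data frame.
#' @param path Output path.
#' @param seed Seed recorded in the header comment (optional).
#' @export
write_result_tsv <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(result_header(seed), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a study table in either on-disk dialect
#' @param table A `study_table`.
#' @param path Output path.
#' @param dialect `"tsv"` or `"mothur_shared"`.
#' @export
write_feature_table <- function(table, path,
                                dialect = c("tsv", "mothur_shared")) {
  dialect <- match.arg(dialect)
  counts <- table$counts
  if (dialect == "tsv") {
    df <- data.frame(sample_id = rownames(counts), counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    df <- data.frame(label = "0.03", Group = rownames(counts),
                     numOtus = ncol(counts), counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the per-sample metadata of a collection or study
#' @param x A `study_table` or `meta_collection`.
#' @param path Output path.
#' @export
write_metadata <- function(x, path) {
  meta <- if (inherits(x, "meta_collection")) {
    do.call(rbind, lapply(x$studies, `[[`, "meta"))
  } else {
    x$meta
  }
  rownames(meta) <- NULL
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a collection directory written by [write_collection()]
#' @param dir Directory containing `study_*.tsv` and `metadata.tsv`.
#' @param feature_level `"taxon"` or `"otu"`.
#' @param min_total Per-sample minimum total count filter.
#' @return A `meta_collection`.
#' @export
read_collection <- function(dir, feature_level = "taxon", min_total = 1) {
  files <- sort(list.files(dir, pattern = "^study_.*\\.tsv$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no study_*.tsv files in ", dir)
  meta_path <- file.path(dir, "metadata.tsv")
  if (!file.exists(meta_path)) stop("metadata.tsv not found in ", dir)
  meta <- read.table(meta_path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE, colClasses = "character")
  studies <- lapply(files, function(f) {
    sid <- sub("^study_(.*)\\.tsv$", "\\1", basename(f))
    tab <- read_feature_table(f, "tsv", study_id = sid,
                              feature_level = feature_level,
                              min_total = min_total)
    attach_metadata(tab, meta[meta$study_id == sid, , drop = FALSE])
  })
  if (feature_level == "taxon") harmonize(studies) else
    as_meta_collection(studies)
}

#' Write a collection to a directory (one TSV per study plus metadata)
#' @param collection A `meta_collection`.
#' @param dir Output directory (created if missing).
#' @export
write_collection <- function(collection, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in collection$studies)
    write_feature_table(s, file.path(dir, paste0("study_", s$study_id, ".tsv")))
  write_metadata(collection, file.path(dir, "metadata.tsv"))
  invisible(dir)
}
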