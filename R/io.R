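#' Read and validate an ASV count table with sample metadata
#'
#' Counts are tab-separated with samples as rows: column 1 holds the sample
#' identifier, the header row the ASV identifiers. Metadata is tab-separated
#' with columns `sample_id`, `individual`, `fraction`, `treatment`,
#' `replicate`; `fraction` must come from the closed vocabulary
#' Whole/HNA/LNA/BONCATpos/BONCATneg/PIpos/Sheath and `treatment` (when not
#' NA) from Control/Digoxin/Nizatidine/Glucose. Every sample in the count
#' table must have a metadata row.
#'
#' @param path path of the counts TSV.
#' @param metadata_path path of the metadata TSV.
#' @return list of class `count_table` with `counts` (integer matrix) and
#'   `metadata` (data.frame, one row per sample, same order).
#' @export
read_count_table <- function(path, metadata_path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 1) stopf("count table has no columns")
  counts <- as.matrix(raw[, -1, drop = FALSE])
  rownames(counts) <- as.character(raw[[1]])
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  validate_count_table(counts, meta)
}

#' @rdname read_count_table
#' @param counts samples x ASVs matrix.
#' @param metadata data.frame with the columns described above.
#' @export
validate_count_table <- function(counts, metadata) {
  if (anyDuplicated(rownames(counts)))
    stopf("duplicated sample identifiers in count table")
  storage_ok <- is.numeric(counts) && all(is.finite(counts)) &&
    all(counts >= 0) && all(counts == floor(counts))
  if (!storage_ok) stopf("counts must be non-negative integers")
  need <- c("sample_id", "individual", "fraction")
  miss <- setdiff(need, names(metadata))
  if (length(miss) > 0) stopf("metadata lacks column(s): %s",
                              paste(miss, collapse = ", "))
  if (!"treatment" %in% names(metadata)) metadata$treatment <- NA_character_
  if (!"replicate" %in% names(metadata)) metadata$replicate <- 1L
  absent <- setdiff(rownames(counts), metadata$sample_id)
  if (length(absent) > 0)
    stopf("sample(s) missing from metadata: %s",
          paste(utils::head(absent, 3), collapse = ", "))
  bad_f <- setdiff(unique(metadata$fraction), FRACTION_LEVELS)
  if (length(bad_f) > 0) stopf("unknown fraction label(s): %s",
                               paste(bad_f, collapse = ", "))
  bad_t <- setdiff(stats::na.omit(unique(metadata$treatment)), TREATMENT_LEVELS)
  if (length(bad_t) > 0) stopf("unknown treatment label(s): %s",
                               paste(bad_t, collapse = ", "))
  meta <- metadata[match(rownames(counts), metadata$sample_id), , drop = FALSE]
  rownames(meta) <- meta$sample_id
  structure(list(counts = counts, metadata = meta), class = "count_table")
}

#' Read a rooted Newick phylogeny for UniFrac
#'
#' Validates that every leaf is labelled and every edge has a non-negative
#' branch length. Leaves absent from `asv_ids` (when given) are pruned with a
#' warning, so the tree maps 1:1 onto count-table ASVs.
#'
#' @param path Newick file path.
#' @param asv_ids optional character vector of ASV identifiers to retain.
#' @return an `ape` `phylo` object.
#' @export
read_newick <- function(path, asv_ids = NULL) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stopf("malformed Newick: %s",
                                             conditionMessage(e)))
  if (is.null(tree)) stopf("malformed Newick file '%s'", path)
  if (any(is.na(tree$tip.label)) || any(tree$tip.label == ""))
    stopf("tree has unlabelled leaves")
  if (is.null(tree$edge.length)) stopf("tree lacks branch lengths")
  if (any(is.na(tree$edge.length)) || any(tree$edge.length < 0))
    stopf("tree has missing or negative branch lengths")
  if (!is.null(asv_ids)) {
    extra <- setdiff(tree$tip.label, asv_ids)
    if (length(extra) > 0) {
      warnf("pruning %d tree leaves absent from the count table", length(extra))
      tree <- ape::drop.tip(tree, extra)
    }
  }
  tree
}

#' Write analysis result tables
#'
#' Writes each element of `tables` as a TSV under `out_dir` (numeric columns
#' serialised to 6 significant digits for reproducible diffs) together with a
#' `run_log.txt` echoing the seed, package version and any config entries.
#'
#' @param tables named list of data.frames (or matrices).
#' @param out_dir output directory, created if needed.
#' @param seed,config optional provenance to record in the run log.
#' @return invisibly, the paths written.
#' @export
write_results <- function(tables, out_dir, seed = NULL, config = NULL) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory '%s'", out_dir)
  paths <- character(0)
  for (nm in names(tables)) {
    df <- as.data.frame(tables[[nm]])
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, digits = 6)
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(c(
    paste("timestamp:", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    paste("physofrac version:", as.character(utils::packageVersion("physofrac"))),
    paste("R version:", R.version.string),
    paste("seed:", seed %||% "unset"),
    if (!is.null(config)) paste0("config.", names(config), ": ",
                                 vapply(config, function(x)
                                   paste(format(x), collapse = " "),
                                   character(1)))
  ), log_path)
  invisible(c(paths, log_path))
}

#' Write a count table (and companion files) to TSV
#'
#' Inverse of [read_count_table()]: samples as rows, first column
#' `sample_id`, one header column per ASV.
#'
#' @param table a `count_table`.
#' @param counts_path,metadata_path output paths.
#' @return invisibly, the two paths.
#' @export
write_count_table <- function(table, counts_path, metadata_path) {
  df <- data.frame(sample_id = rownames(table$counts), table$counts,
                   check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(table$metadata, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts_path, metadata_path))
}

#' Write a simulated cohort bundle to a directory
#'
#' Emits `counts.tsv`, `metadata.tsv`, `taxonomy.tsv`, `tree.nwk`,
#' `cytometry.tsv` and `truth.tsv` (latent gate percentages per individual),
#' the files the analysis pipeline reads.
#'
#' @param cohort a `facs_cohort` from [simulate_cohort()].
#' @param out_dir output directory.
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_count_table(list(counts = cohort$counts, metadata = cohort$metadata),
                    file.path(out_dir, "counts.tsv"),
                    file.path(out_dir, "metadata.tsv"))
  utils::write.table(cohort$taxonomy, file.path(out_dir, "taxonomy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ape::write.tree(cohort$tree, file.path(out_dir, "tree.nwk"))
  utils::write.table(cohort$cytometry, file.path(out_dir, "cytometry.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- data.frame(individual = rownames(cohort$truth$pi),
                      signif(cohort$truth$pi, 6), check.names = FALSE)
  utils::write.table(truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
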