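#' Sheath-fluid decontamination
#'
#' Removes ASVs that carry reads in any sheath-fluid negative control but are
#' absent from every whole-community (unsorted) sample: such ASVs entered the
#' samples through the sorter's sheath fluid, not the community. Matching
#' ASVs are dropped from all samples, and the sheath controls themselves are
#' excluded from the returned table.
#'
#' @param table a `count_table` (counts + metadata).
#' @return list `(table, report)` where `report` is a `filter_report` row set
#'   recording rule, removed ASVs and reads removed per sample.
#' @export
remove_sheath_contaminants <- function(table) {
  meta <- table$metadata
  sheath <- meta$sample_id[meta$fraction == "Sheath"]
  whole <- meta$sample_id[meta$fraction == "Whole"]
  if (length(whole) == 0) stopf("decontamination requires Whole samples")
  if (length(sheath) == 0) {
    warnf("no Sheath samples present; decontamination skipped")
    return(list(table = table, report = filter_report("sheath", character(0),
                                                      table$counts * 0L)))
  }
  in_sheath <- colSums(table$counts[sheath, , drop = FALSE]) > 0
  in_whole <- colSums(table$counts[whole, , drop = FALSE]) > 0
  contam <- colnames(table$counts)[in_sheath & !in_whole]
  removed_reads <- table$counts[, contam, drop = FALSE]
  keep_samples <- setdiff(rownames(table$counts), sheath)
  counts <- table$counts[keep_samples, setdiff(colnames(table$counts), contam),
                         drop = FALSE]
  out <- validate_count_table(counts,
                              meta[meta$sample_id %in% keep_samples, ,
                                   drop = FALSE])
  list(table = out, report = filter_report("sheath_contaminants", contam,
                                           removed_reads))
}

#' Drop ASVs without a phylum-level assignment
#'
#' @param table a `count_table`.
#' @param taxonomy data.frame with columns `asv` and `phylum`; ASVs absent
#'   from it count as unassigned.
#' @return list `(table, report)`.
#' @export
drop_unassigned_phylum <- function(table, taxonomy) {
  phy <- taxonomy$phylum[match(colnames(table$counts), taxonomy$asv)]
  drop <- is.na(phy) | trimws(as.character(phy)) == ""
  subset_report(table, colnames(table$counts)[drop], "unassigned_phylum")
}

#' Prevalence filter
#'
#' Keeps an ASV iff it reaches at least `min_reads` reads in each of at least
#' `min_samples` samples (the per-sample reading of "a minimum of 6 reads in
#' at least 2 samples").
#'
#' @param table a `count_table`.
#' @param min_reads per-sample read threshold.
#' @param min_samples number of samples that must reach it.
#' @return list `(table, report)`.
#' @export
prevalence_filter <- function(table, min_reads = 6, min_samples = 2) {
  if (min_reads < 1 || min_samples < 1) stopf("thresholds must be >= 1")
  n_ok <- colSums(table$counts >= min_reads)
  drop <- colnames(table$counts)[n_ok < min_samples]
  subset_report(table, drop, "prevalence")
}

#' Remove explicitly named taxa
#'
#' Drops a caller-supplied list of ASV identifiers (e.g. taxa identified as
#' contaminants by inspection). Unknown identifiers are skipped with a
#' warning.
#'
#' @param table a `count_table`.
#' @param ids ASV identifiers to drop.
#' @return list `(table, report)`.
#' @export
remove_named_taxa <- function(table, ids) {
  unknown <- setdiff(ids, colnames(table$counts))
  if (length(unknown) > 0)
    warnf("%d identifier(s) not present; skipped", length(unknown))
  subset_report(table, intersect(ids, colnames(table$counts)), "named_taxa")
}

subset_report <- function(table, drop_ids, rule) {
  removed_reads <- table$counts[, drop_ids, drop = FALSE]
  counts <- table$counts[, setdiff(colnames(table$counts), drop_ids),
                         drop = FALSE]
  out <- list(counts = counts, metadata = table$metadata)
  class(out) <- "count_table"
  list(table = out, report = filter_report(rule, drop_ids, removed_reads))
}

filter_report <- function(rule, removed_ids, removed_reads) {
  structure(list(rule = rule, removed_asvs = removed_ids,
                 n_removed = length(removed_ids),
                 reads_removed_per_sample = rowSums(removed_reads)),
            class = "filter_report")
}

#' Apply the full filtering cascade
#'
#' Fixed order: sheath decontamination, unassigned-phylum removal, prevalence
#' filter, named-taxon removal. Reports reconcile read totals exactly.
#'
#' @param table a `count_table`.
#' @param taxonomy taxonomy data.frame (see [drop_unassigned_phylum()]).
#' @param min_reads,min_samples prevalence thresholds.
#' @param drop_ids explicit ASVs to remove last.
#' @param decontaminate set `FALSE` to skip the sheath rule.
#' @return list `(table, reports)` with one `filter_report` per applied rule.
#' @export
preprocess_counts <- function(table, taxonomy = NULL, min_reads = 6,
                              min_samples = 2, drop_ids = character(0),
                              decontaminate = TRUE) {
  reports <- list()
  if (decontaminate) {
    step <- remove_sheath_contaminants(table)
    table <- step$table; reports$sheath <- step$report
  }
  if (!is.null(taxonomy)) {
    step <- drop_unassigned_phylum(table, taxonomy)
    table <- step$table; reports$phylum <- step$report
  }
  step <- prevalence_filter(table, min_reads, min_samples)
  table <- step$table; reports$prevalence <- step$report
  if (length(drop_ids) > 0) {
    step <- remove_named_taxa(table, drop_ids)
    table <- step$table; reports$named <- step$report
  }
  list(table = table, reports = reports)
}

#' Variance-stabilising count transform
#'
#' Median-of-ratios size factors followed by a shifted log: the size factor
#' of sample `j` is the median over ASVs (restricted to ASVs with a nonzero
#' count in every sample) of `count_ij / geometric_mean_i`, and the
#' transformed value is `log2(count_ij / s_j + 1)`. When no ASV is nonzero in
#' all samples, size factors fall back to library size over mean library
#' size, with a warning.
#'
#' @param table a `count_table` or a samples x ASVs matrix.
#' @return samples x ASVs numeric matrix with attribute `size_factors`.
#' @export
vst_transform <- function(table) {
  counts <- if (inherits(table, "count_table")) table$counts else table
  if (nrow(counts) < 2) stopf("the transform needs at least 2 samples")
  log_gm <- colMeans(log(counts))          # -Inf where any sample has a zero
  usable <- is.finite(log_gm)
  if (any(usable)) {
    sf <- apply(counts[, usable, drop = FALSE], 1, function(row)
      stats::median(exp(log(row) - log_gm[usable])))
  } else {
    warnf("no ASV is nonzero in all samples; using library-size factors")
    libs <- rowSums(counts)
    sf <- libs / mean(libs)
  }
  out <- log2(sweep(counts, 1, sf, "/") + 1)
  attr(out, "size_factors") <- sf
  out
}

#' Rarefy samples to a fixed depth without replacement
#'
#' Subsamples each sample's reads to exactly `depth` without replacement
#' (via [vegan::rrarefy()]). Samples with fewer than `depth` total reads are
#' dropped with a warning.
#'
#' @param table a `count_table` or counts matrix.
#' @param depth target reads per sample.
#' @param seed integer seed.
#' @return rarefied counts matrix (possibly with fewer rows).
#' @export
rarefy_counts <- function(table, depth = 10534, seed = NULL) {
  counts <- if (inherits(table, "count_table")) table$counts else table
  if (depth < 1) stopf("`depth` must be >= 1")
  tot <- rowSums(counts)
  keep <- tot >= depth
  if (!any(keep)) stopf("every sample is below the rarefaction depth")
  if (any(!keep))
    warnf("dropping %d sample(s) below depth %d", sum(!keep), depth)
  with_seed(seed, vegan::rrarefy(counts[keep, , drop = FALSE], depth))
}
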