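#' Fraction proportions from cytometry gate counts
#'
#' Converts per-sample gate event tallies to percentages of total quantified
#' cells. The HNA and LNA gates arise from one bimodal SYBR split, so when
#' both are present they are expressed as shares of their sum and complement
#' to exactly 100; when only HNA is tallied, LNA is its complement.
#'
#' @param cytometry data.frame with columns `sample_id`, `gate`, `events`,
#'   `total_events`.
#' @return data.frame: sample_id plus one percentage column per gate.
#' @export
fraction_proportions <- function(cytometry) {
  need <- c("sample_id", "gate", "events", "total_events")
  miss <- setdiff(need, names(cytometry))
  if (length(miss) > 0) stopf("cytometry lacks column(s): %s",
                              paste(miss, collapse = ", "))
  if (any(cytometry$total_events <= 0)) stopf("zero total events")
  if (any(cytometry$events > cytometry$total_events))
    stopf("gate events exceed total events")
  ids <- unique(cytometry$sample_id)
  ev <- stats::xtabs(events ~ factor(sample_id, levels = ids) + gate,
                     data = cytometry)
  tot <- cytometry$total_events[match(ids, cytometry$sample_id)]
  pct <- as.data.frame.matrix(100 * ev / tot)
  if (all(c("HNA", "LNA") %in% names(pct))) {
    hna <- ev[, "HNA"] / (ev[, "HNA"] + ev[, "LNA"]) * 100
    pct$HNA <- as.numeric(hna)
    pct$LNA <- 100 - as.numeric(hna)
  } else if ("HNA" %in% names(pct)) {
    pct$LNA <- 100 - pct$HNA
  }
  data.frame(sample_id = ids, pct, row.names = NULL)
}

#' Correlations between fraction proportions
#'
#' Pearson correlations (with t-based p-values) between per-individual gate
#' percentages; by default the two contrasts of interest, HNA vs PI+ and
#' HNA vs BONCAT+.
#'
#' @param props data.frame from [fraction_proportions()] (or any data.frame
#'   with the gate columns).
#' @param pairs 2-column character matrix of gate pairs to test.
#' @return data.frame: gate1, gate2, r, p, n.
#' @export
proportion_correlations <- function(props,
                                    pairs = rbind(c("HNA", "PIpos"),
                                                  c("HNA", "BONCATpos"))) {
  if (nrow(props) < 3) stopf("need at least 3 individuals")
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    pt <- pearson_test(props[[pairs[k, 1]]], props[[pairs[k, 2]]])
    data.frame(gate1 = pairs[k, 1], gate2 = pairs[k, 2],
               r = pt$r, p = pt$p, n = pt$n)
  })
  do.call(rbind, rows)
}

#' Partition taxa into core, unique and shared
#'
#' Presence is called per individual from its whole-community (unsorted)
#' sample: at least one read. Core taxa occur in at least `threshold`
#' individuals, unique taxa in exactly one, shared taxa are the remainder.
#' Percentages of the ASV total are reported to one decimal
#' (round-half-even).
#'
#' @param table a `count_table`; only `Whole` samples are used unless
#'   `pool_all_samples` is set, in which case presence is pooled over every
#'   sample of an individual.
#' @param threshold individuals required for core membership (>= 2).
#' @param pool_all_samples call presence from all of an individual's samples.
#' @return list of class `core_partition`: `threshold`, `n_individuals`,
#'   `core`, `unique`, `shared` (ASV id vectors), `n_present` (named
#'   per-ASV prevalence), `summary` (data.frame with counts and percentages).
#' @export
partition_core <- function(table, threshold = NULL, pool_all_samples = FALSE) {
  meta <- table$metadata
  sel <- if (pool_all_samples) meta$fraction != "Sheath" else
    meta$fraction == "Whole"
  if (!any(sel)) stopf("no Whole samples to call presence from")
  ind <- meta$individual[sel]
  counts <- table$counts[meta$sample_id[sel], , drop = FALSE]
  pres <- rowsum((counts > 0) * 1, ind) > 0
  n_ind <- nrow(pres)
  if (is.null(threshold)) threshold <- n_ind
  if (threshold < 2) stopf("`threshold` below 2 merges core and unique semantics")
  if (threshold > n_ind) stopf("`threshold` exceeds the number of individuals")
  n_present <- colSums(pres)
  core <- names(n_present)[n_present >= threshold]
  uniq <- names(n_present)[n_present == 1]
  shared <- setdiff(names(n_present), c(core, uniq))
  total <- ncol(counts)
  summary <- data.frame(
    category = c("core", "unique", "shared"),
    n = c(length(core), length(uniq), length(shared)),
    percent = round(100 * c(length(core), length(uniq), length(shared)) / total, 1)
  )
  structure(list(threshold = threshold, n_individuals = n_ind, core = core,
                 unique = uniq, shared = shared, n_present = n_present,
                 summary = summary),
            class = "core_partition")
}

#' @export
print.core_partition <- function(x, ...) {
  cat(sprintf("<core_partition> threshold %d/%d individuals\n",
              x$threshold, x$n_individuals))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Core/unique/shared enrichment of sorted fractions
#'
#' Sums each sample's reads over the core, unique and shared ASV sets and
#' tests, per sorted fraction and per category, whether the category's
#' proportion differs from the whole community (beta-binomial likelihood
#' ratio tests of category reads out of library size, fraction vs Whole).
#' q-values adjust each category family across fractions.
#'
#' @param table a `count_table` containing Whole and sorted samples.
#' @param partition a `core_partition` computed on the whole community.
#' @param fractions sorted fractions to test (default: all present).
#' @return list with `category_counts` (long data.frame of per-sample sums)
#'   and `tests` (fraction, category, mu in fraction and in Whole, p, q,
#'   direction).
#' @export
fraction_core_enrichment <- function(table, partition, fractions = NULL) {
  meta <- table$metadata
  fractions <- fractions %||%
    setdiff(intersect(unique(meta$fraction), SORTED_FRACTIONS), "Whole")
  sets <- list(core = partition$core, unique = partition$unique,
               shared = partition$shared)
  totals <- rowSums(table$counts)
  cat_counts <- sapply(sets, function(ids)
    rowSums(table$counts[, intersect(ids, colnames(table$counts)),
                         drop = FALSE]))
  long <- data.frame(sample_id = rep(rownames(cat_counts), 3),
                     fraction = rep(meta$fraction, 3),
                     category = rep(names(sets), each = nrow(cat_counts)),
                     reads = as.vector(cat_counts),
                     total = rep(totals, 3), row.names = NULL)
  whole_ids <- meta$sample_id[meta$fraction == "Whole"]
  rows <- list()
  for (f in fractions) {
    f_ids <- meta$sample_id[meta$fraction == f]
    if (length(f_ids) < 2 || length(whole_ids) < 2) next
    for (cat in names(sets)) {
      if (length(sets[[cat]]) == 0) {
        rows[[paste(f, cat)]] <- data.frame(fraction = f, category = cat,
                                            mu_fraction = NA, mu_whole = NA,
                                            p = NA, direction = NA)
        next
      }
      ids <- c(f_ids, whole_ids)
      grp <- factor(rep(c(f, "Whole"), c(length(f_ids), length(whole_ids))),
                    levels = c(f, "Whole"))
      fit <- fit_betabinom_test(cat_counts[ids, cat], totals[ids], grp)
      rows[[paste(f, cat)]] <- data.frame(
        fraction = f, category = cat,
        mu_fraction = fit[[paste0("mu.", f)]],
        mu_whole = fit[["mu.Whole"]],
        p = fit$p_abundance,
        direction = ifelse(fit[[paste0("mu.", f)]] > fit[["mu.Whole"]],
                           "enriched", "depleted"))
    }
  }
  tests <- do.call(rbind, c(rows, make.row.names = FALSE))
  tests$q <- stats::ave(tests$p, tests$category,
                        FUN = function(p) bh_adjust(p))
  list(category_counts = long, tests = tests)
}

#' Between-individual distances per fraction
#'
#' For each fraction, collects the distances between samples of distinct
#' individuals (one sample per individual per fraction), the inputs of the
#' Kruskal-Wallis/Dunn comparison of inter-individual similarity.
#'
#' @param D symmetric distance matrix over samples.
#' @param metadata per-sample data.frame (`sample_id`, `individual`,
#'   `fraction`).
#' @param fractions fractions to include (default: all non-Sheath).
#' @return long data.frame: fraction, individual1, individual2, distance.
#' @export
interindividual_distance_groups <- function(D, metadata, fractions = NULL) {
  D <- as.matrix(D)
  fractions <- fractions %||% setdiff(unique(metadata$fraction), "Sheath")
  rows <- list()
  for (f in fractions) {
    sub <- metadata[metadata$fraction == f &
                      metadata$sample_id %in% rownames(D), , drop = FALSE]
    if (anyDuplicated(sub$individual))
      stopf("more than one '%s' sample per individual", f)
    if (nrow(sub) < 2) next
    cmb <- utils::combn(nrow(sub), 2)
    rows[[f]] <- data.frame(
      fraction = f,
      individual1 = sub$individual[cmb[1, ]],
      individual2 = sub$individual[cmb[2, ]],
      distance = D[cbind(sub$sample_id[cmb[1, ]], sub$sample_id[cmb[2, ]])])
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
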