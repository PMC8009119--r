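#' Simulate a complete sorted-community cohort
#'
#' Composes the generator stages into one reproducible bundle: a phylogeny
#' with phylum-labelled clades (plus Pseudomonas-like contaminant tips), a
#' core/unique-structured abundance matrix, copula-drawn cytometric fraction
#' proportions, per-individual calibrated gate propensities, FACS sorting
#' with gate-error leakage, and multinomial 16S sequencing with sheath-fluid
#' contamination and per-day sheath controls. Identical `config` (including
#' its `seed`) always yields an identical bundle.
#'
#' @param config a [sim_config()].
#' @return an object of class `facs_cohort`: list with elements `counts`
#'   (samples x ASVs), `metadata`, `taxonomy` (data.frame: asv, kingdom,
#'   phylum, genus), `tree` (`phylo` over all ASVs incl. contaminants),
#'   `cytometry` (sample_id, gate, events, total_events), `abundance`,
#'   `theta_logit`, `delta`, `pool` (the `sorted_pool`), and `truth`
#'   (latent proportions, contaminant ids, purity, taxon status).
#' @export
simulate_cohort <- function(config = sim_config()) {
  seed <- config$seed
  n_c <- config$n_contaminant_asvs
  full_tree <- simulate_tree(config$n_taxa + n_c, seed = child_seed(seed, 1),
                             phylum_labels = config$phylum_labels,
                             phylum_weights = config$phylum_weights)
  phylum <- attr(full_tree, "phylum")
  # the last clade block is Proteobacteria-like: its final tips become the
  # sheath contaminants, absent from every whole-community sample
  old_ids <- sprintf("ASV%04d", config$n_taxa + seq_len(n_c))
  contam_ids <- sprintf("CONTAM%02d", seq_len(n_c))
  full_tree$tip.label[match(old_ids, full_tree$tip.label)] <- contam_ids
  names(phylum)[match(old_ids, names(phylum))] <- contam_ids
  attr(full_tree, "phylum") <- phylum

  ab <- simulate_abundances(config, seed = child_seed(seed, 2))
  status <- attr(ab, "status")
  pi_mat <- draw_fraction_proportions(config, seed = child_seed(seed, 3))
  rownames(pi_mat) <- rownames(ab)
  theta_logit <- build_propensity_logits(config, phylum[colnames(ab)], status,
                                         seed = child_seed(seed, 4))
  delta <- calibrate_cohort(ab, theta_logit, pi_mat)

  cohort <- list(abundance = ab, theta_logit = theta_logit, delta = delta)
  pool <- simulate_sorting(cohort, config, seed = child_seed(seed, 5))
  seqd <- simulate_sequencing(pool, cohort, config, seed = child_seed(seed, 6),
                              contaminant_ids = contam_ids)

  taxonomy <- data.frame(
    asv = names(phylum),
    kingdom = "Bacteria",
    phylum = unname(phylum),
    genus = ifelse(names(phylum) %in% contam_ids, "Pseudomonas",
                   paste0("g__", substr(unname(phylum), 1, 4), "_",
                          cumsum(!duplicated(names(phylum))) %/% 10 + 1)),
    stringsAsFactors = FALSE
  )
  cyto <- cytometry_from_pi(pi_mat)

  structure(list(
    counts = seqd$counts, metadata = seqd$metadata, taxonomy = taxonomy,
    tree = full_tree, cytometry = cyto,
    abundance = ab, theta_logit = theta_logit, delta = delta, pool = pool,
    truth = list(pi = pi_mat, contaminant_ids = contam_ids,
                 purity = pool$purity, status = status),
    config = config
  ), class = "facs_cohort")
}

# per-individual, per-gate calibrated logit offsets
calibrate_cohort <- function(ab, theta_logit, pi_mat) {
  delta <- matrix(0, nrow(ab), 3,
                  dimnames = list(rownames(ab), GATE_FRACTIONS))
  for (i in rownames(ab)) {
    for (g in GATE_FRACTIONS) {
      delta[i, g] <- calibrate_propensities(ab[i, ],
                                            inv_logit(theta_logit[, g]),
                                            pi_mat[i, g])
    }
  }
  delta
}

#' Cytometry gate counts from latent fraction percentages
#'
#' Converts a matrix of per-sample gate percentages into the long
#' event-count form of a cytometry table (the instrument quantifies a fixed
#' number of cells per sample); inverse of [fraction_proportions()] up to
#' rounding.
#'
#' @param pi_mat samples x gates percentage matrix with row names.
#' @param total_events quantified cells per sample.
#' @return data.frame: sample_id, gate, events, total_events.
#' @export
cytometry_from_pi <- function(pi_mat, total_events = 100000L) {
  gates <- colnames(pi_mat)
  data.frame(
    sample_id = rep(rownames(pi_mat), each = length(gates)),
    gate = rep(gates, times = nrow(pi_mat)),
    events = as.integer(round(t(pi_mat) / 100 * total_events)),
    total_events = total_events,
    stringsAsFactors = FALSE
  )
}

#' Simulate xenobiotic incubation replicates for one individual
#'
#' Re-runs the cytometry, sorting and sequencing stages for each
#' treatment x replicate of an in vitro incubation experiment. Replicate gate
#' proportions are drawn from normal distributions with the treatment's
#' target means and replicate SDs (truncated to `[0, 100]`), the propensity
#' offsets are re-calibrated to each replicate's proportions, and the full
#' sorting + sequencing pipeline is re-run per replicate.
#'
#' @param cohort a `facs_cohort`; the individual's abundance profile and
#'   taxon propensities are taken from it.
#' @param config a [sim_config()].
#' @param individual which cohort individual to incubate (row name or index).
#' @param effects treatment parameterisation as from [treatment_defaults()];
#'   defaults to `config$treatment_effects` or `treatment_defaults(1)`.
#' @param seed integer seed.
#' @return list with `counts`, `metadata` (treatment and replicate filled
#'   in), `proportions` (a data.frame of drawn gate percentages per
#'   treatment x replicate) and `cytometry`.
#' @export
simulate_treatments <- function(cohort, config = cohort$config,
                                individual = 1,
                                effects = config$treatment_effects %||%
                                  treatment_defaults(1),
                                seed = config$seed) {
  if (is.numeric(individual)) individual <- rownames(cohort$abundance)[individual]
  if (!"Control" %in% names(effects)) stopf("treatments must include Control")
  bad <- setdiff(names(effects), TREATMENT_LEVELS)
  if (length(bad) > 0) stopf("unknown treatment label: %s", bad[1])
  ab <- cohort$abundance[individual, , drop = FALSE]
  counts_list <- list(); meta_list <- list(); prop_list <- list()
  k <- 0
  for (tr in names(effects)) {
    for (rep_i in seq_len(config$n_replicates)) {
      k <- k + 1
      s <- child_seed(seed, 100 + k)
      pi_rep <- with_seed(s, draw_treated_pi(effects[[tr]]))
      delta <- matrix(0, 1, 3, dimnames = list(individual, GATE_FRACTIONS))
      for (g in GATE_FRACTIONS)
        delta[1, g] <- calibrate_propensities(ab[1, ],
                                              inv_logit(cohort$theta_logit[, g]),
                                              pi_rep[g])
      sub <- list(abundance = ab, theta_logit = cohort$theta_logit,
                  delta = delta)
      pool <- simulate_sorting(sub, config, seed = child_seed(s, 1))
      seqd <- simulate_sequencing(pool, sub, config, seed = child_seed(s, 2))
      tag <- sprintf("%s_%s_r%d", individual, tr, rep_i)
      rownames(seqd$counts) <- paste0(tag, "_", seqd$metadata$fraction)
      seqd$metadata$sample_id <- rownames(seqd$counts)
      seqd$metadata$treatment <- tr
      seqd$metadata$replicate <- rep_i
      counts_list[[tag]] <- seqd$counts
      meta_list[[tag]] <- seqd$metadata
      prop_list[[tag]] <- data.frame(individual = individual, treatment = tr,
                                     replicate = rep_i, t(pi_rep),
                                     stringsAsFactors = FALSE)
    }
  }
  props <- do.call(rbind, prop_list)
  rownames(props) <- NULL
  props$LNA <- 100 - props$HNA
  pim <- as.matrix(props[, c("HNA", "LNA", "BONCATpos", "PIpos")])
  rownames(pim) <- sprintf("%s_%s_r%d", props$individual, props$treatment,
                           props$replicate)
  list(counts = do.call(rbind, counts_list),
       metadata = do.call(rbind, c(meta_list, make.row.names = FALSE)),
       proportions = props,
       cytometry = cytometry_from_pi(pim))
}

# truncated-normal replicate gate percentages for one treatment arm
draw_treated_pi <- function(arm) {
  out <- numeric(3); names(out) <- GATE_FRACTIONS
  for (g in GATE_FRACTIONS) {
    x <- stats::rnorm(1, arm$means[[g]], arm$sds[[g]])
    while (x < 0 || x > 100) x <- stats::rnorm(1, arm$means[[g]], arm$sds[[g]])
    out[g] <- x
  }
  out
}

#' @export
print.facs_cohort <- function(x, ...) {
  cat("<facs_cohort>\n")
  cat(sprintf("  %d samples x %d ASVs (%d contaminant)\n",
              nrow(x$counts), ncol(x$counts),
              length(x$truth$contaminant_ids)))
  cat(sprintf("  %d individuals, fractions: %s\n",
              nrow(x$abundance),
              paste(unique(x$metadata$fraction), collapse = ", ")))
  invisible(x)
}
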