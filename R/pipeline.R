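#' Run the full sorted-fraction analysis
#'
#' Orchestrates the end-to-end analysis of a cohort of whole and sorted
#' samples: sheath decontamination and filtering, cytometric proportions and
#' their correlations, the variance-stabilising transform, weighted UniFrac
#' distances, PCoA, PERMANOVA by individual and by physiology, pairwise
#' PERMANOVA with FDR, the core/unique/shared partition with per-fraction
#' enrichment, the Kruskal-Wallis/Dunn comparison of between-individual
#' distances, rarefied Shannon diversity and (optionally) per-taxon
#' beta-binomial tests.
#'
#' @param cohort either a `facs_cohort` from [simulate_cohort()] or a list
#'   with `counts`, `metadata`, `taxonomy`, `tree`, `cytometry` (e.g. read
#'   from files).
#' @param n_perm PERMANOVA permutations.
#' @param rarefy_depth depth for alpha diversity; samples below it are
#'   dropped.
#' @param core_threshold individuals required for core membership (default:
#'   all individuals).
#' @param taxon_tests run the per-taxon beta-binomial scan (slowest stage).
#' @param drop_ids ASVs to remove by name after the standard filters.
#' @param seed integer seed for permutations and rarefaction.
#' @param out_dir if given, results are written as TSVs via
#'   [write_results()].
#' @return list of class `physofrac_report` with elements `filtered`,
#'   `reports`, `proportions`, `correlations`, `distances`, `pcoa`,
#'   `permanova_individual`, `permanova_physiology`, `pairwise_physiology`,
#'   `core_partition`, `core_enrichment`, `distance_groups`,
#'   `distance_kruskal`, `distance_dunn`, `alpha`, and (optionally)
#'   `taxon_tests`.
#' @export
run_full <- function(cohort, n_perm = 999, rarefy_depth = 10534,
                     core_threshold = NULL, taxon_tests = FALSE,
                     drop_ids = character(0), seed = 1, out_dir = NULL) {
  table <- validate_count_table(cohort$counts, cohort$metadata)
  pp <- preprocess_counts(table, taxonomy = cohort$taxonomy,
                          drop_ids = drop_ids)
  filtered <- pp$table
  meta <- filtered$metadata

  props <- fraction_proportions(cohort$cytometry)
  corrs <- proportion_correlations(props)

  vst <- vst_transform(filtered)
  tree <- read_newick_obj(cohort$tree, colnames(filtered$counts))
  D <- distance_matrix(filtered, "weighted_unifrac", tree = tree)
  ord <- pcoa(D, n_axes = 2)

  pm_ind <- permanova(D, meta$individual, n_perm = n_perm,
                      seed = child_seed(seed, 1))
  pm_phys <- permanova(D, meta$fraction, n_perm = n_perm,
                       seed = child_seed(seed, 2))
  pw_phys <- pairwise_permanova(D, meta$fraction, n_perm = n_perm,
                                seed = child_seed(seed, 3))

  part <- partition_core(filtered, threshold = core_threshold)
  enrich <- fraction_core_enrichment(filtered, part)

  dgroups <- interindividual_distance_groups(D, meta)
  kw <- kruskal_wallis(dgroups$distance, dgroups$fraction)
  dunn <- dunn_posthoc(dgroups$distance, dgroups$fraction)

  alpha <- tryCatch(alpha_diversity(filtered, depth = rarefy_depth,
                                    seed = child_seed(seed, 4)),
                    error = function(e) {
                      warnf("alpha diversity skipped: %s", conditionMessage(e))
                      NULL
                    })

  out <- list(filtered = filtered, reports = pp$reports, vst = vst,
              proportions = props, correlations = corrs, distances = D,
              pcoa = ord, permanova_individual = pm_ind,
              permanova_physiology = pm_phys, pairwise_physiology = pw_phys,
              core_partition = part, core_enrichment = enrich,
              distance_groups = dgroups, distance_kruskal = kw,
              distance_dunn = dunn, alpha = alpha, seed = seed)
  if (taxon_tests)
    out$taxon_tests <- taxa_betabinom_tests(filtered$counts, meta$fraction)
  class(out) <- "physofrac_report"

  if (!is.null(out_dir)) {
    tables <- list(
      proportions = props, correlations = corrs,
      distances = data.frame(sample_id = rownames(D), D, check.names = FALSE),
      pcoa = data.frame(sample_id = rownames(ord$coordinates),
                        ord$coordinates),
      permanova = rbind(cbind(model = "individual", pm_ind),
                        cbind(model = "physiology", pm_phys)),
      pairwise_permanova = pw_phys,
      core_partition = data.frame(asv = names(part$n_present),
                                  n_individuals_present = part$n_present,
                                  category = ifelse(
                                    names(part$n_present) %in% part$core, "core",
                                    ifelse(names(part$n_present) %in% part$unique,
                                           "unique", "shared"))),
      core_enrichment = enrich$tests,
      distance_groups = dgroups,
      dunn = dunn
    )
    if (!is.null(alpha)) tables$alpha <- alpha
    if (taxon_tests) tables$taxa_tests <- out$taxon_tests
    write_results(tables, out_dir, seed = seed)
  }
  out
}

# accept either a phylo object or a Newick path
read_newick_obj <- function(tree, asv_ids) {
  if (inherits(tree, "phylo")) {
    extra <- setdiff(tree$tip.label, asv_ids)
    if (length(extra) > 0) tree <- ape::drop.tip(tree, extra)
    return(tree)
  }
  read_newick(tree, asv_ids)
}

#' Xenobiotic incubation analysis for one individual
#'
#' Mirrors the treatment-experiment design: simulates (or accepts) replicate
#' incubations under Control/Digoxin/Nizatidine/Glucose, computes weighted
#' UniFrac distances over all fraction x treatment x replicate samples, and
#' reports an effect-size table with one PERMANOVA model per row --
#' physiology alone, treatment alone, and treatment nested within physiology
#' (the physiology x treatment cell model) -- plus per-fraction one-way
#' ANOVAs of gate proportions against the control with FDR correction.
#'
#' @param cohort a `facs_cohort`.
#' @param config a [sim_config()].
#' @param individual cohort individual to incubate.
#' @param effects treatment parameterisation (see [treatment_defaults()]).
#' @param n_perm PERMANOVA permutations.
#' @param seed integer seed.
#' @return list with `treated` (the simulated bundle), `effect_table`
#'   (model, df, R2, F, p), `nested` (the sequential two-term fit) and
#'   `proportion_tests` (per-gate ANOVA vs control).
#' @export
run_xenobiotic <- function(cohort, config = cohort$config, individual = 1,
                           effects = config$treatment_effects %||%
                             treatment_defaults(1),
                           n_perm = 999, seed = config$seed) {
  tr <- simulate_treatments(cohort, config, individual = individual,
                            effects = effects, seed = seed)
  meta <- tr$metadata
  keep <- meta$fraction %in% c("Whole", SORTED_FRACTIONS)
  counts <- tr$counts[meta$sample_id[keep], , drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  tree <- read_newick_obj(cohort$tree, colnames(counts))
  D <- distance_matrix(counts, "weighted_unifrac", tree = tree)

  pm_phys <- permanova(D, meta$fraction, n_perm = n_perm,
                       seed = child_seed(seed, 11))
  pm_treat <- permanova(D, meta$treatment, n_perm = n_perm,
                        seed = child_seed(seed, 12))
  cells <- interaction(meta$fraction, meta$treatment, drop = TRUE)
  pm_nested <- permanova(D, cells, n_perm = n_perm,
                         seed = child_seed(seed, 13))
  nested_seq <- nested_permanova(D, meta$fraction, meta$treatment,
                                 n_perm = n_perm, seed = child_seed(seed, 14))
  effect_table <- data.frame(
    model = c("Physiology", "Treatment", "Treatment %in% Physiology"),
    df = c(pm_phys$df[1], pm_treat$df[1], pm_nested$df[1]),
    R2 = c(pm_phys$R2[1], pm_treat$R2[1], pm_nested$R2[1]),
    F = c(pm_phys$F[1], pm_treat$F[1], pm_nested$F[1]),
    p = c(pm_phys$p[1], pm_treat$p[1], pm_nested$p[1]))

  gates <- c("HNA", "LNA", "BONCATpos", "PIpos")
  prop_tests <- lapply(gates, function(g) {
    res <- anova_vs_control(tr$proportions[[g]], tr$proportions$treatment)
    cbind(gate = g, anova_F = res$anova$F, anova_p = res$anova$p,
          res$vs_control)
  })
  list(treated = tr, effect_table = effect_table, nested = nested_seq,
       proportion_tests = do.call(rbind, prop_tests))
}
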