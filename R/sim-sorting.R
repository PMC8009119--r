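# Propensity construction and the sorting / sequencing stages of the
# synthetic cohort generator.

# Per-taxon logit-scale gate propensities shared across individuals:
# baseline + phylum offset + core/unique offsets (HNA gate) + taxon noise.
build_propensity_logits <- function(config, phylum, status, seed) {
  n_t <- length(phylum)
  with_seed(seed, {
    lt <- matrix(rep(logit(config$propensity_base[GATE_FRACTIONS]), each = n_t),
                 n_t, 3, dimnames = list(names(phylum), GATE_FRACTIONS))
    offs <- config$phylum_logit_offsets
    known <- phylum %in% rownames(offs)
    lt[known, ] <- lt[known, ] + offs[phylum[known], GATE_FRACTIONS]
    # active core vs transient unique taxa: an HNA-gate contrast
    lt[status == "core", "HNA"] <- lt[status == "core", "HNA"] +
      config$core_logit_offset
    lt[status == "unique", "HNA"] <- lt[status == "unique", "HNA"] +
      config$unique_logit_offset
    lt + matrix(stats::rnorm(n_t * 3, 0, config$propensity_noise_sd), n_t, 3)
  })
}

# theta for any sorted fraction from the gate logits and calibrated offsets;
# LNA and BONCATneg are the complements of their gate.
fraction_theta <- function(theta_logit, delta, fraction) {
  gate <- switch(fraction,
    HNA = "HNA", LNA = "HNA",
    BONCATpos = "BONCATpos", BONCATneg = "BONCATpos",
    PIpos = "PIpos",
    stopf("unknown sorted fraction '%s'", fraction))
  th <- inv_logit(theta_logit[, gate] + delta[gate])
  if (fraction %in% c("LNA", "BONCATneg")) 1 - th else th
}

#' Simulate FACS sorting of physiological fractions
#'
#' For every individual and sorted fraction, draws `sort_events` events. Each
#' event is, with probability `1 - gate_error`, a cell from the in-fraction
#' taxon distribution (abundance weighted by gate propensity) and otherwise a
#' leaked cell from the complement distribution; the number of truly in-gate
#' events is binomial. Taxon tallies and the latent true/leaked split are
#' both recorded, so re-acquired purity can be measured against the
#' configured gate error.
#'
#' @param cohort a `facs_cohort` as built by [simulate_cohort()] (or its
#'   internal pieces: `abundance`, `theta_logit`, `delta`).
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param fractions sorted fractions to draw; defaults to all five gates.
#' @param individuals individuals to sort; defaults to all.
#' @return a `sorted_pool`: list with `tallies` (taxa x fraction x individual
#'   integer array), `true_in` (individual x fraction count of truly in-gate
#'   events) and `purity` (`true_in / sort_events`).
#' @export
simulate_sorting <- function(cohort, config, seed = config$seed,
                             fractions = SORTED_FRACTIONS,
                             individuals = rownames(cohort$abundance)) {
  ab <- cohort$abundance
  n_t <- ncol(ab)
  tallies <- array(0L, c(n_t, length(fractions), length(individuals)),
                   dimnames = list(colnames(ab), fractions, individuals))
  true_in <- matrix(0L, length(individuals), length(fractions),
                    dimnames = list(individuals, fractions))
  with_seed(seed, {
    for (i in individuals) {
      for (f in fractions) {
        th <- fraction_theta(cohort$theta_logit, cohort$delta[i, ], f)
        p_in <- ab[i, ] * th
        p_out <- ab[i, ] * (1 - th)
        if (sum(p_in) <= 0) stopf("fraction '%s' has zero in-gate mass", f)
        ge <- config$gate_error[[f]]
        n_true <- stats::rbinom(1, config$sort_events, 1 - ge)
        ev <- stats::rmultinom(1, n_true, p_in)[, 1] +
          stats::rmultinom(1, config$sort_events - n_true, p_out)[, 1]
        tallies[, f, i] <- ev
        true_in[i, f] <- n_true
      }
    }
  })
  structure(list(tallies = tallies, true_in = true_in,
                 purity = true_in / config$sort_events,
                 sort_events = config$sort_events),
            class = "sorted_pool")
}

#' Simulate 16S sequencing of whole and sorted samples
#'
#' Every sample receives `seq_depth` reads drawn multinomially from its taxon
#' proportions (whole-community abundance for Whole samples, sorted tallies
#' for sorted fractions). Sorted samples additionally carry sheath-fluid
#' contamination: a total drawn uniformly from `sheath_read_range`, spread
#' multinomially over the contaminant ASVs, which never occur in Whole
#' samples. One sheath-fluid negative control per sort day (= per individual)
#' contains only contaminant reads.
#'
#' @param pool a `sorted_pool` from [simulate_sorting()].
#' @param cohort the `facs_cohort` the pool was sorted from.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param contaminant_ids ASV identifiers of the sheath contaminants.
#' @return list with `counts` (samples x ASVs integer matrix, contaminant
#'   columns included) and `metadata` (data.frame: sample_id, individual,
#'   fraction, treatment, replicate).
#' @export
simulate_sequencing <- function(pool, cohort, config, seed = config$seed,
                                contaminant_ids = sprintf("CONTAM%02d",
                                  seq_len(config$n_contaminant_asvs))) {
  if (config$seq_depth <= 0) stopf("`seq_depth` must be positive")
  individuals <- rownames(cohort$abundance)
  fractions <- dimnames(pool$tallies)[[2]]
  taxa <- c(colnames(cohort$abundance), contaminant_ids)
  samples <- c(
    paste0(individuals, "_Whole"),
    as.vector(outer(individuals, fractions, paste, sep = "_")),
    paste0("Sheath_", individuals)
  )
  counts <- matrix(0L, length(samples), length(taxa),
                   dimnames = list(samples, taxa))
  meta <- data.frame(
    sample_id = samples,
    individual = c(individuals, rep(individuals, times = length(fractions)),
                   individuals),
    fraction = c(rep("Whole", length(individuals)),
                 rep(fractions, each = length(individuals)),
                 rep("Sheath", length(individuals))),
    treatment = NA_character_, replicate = 1L,
    stringsAsFactors = FALSE
  )
  rng <- config$sheath_read_range
  n_c <- length(contaminant_ids)
  with_seed(seed, {
    for (i in individuals) {
      counts[paste0(i, "_Whole"), colnames(cohort$abundance)] <-
        stats::rmultinom(1, config$seq_depth, cohort$abundance[i, ])[, 1]
      for (f in fractions) {
        s <- paste0(i, "_", f)
        counts[s, colnames(cohort$abundance)] <-
          stats::rmultinom(1, config$seq_depth, pool$tallies[, f, i])[, 1]
        tot <- sample(rng[1]:rng[2], 1)
        counts[s, contaminant_ids] <- stats::rmultinom(1, tot, rep(1, n_c))[, 1]
      }
      tot <- sample(rng[1]:rng[2], 1)
      counts[paste0("Sheath_", i), contaminant_ids] <-
        stats::rmultinom(1, tot, rep(1, n_c))[, 1]
    }
  })
  list(counts = counts, metadata = meta)
}
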