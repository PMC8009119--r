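# shared fixtures, built in code

# a small but structurally complete cohort configuration: full prevalence
# classes over 10 individuals, light sorting/sequencing depths for speed
small_config <- function(seed = 1, n_taxa = 60, core_count = 5,
                         unique_count = 20, relaxed_core_count = 8,
                         sort_events = 20000, seq_depth = 4000,
                         sheath_read_range = c(50L, 200L), ...) {
  sim_config(n_taxa = n_taxa, core_count = core_count,
             unique_count = unique_count,
             relaxed_core_count = relaxed_core_count,
             sort_events = sort_events, seq_depth = seq_depth,
             sheath_read_range = sheath_read_range, seed = seed, ...)
}

# beta-binomial sampler used by calibration/recovery tests (independent of
# the package's likelihood code)
rbetabinom <- function(n, size, mu, phi) {
  a <- mu * (1 - phi) / phi
  b <- (1 - mu) * (1 - phi) / phi
  stats::rbinom(n, size, stats::rbeta(n, a, b))
}

# random rooted tree with exponential branch lengths and ASV-style labels
random_test_tree <- function(n, seed) {
  set.seed(seed)
  tree <- ape::rtree(n, rooted = TRUE, br = function(k) rexp(k))
  tree$tip.label <- sprintf("ASV%04d", seq_len(n))
  tree
}

# random count matrix over the tips of a tree
random_counts <- function(n_samples, tree, seed, depth = 500) {
  set.seed(seed)
  n_taxa <- length(tree$tip.label)
  m <- t(sapply(seq_len(n_samples), function(i)
    rmultinom(1, depth, rexp(n_taxa))[, 1]))
  dimnames(m) <- list(sprintf("S%02d", seq_len(n_samples)), tree$tip.label)
  m
}
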