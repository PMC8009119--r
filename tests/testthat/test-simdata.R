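test_that("simulated trees are rooted, binary, phylum-monophyletic and seeded", {
  t2 <- simulate_tree(2, seed = 1)
  expect_equal(length(t2$tip.label), 2)
  expect_true(all(t2$edge.length > 0))

  tr <- simulate_tree(120, seed = 7)
  expect_equal(length(tr$tip.label), 120)
  expect_equal(tr$Nnode, 119)  # binary rooted: n - 1 internal splits
  expect_true(ape::is.rooted(tr))
  expect_true(ape::is.binary(tr))
  ph <- attr(tr, "phylum")
  for (p in unique(ph))
    expect_true(ape::is.monophyletic(tr, names(ph)[ph == p]), label = p)

  expect_identical(ape::write.tree(simulate_tree(50, seed = 3)),
                   ape::write.tree(simulate_tree(50, seed = 3)))
  expect_false(identical(ape::write.tree(simulate_tree(50, seed = 3)),
                         ape::write.tree(simulate_tree(50, seed = 4))))
  expect_error(simulate_tree(1), ">= 2")
})

test_that("abundance matrix realises the exact prevalence structure", {
  cfg <- small_config(seed = 5)
  ab <- simulate_abundances(cfg)
  expect_equal(rowSums(ab), rep(1, 10), tolerance = 1e-9,
               ignore_attr = TRUE)
  prev <- colSums(ab > 0)
  expect_equal(sum(prev == 10), cfg$core_count)
  expect_equal(sum(prev == 1), cfg$unique_count)
  expect_equal(sum(prev >= 8), cfg$relaxed_core_count)
  mid <- prev[prev > 1 & prev < 8]
  expect_equal(length(mid),
               cfg$n_taxa - cfg$relaxed_core_count - cfg$unique_count)

  # all-core degenerate configuration
  cfg2 <- sim_config(n_taxa = 60, core_count = 60, unique_count = 0,
                     relaxed_core_count = 60, seed = 5)
  expect_true(all(simulate_abundances(cfg2) > 0))
  expect_error(sim_config(n_taxa = 10, core_count = 8, unique_count = 5),
               "exceeds n_taxa")
})

test_that("fraction proportions recover configured moments", {
  cfg <- sim_config()
  p <- draw_fraction_proportions(cfg, n = 10000, seed = 42)
  expect_true(all(p >= 0 & p <= 100))
  expect_equal(p[, "LNA"], 100 - p[, "HNA"], tolerance = 1e-12)
  g <- c("HNA", "BONCATpos", "PIpos")
  expect_lt(max(abs(colMeans(p)[g] - cfg$fraction_means[g])), 0.5)
  expect_lt(max(abs(apply(p, 2, sd)[g] - cfg$fraction_sds[g])), 0.6)
  r <- cor(p[, g])
  expect_lt(abs(r["HNA", "PIpos"] - 0.74), 0.05)
  expect_lt(abs(r["HNA", "BONCATpos"] - (-0.62)), 0.05)
})

test_that("degenerate zero-SD copula returns the configured means exactly", {
  cfg <- sim_config(fraction_sds = c(HNA = 0, BONCATpos = 0, PIpos = 0))
  p <- draw_fraction_proportions(cfg, n = 5, seed = 1)
  expect_equal(unname(p[, "HNA"]), rep(51.73, 5))
  expect_equal(unname(p[, "PIpos"]), rep(15.73, 5))
})

test_that("propensity calibration solves the aggregate-membership equation", {
  # equal propensities: closed form delta = logit(pi/100) - logit(theta)
  a <- rep(0.25, 4)
  expect_equal(calibrate_propensities(a, rep(0.3, 4), 30), 0, tolerance = 1e-8)
  expect_equal(calibrate_propensities(a, rep(0.3, 4), 70),
               qlogis(0.7) - qlogis(0.3), tolerance = 1e-8)
  # random propensities: residual at the root is ~0
  set.seed(9)
  for (i in 1:10) {
    ab <- rexp(30); ab <- ab / sum(ab)
    th <- runif(30, 0.05, 0.95)
    d <- calibrate_propensities(ab, th, 50)
    expect_equal(sum(ab * plogis(qlogis(th) + d)), 0.5, tolerance = 1e-8)
  }
  expect_error(calibrate_propensities(a, rep(0.3, 4), 0), "reachable")
})

test_that("sorting honours gate error and conserves event counts", {
  cfg <- small_config(seed = 3)
  co <- simulate_cohort(cfg)
  tal <- co$pool$tallies
  expect_true(all(apply(tal, c(2, 3), sum) == cfg$sort_events))
  # zero gate error means perfect purity
  cfg0 <- small_config(seed = 3,
                       gate_error = c(HNA = 0, LNA = 0, BONCATpos = 0,
                                      BONCATneg = 0, PIpos = 0))
  co0 <- simulate_cohort(cfg0)
  expect_true(all(co0$pool$purity == 1))
  # at the configured 20% BONCAT+ gate error, purity concentrates at 80%
  expect_equal(mean(co$pool$purity[, "BONCATpos"]), 0.80, tolerance = 0.02)
})

test_that("sequencing conserves depth and places contaminants correctly", {
  cfg <- small_config(seed = 4)
  co <- simulate_cohort(cfg)
  meta <- co$metadata
  contam <- co$truth$contaminant_ids
  whole <- meta$sample_id[meta$fraction == "Whole"]
  sorted <- meta$sample_id[!meta$fraction %in% c("Whole", "Sheath")]
  sheath <- meta$sample_id[meta$fraction == "Sheath"]
  expect_true(all(co$counts[whole, contam] == 0))
  noncontam <- setdiff(colnames(co$counts), contam)
  expect_true(all(rowSums(co$counts[c(whole, sorted), noncontam]) ==
                    cfg$seq_depth))
  sheath_tot <- rowSums(co$counts[sheath, , drop = FALSE])
  expect_true(all(sheath_tot >= cfg$sheath_read_range[1] &
                    sheath_tot <= cfg$sheath_read_range[2]))
  expect_true(all(co$counts[sheath, noncontam] == 0))
  contam_reads <- rowSums(co$counts[sorted, contam, drop = FALSE])
  expect_true(all(contam_reads >= cfg$sheath_read_range[1] &
                    contam_reads <= cfg$sheath_read_range[2]))
})

test_that("cohort bundles are deterministic and complete", {
  cfg <- small_config(seed = 8)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$cytometry, b$cytometry)
  expect_setequal(unique(a$metadata$fraction),
                  c("Whole", "HNA", "LNA", "BONCATpos", "BONCATneg", "PIpos",
                    "Sheath"))
  expect_equal(sum(a$metadata$fraction == "Sheath"), cfg$n_individuals)
})

test_that("HNA fraction is Firmicutes-enriched relative to the whole community", {
  co <- simulate_cohort(sim_config(seed = 11))
  ph <- attr(co$tree, "phylum")[colnames(co$counts)]
  firm <- names(ph)[ph == "Firmicutes" & !grepl("CONTAM", names(ph))]
  meta <- co$metadata
  frac_share <- function(f) {
    ids <- meta$sample_id[meta$fraction == f]
    mean(rowSums(co$counts[ids, firm]) / rowSums(co$counts[ids, ]))
  }
  expect_gt(frac_share("HNA"), frac_share("Whole"))
})

test_that("treatment simulation shifts the targeted gates", {
  cfg <- small_config(seed = 2)
  co <- simulate_cohort(cfg)
  tr <- simulate_treatments(co, cfg, individual = 2,
                            effects = treatment_defaults(2), seed = 5)
  expect_equal(nrow(tr$proportions), 4 * cfg$n_replicates)
  expect_equal(sum(tr$proportions$treatment == "Glucose"), cfg$n_replicates)
  glu <- mean(tr$proportions$BONCATpos[tr$proportions$treatment == "Glucose"])
  ctl <- mean(tr$proportions$BONCATpos[tr$proportions$treatment == "Control"])
  expect_gt(glu, ctl)
  expect_error(simulate_treatments(co, cfg, effects = list(Glucose = NULL)),
               "Control")
  # zero effects: treatments share the control distribution
  eff0 <- treatment_defaults(2)
  eff0$Glucose <- eff0$Control
  tr0 <- simulate_treatments(co, cfg, individual = 1, effects = eff0, seed = 9)
  expect_lt(abs(mean(tr0$proportions$BONCATpos[tr0$proportions$treatment == "Glucose"]) -
                  mean(tr0$proportions$BONCATpos[tr0$proportions$treatment == "Control"])),
            25)
})
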