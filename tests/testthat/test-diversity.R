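test_that("branch mass concentrates on root-to-leaf paths and conserves", {
  tree <- ape::read.tree(text = "((A:1,B:2):0.5,C:3):0;")
  m <- branch_mass(tree, c(A = 1))
  # mass 1 on every branch from root to A, 0 elsewhere
  kids <- tree$edge[, 2]
  a_node <- which(tree$tip.label == "A")
  path <- c(a_node, ape::Ntip(tree) + 2)  # A and the AB ancestor
  expect_equal(m[kids %in% path], c(1, 1))
  expect_equal(sum(m[!kids %in% path]), 0)
  # cherry split evenly
  m2 <- branch_mass(tree, c(A = 0.5, B = 0.5))
  expect_equal(m2[kids == a_node], 0.5)
  expect_equal(m2[kids == ape::Ntip(tree) + 2], 1)
  # root mass conservation: total over root children is 1
  root_children <- tree$edge[tree$edge[, 1] == ape::Ntip(tree) + 1, 2]
  expect_equal(sum(m2[tree$edge[, 2] %in% root_children]), 1,
               tolerance = 1e-12)
  expect_error(branch_mass(tree, c(Z = 1)), "absent from the tree")
})

test_that("UniFrac hand computations on tiny trees", {
  star <- ape::read.tree(text = "(A:1,B:1):0;")
  expect_equal(weighted_unifrac(star, c(A = 1, B = 0), c(A = 0, B = 1)), 2)
  expect_equal(weighted_unifrac(star, c(A = 1, B = 0), c(A = 0, B = 1),
                                normalized = TRUE), 1)
  expect_equal(weighted_unifrac(star, c(A = 2, B = 2), c(A = 1, B = 1)), 0)
  expect_equal(unweighted_unifrac(star, c(A = 1, B = 0), c(A = 0, B = 1)), 1)
  expect_equal(unweighted_unifrac(star, c(A = 1, B = 1), c(A = 2, B = 5)), 0)
  expect_error(weighted_unifrac(star, c(A = 0, B = 0), c(A = 1, B = 0)),
               "zero-total")
})

test_that("UniFrac matches brute-force per-branch summation on random trees", {
  for (s in 1:5) {
    tree <- random_test_tree(12, seed = s)
    counts <- random_counts(4, tree, seed = s + 100)
    rel <- counts / rowSums(counts)
    # brute force: per branch, sum abundances over the descendant tip set
    brute_mass <- function(x) {
      sapply(seq_len(nrow(tree$edge)), function(e) {
        node <- tree$edge[e, 2]
        tips <- if (node <= ape::Ntip(tree)) tree$tip.label[node]
                else ape::extract.clade(tree, node)$tip.label
        sum(x[tips])
      })
    }
    D <- distance_matrix(counts, "weighted_unifrac", tree = tree)
    for (i in 1:3) for (j in (i + 1):4) {
      expect_equal(D[i, j],
                   sum(tree$edge.length *
                         abs(brute_mass(rel[i, ]) - brute_mass(rel[j, ]))),
                   tolerance = 1e-12)
    }
  }
})

test_that("UniFrac agrees with the phyloseq reference implementation", {
  skip_if_not_installed("phyloseq")
  tree <- random_test_tree(16, seed = 42)
  counts <- random_counts(20, tree, seed = 43)
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(t(counts), taxa_are_rows = TRUE), ape::as.phylo(tree))
  ref_raw <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE,
                                         normalized = FALSE))
  got_raw <- distance_matrix(counts, "weighted_unifrac", tree = tree)
  expect_equal(got_raw, ref_raw[rownames(got_raw), colnames(got_raw)],
               tolerance = 1e-9, ignore_attr = TRUE)
  ref_norm <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE,
                                          normalized = TRUE))
  got_norm <- distance_matrix(counts, "weighted_unifrac", tree = tree,
                              normalized = TRUE)
  expect_equal(got_norm, ref_norm[rownames(got_norm), colnames(got_norm)],
               tolerance = 1e-9, ignore_attr = TRUE)
  ref_uw <- as.matrix(phyloseq::UniFrac(ps, weighted = FALSE))
  got_uw <- distance_matrix(counts, "unweighted_unifrac", tree = tree)
  expect_equal(got_uw, ref_uw[rownames(got_uw), colnames(got_uw)],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("Bray-Curtis matches hand values and the vegan implementation", {
  expect_equal(bray_curtis(c(0.5, 0.5), c(0.25, 0.75)), 0.25)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_equal(bray_curtis(c(2, 2), c(5, 5)), 0)
  set.seed(3)
  m <- matrix(rpois(60, 20), 6, 10,
              dimnames = list(paste0("s", 1:6), paste0("t", 1:10)))
  got <- distance_matrix(m, "bray_curtis")
  ref <- as.matrix(vegan::vegdist(m / rowSums(m), method = "bray"))
  expect_equal(got, ref[rownames(got), colnames(got)], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("distance matrices are symmetric with zero diagonal and metric-ish", {
  tree <- random_test_tree(10, seed = 5)
  counts <- random_counts(6, tree, seed = 6)
  counts <- rbind(counts, dup = counts[1, ])  # duplicated sample
  for (metric in c("weighted_unifrac", "unweighted_unifrac", "bray_curtis")) {
    D <- distance_matrix(counts, metric, tree = tree)
    expect_equal(D, t(D))
    expect_equal(unname(diag(D)), rep(0, nrow(D)))
    expect_equal(D["S01", "dup"], 0)
    # triangle inequality spot checks on all triples
    for (i in 1:5) for (j in (i + 1):6) for (k in 1:7)
      expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
  }
  expect_error(distance_matrix(counts, "weighted_unifrac"), "require a tree")
})

test_that("PCoA recovers classical-scaling geometry", {
  # three collinear points at 0, 1, 2
  D <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  res <- pcoa(D, n_axes = 2)
  expect_equal(abs(res$coordinates[, 1]), c(a = 1, b = 0, c = 1))
  expect_lt(sum(res$eigenvalues[-1]^2), 1e-20)
  # Euclidean distances are reproduced exactly by the embedding
  set.seed(8)
  X <- matrix(rnorm(5 * 3), 5, 3)
  DE <- as.matrix(dist(X))
  emb <- pcoa(DE, n_axes = 5)$coordinates
  expect_equal(as.matrix(dist(emb)), DE, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(diff(pcoa(DE, 5)$eigenvalues) <= 1e-9))
  # agreement with cmdscale up to axis sign
  ref <- cmdscale(DE, k = 2)
  got <- pcoa(DE, 2)$coordinates
  for (k in 1:2)
    expect_equal(abs(got[, k]), abs(ref[, k]), tolerance = 1e-9,
                 ignore_attr = TRUE)
})

test_that("Shannon diversity uses natural log and is maximal at uniformity", {
  expect_equal(shannon(c(5, 0, 0)), 0)
  expect_equal(shannon(rep(3, 4)), log(4))
  expect_equal(shannon(c(10, 20, 30, 40)),
               vegan::diversity(c(10, 20, 30, 40), index = "shannon"))
  set.seed(2)
  for (i in 1:5) {
    x <- rpois(6, 30) + 1
    expect_lte(shannon(x), log(6) + 1e-12)
  }
  expect_error(shannon(c(0, 0)), "zero-total")
})
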