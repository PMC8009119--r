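#' Simulate a rooted phylogeny over synthetic ASVs
#'
#' Generates a rooted binary tree with `n_taxa` leaves and strictly positive,
#' exponentially distributed branch lengths. Leaves are organised into
#' monophyletic clades, one per phylum label, by simulating one random
#' topology per phylum and joining the clades along a ladder backbone; leaf
#' counts per phylum follow `phylum_weights` (largest-remainder rounding).
#' Tip labels are `ASV0001 ... ASVnnnn` in clade order, so each phylum is a
#' contiguous, monophyletic block.
#'
#' @param n_taxa number of leaves (at least 2).
#' @param seed integer seed; the same `(n_taxa, seed)` pair always yields a
#'   byte-identical tree.
#' @param phylum_labels,phylum_weights clade labels and their expected leaf
#'   shares.
#' @param branch_rate rate of the exponential branch-length distribution.
#' @return an [ape::read.tree()] `phylo` object with an added `phylum`
#'   attribute: a character vector named by tip label.
#' @export
simulate_tree <- function(n_taxa, seed = NULL,
                          phylum_labels = c("Firmicutes", "Bacteroidetes",
                                            "Actinobacteria", "Proteobacteria"),
                          phylum_weights = c(0.60, 0.25, 0.08, 0.07),
                          branch_rate = 1) {
  if (length(n_taxa) != 1 || n_taxa < 2 || n_taxa != floor(n_taxa))
    stopf("`n_taxa` must be an integer >= 2")
  with_seed(seed, {
    sizes <- largest_remainder(n_taxa, phylum_weights)
    keep <- sizes > 0
    sizes <- sizes[keep]
    labels <- phylum_labels[keep]
    subnwk <- character(length(sizes))
    for (i in seq_along(sizes)) {
      if (sizes[i] == 1) {
        subnwk[i] <- "@"
      } else {
        sub <- ape::rtree(sizes[i], rooted = TRUE,
                          br = function(n) stats::rexp(n, branch_rate))
        sub$tip.label <- rep("@", sizes[i])  # placeholder, renamed below
        subnwk[i] <- gsub(";$", "", ape::write.tree(sub))
      }
    }
    if (length(subnwk) == 1) {
      tree <- ape::read.tree(text = paste0(subnwk, ";"))
    } else {
      # ladder backbone joining the phylum clades; every join is binary
      nwk <- paste0(subnwk[length(subnwk)], ":",
                    format(stats::rexp(1, branch_rate), digits = 12))
      for (i in (length(subnwk) - 1):1) {
        e <- format(stats::rexp(2, branch_rate), digits = 12)
        nwk <- paste0("(", subnwk[i], ":", e[1], ",", nwk, ")",
                      if (i > 1) paste0(":", e[2]) else "")
      }
      tree <- ape::read.tree(text = paste0(nwk, ";"))
    }
    # name tips in clade order so phylum blocks are contiguous
    ord <- tip_order(tree)
    tree$tip.label[ord] <- sprintf("ASV%04d", seq_len(n_taxa))
    phylum <- rep(labels, sizes)
    names(phylum) <- sprintf("ASV%04d", seq_len(n_taxa))
    attr(tree, "phylum") <- phylum
    tree
  })
}

# leaf indices in left-to-right (cladewise) order
tip_order <- function(tree) {
  edge <- ape::reorder.phylo(tree, "cladewise")$edge
  edge[edge[, 2] <= length(tree$tip.label), 2]
}

largest_remainder <- function(n, weights) {
  w <- weights / sum(weights)
  raw <- n * w
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    up <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[up] <- base[up] + 1
  }
  as.integer(base)
}
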