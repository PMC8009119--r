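#' Per-branch descendant mass
#'
#' For a rooted tree and one sample's relative abundances over its leaves,
#' returns for every edge the summed abundance of the leaves below it. This
#' is the inner quantity of both UniFrac variants: the root carries mass 1.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param abundances named relative-abundance vector; names must be a subset
#'   mapping onto `tree$tip.label` (absent tips get mass 0).
#' @return numeric vector of length `nrow(tree$edge)`, in edge order.
#' @export
branch_mass <- function(tree, abundances) {
  miss <- setdiff(names(abundances)[abundances > 0], tree$tip.label)
  if (length(miss) > 0)
    stopf("taxa absent from the tree: %s", paste(utils::head(miss, 3),
                                                 collapse = ", "))
  edge_mass_matrix(tree, matrix(abundances, 1,
                                dimnames = list("s", names(abundances))))[, 1]
}

# edges x samples matrix of descendant mass, one postorder accumulation pass
edge_mass_matrix <- function(tree, rel) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  node_mass <- matrix(0, n_node, nrow(rel))
  idx <- match(colnames(rel), tree$tip.label)
  ok <- !is.na(idx)
  node_mass[idx[ok], ] <- t(rel[, ok, drop = FALSE])
  edge <- tree$edge
  po <- ape::reorder.phylo(tree, "postorder")$edge
  ord <- match(paste(po[, 1], po[, 2]), paste(edge[, 1], edge[, 2]))
  for (k in seq_len(nrow(po)))
    node_mass[po[k, 1], ] <- node_mass[po[k, 1], ] + node_mass[po[k, 2], ]
  out <- node_mass[edge[, 2], , drop = FALSE]
  rownames(out) <- NULL
  out
}

# normalise count/abundance rows to proportions
rel_abund <- function(x) {
  tot <- rowSums(x)
  if (any(tot <= 0)) stopf("sample(s) with zero total abundance")
  x / tot
}

#' Weighted UniFrac distance between two samples
#'
#' Raw weighted UniFrac is `sum_i l_i * |p_Ai - p_Bi|` over branches `i` with
#' length `l_i` and descendant proportions `p`. The normalised variant
#' divides by `sum_i l_i * (p_Ai + p_Bi)`.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param A,B named abundance vectors (normalised internally).
#' @param normalized divide by the maximum attainable spread.
#' @return a single non-negative distance.
#' @export
weighted_unifrac <- function(tree, A, B, normalized = FALSE) {
  if (sum(A) <= 0 || sum(B) <= 0) stopf("zero-total sample")
  pa <- branch_mass(tree, A / sum(A))
  pb <- branch_mass(tree, B / sum(B))
  l <- tree$edge.length
  raw <- sum(l * abs(pa - pb))
  if (normalized) raw / sum(l * (pa + pb)) else raw
}

#' Unweighted UniFrac distance between two samples
#'
#' Fraction of branch length leading to leaves present in exactly one of the
#' two samples, over branch length leading to leaves present in either.
#'
#' @inheritParams weighted_unifrac
#' @return a distance in `[0, 1]`.
#' @export
unweighted_unifrac <- function(tree, A, B) {
  if (sum(A) <= 0 || sum(B) <= 0) stopf("zero-total sample")
  pa <- branch_mass(tree, (A > 0) / sum(A > 0))
  pb <- branch_mass(tree, (B > 0) / sum(B > 0))
  in_a <- pa > 0; in_b <- pb > 0
  l <- tree$edge.length
  sum(l[xor(in_a, in_b)]) / sum(l[in_a | in_b])
}

#' Bray-Curtis dissimilarity between two samples
#'
#' `sum |a_i - b_i| / sum (a_i + b_i)` on relative abundances.
#'
#' @param A,B abundance vectors of equal length.
#' @return a dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(A, B) {
  if (length(A) != length(B)) stopf("vectors of unequal length")
  if (sum(A) <= 0 || sum(B) <= 0) stopf("zero-total sample")
  a <- A / sum(A); b <- B / sum(B)
  sum(abs(a - b)) / sum(a + b)
}

#' All pairwise distances between samples
#'
#' @param x samples x ASVs count or abundance matrix (rows are normalised to
#'   proportions internally), or a `count_table`.
#' @param metric one of `"weighted_unifrac"`, `"unweighted_unifrac"`,
#'   `"bray_curtis"`.
#' @param tree required for the UniFrac metrics.
#' @param normalized for weighted UniFrac only.
#' @return a symmetric `dist`-compatible matrix with zero diagonal, class
#'   `matrix`, sample ids as dimnames.
#' @export
distance_matrix <- function(x, metric = c("weighted_unifrac",
                                          "unweighted_unifrac", "bray_curtis"),
                            tree = NULL, normalized = FALSE) {
  metric <- match.arg(metric)
  counts <- if (inherits(x, "count_table")) x$counts else as.matrix(x)
  rel <- rel_abund(counts)
  n <- nrow(rel)
  D <- matrix(0, n, n, dimnames = list(rownames(rel), rownames(rel)))
  if (metric == "bray_curtis") {
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      D[i, j] <- D[j, i] <- sum(abs(rel[i, ] - rel[j, ])) / 2
    return(D)
  }
  if (is.null(tree)) stopf("UniFrac metrics require a tree")
  miss <- setdiff(colnames(rel)[colSums(rel) > 0], tree$tip.label)
  if (length(miss) > 0)
    stopf("taxa absent from the tree: %s", paste(utils::head(miss, 3),
                                                 collapse = ", "))
  l <- tree$edge.length
  if (metric == "weighted_unifrac") {
    M <- edge_mass_matrix(tree, rel)               # edges x samples
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      raw <- sum(l * abs(M[, i] - M[, j]))
      D[i, j] <- D[j, i] <- if (normalized)
        raw / sum(l * (M[, i] + M[, j])) else raw
    }
  } else {
    P <- edge_mass_matrix(tree, rel_abund((counts > 0) * 1)) > 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      either <- P[, i] | P[, j]
      D[i, j] <- D[j, i] <- sum(l[xor(P[, i], P[, j])]) / sum(l[either])
    }
  }
  D
}

#' Principal coordinates analysis (classical scaling)
#'
#' Gower-centres `-D^2 / 2` and eigendecomposes. Coordinates are the
#' eigenvectors scaled by the square roots of the positive eigenvalues; axes
#' are ordered by nonincreasing eigenvalue. Negative eigenvalues (possible
#' for non-Euclidean dissimilarities) are reported but excluded from the
#' coordinates, and no Cailliez/Lingoes correction is applied.
#'
#' @param D symmetric distance matrix.
#' @param n_axes maximum number of axes to return.
#' @return list of class `pcoa_result`: `coordinates` (samples x axes),
#'   `eigenvalues` (all of them), `prop_explained` (relative to the sum of
#'   positive eigenvalues).
#' @export
pcoa <- function(D, n_axes = 2) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (all(D == 0)) {
    warnf("all distances are zero; coordinates degenerate")
    return(structure(list(coordinates = matrix(0, n, n_axes,
                                               dimnames = list(rownames(D), NULL)),
                          eigenvalues = rep(0, n), prop_explained = rep(0, n_axes)),
                     class = "pcoa_result"))
  }
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (D^2) %*% J
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-12
  k <- min(n_axes, sum(pos))
  coords <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(eg$values[seq_len(k)]), k)
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("PCo", seq_len(k))
  structure(list(coordinates = coords, eigenvalues = eg$values,
                 prop_explained = eg$values[seq_len(k)] / sum(eg$values[pos])),
            class = "pcoa_result")
}

#' Shannon diversity (natural log)
#'
#' `H = -sum q_i ln q_i` over nonzero proportions; 0 for a single taxon,
#' at most `ln`(richness).
#'
#' @param counts a count or abundance vector with positive total.
#' @return the Shannon index in nats.
#' @export
shannon <- function(counts) {
  if (sum(counts) <= 0) stopf("zero-total sample")
  q <- counts[counts > 0] / sum(counts)
  -sum(q * log(q))
}

#' Rarefied alpha diversity per sample
#'
#' Rarefies to a common depth without replacement, then computes Shannon
#' diversity per sample.
#'
#' @param table a `count_table` or counts matrix.
#' @param depth rarefaction depth.
#' @param seed integer seed for the subsampling.
#' @return data.frame: sample_id, shannon, depth.
#' @export
alpha_diversity <- function(table, depth = 10534, seed = NULL) {
  rare <- rarefy_counts(table, depth, seed)
  data.frame(sample_id = rownames(rare),
             shannon = apply(rare, 1, shannon),
             depth = depth, row.names = NULL)
}
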