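#' Permutational multivariate ANOVA on a distance matrix
#'
#' Partitions the total sum of squares of a Gower-centred distance matrix
#' across a grouping factor (McArdle & Anderson formulation, the model behind
#' `adonis`). The pseudo-F statistic is `(SS_between/df_b) / (SS_within/df_w)`
#' and its p-value comes from free permutation of sample labels, using the
#' `(1 + #better) / (1 + n_perm)` estimator so p is never zero.
#'
#' @param D symmetric distance matrix (or `dist`).
#' @param groups grouping vector, one entry per sample.
#' @param n_perm number of label permutations, or `"exact"` to enumerate all
#'   permutations (feasible for up to ~8 samples).
#' @param seed integer seed for the permutations.
#' @return data.frame of class `permanova_result` with rows for the group
#'   term, residual and total: columns `term, df, SS, R2, F, p, n_perm`.
#' @export
permanova <- function(D, groups, n_perm = 999, seed = NULL) {
  D <- as.matrix(D)
  groups <- as.factor(groups)
  if (length(groups) != nrow(D)) stopf("one group label per sample required")
  if (nlevels(droplevels(groups)) < 2)
    stopf("PERMANOVA needs at least two groups")
  res <- permanova_terms(D, list(groups = droplevels(groups)),
                         n_perm = n_perm, seed = seed)
  res$term[1] <- "groups"
  res
}

# shared engine: sequential (Type I) decomposition over a list of factors
permanova_terms <- function(D, terms, n_perm = 999, seed = NULL) {
  n <- nrow(D)
  G <- gower_center(D)
  ss_total <- sum(diag(G))
  projectors <- list()
  X <- matrix(1, n, 1)  # intercept
  rank0 <- 1
  for (tm in names(terms)) {
    X <- cbind(X, stats::model.matrix(~ f - 1,
                                      data = data.frame(f = terms[[tm]])))
    q <- qr(X)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    projectors[[tm]] <- list(Q = Q, df = q$rank - rank0)
    rank0 <- q$rank
  }
  ss_fn <- function(Gp) {
    cum <- 0
    out <- numeric(length(projectors))
    for (k in seq_along(projectors)) {
      full <- sum(projectors[[k]]$Q * (Gp %*% projectors[[k]]$Q)) -
        sum(Gp) / n  # remove the intercept projection
      out[k] <- full - cum
      cum <- full
    }
    out
  }
  ss_terms <- ss_fn(G)
  df_terms <- vapply(projectors, function(p) p$df, numeric(1))
  df_res <- n - 1 - sum(df_terms)
  if (df_res <= 0) stopf("no residual degrees of freedom")
  ss_res <- ss_total - sum(ss_terms)
  f_obs <- ifelse(df_terms > 0,
                  (ss_terms / pmax(df_terms, 1)) / (ss_res / df_res), NA_real_)

  exact <- identical(n_perm, "exact")
  perms <- permutation_set(n, n_perm, seed)
  exceed <- rep(0, length(ss_terms))
  for (p in seq_len(ncol(perms))) {
    idx <- perms[, p]
    ss_p <- ss_fn(G[idx, idx])
    f_p <- (ss_p / pmax(df_terms, 1)) / ((ss_total - sum(ss_p)) / df_res)
    exceed <- exceed + (f_p >= f_obs - 1e-12)
  }
  # exact enumeration includes the identity permutation, so the plain
  # fraction is already a valid p; Monte-Carlo sampling adds the +1 guard
  pvals <- ifelse(df_terms > 0,
                  if (exact) exceed / ncol(perms)
                  else (exceed + 1) / (ncol(perms) + 1),
                  NA_real_)

  out <- data.frame(
    term = c(names(terms), "Residual", "Total"),
    df = c(df_terms, df_res, n - 1),
    SS = c(ss_terms, ss_res, ss_total),
    R2 = c(ss_terms, ss_res, ss_total) / ss_total,
    F = c(f_obs, NA, NA),
    p = c(pvals, NA, NA),
    n_perm = ncol(perms),
    row.names = NULL
  )
  class(out) <- c("permanova_result", "data.frame")
  out
}

gower_center <- function(D) {
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  A <- -0.5 * D^2
  J %*% A %*% J
}

permutation_set <- function(n, n_perm, seed) {
  if (identical(n_perm, "exact")) {
    if (n > 9) stopf("exact enumeration is limited to 9 samples")
    return(all_permutations(n))
  }
  with_seed(seed, vapply(seq_len(n_perm), function(i) sample.int(n),
                         integer(n)))
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, n, n * ncol(sub))
  col <- 0
  for (pos in seq_len(n)) for (j in seq_len(ncol(sub))) {
    col <- col + 1
    out[, col] <- append(sub[, j], n, after = pos - 1)
  }
  out
}

#' Sequential nested PERMANOVA
#'
#' Fits the two-term sequential (Type I) decomposition `outer` then
#' `inner %in% outer` (the inner factor coded as separate effects within each
#' outer level, i.e. the outer x inner cell dummies after the outer main
#' effect). Each term's pseudo-F uses the common residual; p-values come from
#' free permutation of samples.
#'
#' @param D symmetric distance matrix.
#' @param outer_factor,inner_factor grouping vectors; `inner_factor` is
#'   tested within levels of `outer_factor`.
#' @param n_perm,seed as in [permanova()].
#' @return a `permanova_result` with rows `outer`, `inner_within_outer`,
#'   `Residual`, `Total`.
#' @export
nested_permanova <- function(D, outer_factor, inner_factor, n_perm = 999,
                             seed = NULL) {
  D <- as.matrix(D)
  outer_factor <- droplevels(as.factor(outer_factor))
  inner_factor <- droplevels(as.factor(inner_factor))
  if (length(outer_factor) != nrow(D) || length(inner_factor) != nrow(D))
    stopf("factor lengths must match the distance matrix")
  if (nlevels(outer_factor) < 2) stopf("outer factor needs >= 2 levels")
  cells <- droplevels(interaction(outer_factor, inner_factor, drop = TRUE))
  res <- permanova_terms(D, list(outer = outer_factor,
                                 inner_within_outer = cells),
                         n_perm = n_perm, seed = seed)
  res
}

#' Pairwise PERMANOVA with FDR adjustment
#'
#' Runs [permanova()] on every pair of group levels and adjusts the
#' permutation p-values across pairs by Benjamini-Hochberg.
#'
#' @inheritParams permanova
#' @return data.frame: group1, group2, n, df, R2, F, p, q.
#' @export
pairwise_permanova <- function(D, groups, n_perm = 999, seed = NULL) {
  D <- as.matrix(D)
  groups <- droplevels(as.factor(groups))
  lv <- levels(groups)
  if (length(lv) < 2) stopf("need at least two groups")
  pairs <- utils::combn(lv, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    sel <- groups %in% pairs[, k]
    r <- permanova(D[sel, sel, drop = FALSE], groups[sel], n_perm = n_perm,
                   seed = if (is.null(seed)) NULL else child_seed(seed, k))
    data.frame(group1 = pairs[1, k], group2 = pairs[2, k], n = sum(sel),
               df = r$df[1], R2 = r$R2[1], F = r$F[1], p = r$p[1])
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out
}
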