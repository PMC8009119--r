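#' Kruskal-Wallis rank test over groups of values
#'
#' Thin wrapper around [stats::kruskal.test()] (tie-corrected H, chi-squared
#' p with `groups - 1` df), returning the pieces downstream post hoc tests
#' need. All-identical values yield `H = 0, p = 1`.
#'
#' @param values numeric vector.
#' @param groups grouping vector of the same length.
#' @return list `(H, p, df)`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stopf("need at least two groups")
  if (length(unique(values)) < 2)
    return(list(H = 0, p = 1, df = nlevels(groups) - 1))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}

#' Dunn's post hoc test after Kruskal-Wallis
#'
#' For each pair of groups `(i, j)`,
#' `z = (meanrank_i - meanrank_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))`
#' with tie correction `T = sum(t^3 - t) / (12 (N - 1))` over tie group sizes
#' `t`; two-sided normal p-values, Benjamini-Hochberg adjusted across pairs.
#'
#' @inheritParams kruskal_wallis
#' @return data.frame: group1, group2, z, p, q.
#' @export
dunn_posthoc <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stopf("need at least two groups")
  N <- length(values)
  rk <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rk <- tapply(rk, groups, mean)
  n_g <- tapply(rk, groups, length)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n_g[[i]] + 1 / n_g[[j]]))
    z[k] <- (mean_rk[[i]] - mean_rk[[j]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             q = bh_adjust(p))
}

#' Pearson correlation with t-based p-value
#'
#' Wraps [stats::cor.test()]: two-sided p from
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)` with `n - 2` df.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`, non-constant.
#' @return list `(r, p, n)`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stopf("need paired vectors of length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("constant vector: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' One-way ANOVA plus per-treatment comparisons against a control
#'
#' Overall one-way ANOVA F across all groups, then two-sided Welch t-tests of
#' each non-control group against the control, Benjamini-Hochberg adjusted
#' across treatments. Welch's unequal-variance form suits small replicate
#' numbers with heterogeneous SDs. When every group has zero within-group
#' variance and equal means, p-values are 1 by convention.
#'
#' @param values numeric response.
#' @param groups grouping vector.
#' @param control the control group label.
#' @return list with `anova` (F, p, df) and `vs_control` (data.frame:
#'   treatment, diff, t, p, q).
#' @export
anova_vs_control <- function(values, groups, control = "Control") {
  groups <- droplevels(as.factor(groups))
  if (!control %in% levels(groups)) stopf("control group '%s' absent", control)
  if (any(table(groups) < 2)) stopf("need >= 2 replicates per group")
  if (length(unique(values)) == 1) {
    treats <- setdiff(levels(groups), control)
    return(list(anova = list(F = 0, p = 1, df = c(nlevels(groups) - 1,
                                                  length(values) - nlevels(groups))),
                vs_control = data.frame(treatment = treats, diff = 0,
                                        t = 0, p = 1, q = 1)))
  }
  av <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  treats <- setdiff(levels(groups), control)
  rows <- lapply(treats, function(tr) {
    tt <- stats::t.test(values[groups == tr], values[groups == control])
    data.frame(treatment = tr,
               diff = mean(values[groups == tr]) - mean(values[groups == control]),
               t = unname(tt$statistic), p = tt$p.value)
  })
  vs <- do.call(rbind, rows)
  vs$q <- bh_adjust(vs$p)
  list(anova = list(F = unname(av$statistic), p = av$p.value,
                    df = unname(av$parameter)),
       vs_control = vs)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values via [stats::p.adjust()]; NAs are preserved.
#'
#' @param pvals raw p-values in `[0, 1]`.
#' @return adjusted q-values.
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}
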