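#' Beta-binomial log-likelihood
#'
#' Parameterised by mean `mu` and overdispersion `phi`, both in (0, 1), with
#' shape parameters `alpha = mu (1 - phi) / phi` and
#' `beta = (1 - mu)(1 - phi) / phi`. As `phi -> 0` the distribution
#' approaches Binomial(n, mu); as `phi -> 1` it spreads mass to the extremes.
#' The log-likelihood of counts `y` out of totals `n` is
#' `sum [ ln C(n, y) + ln B(y + alpha, n - y + beta) - ln B(alpha, beta) ]`.
#'
#' @param y successes (taxon reads), same length as `n`.
#' @param n trials (library sizes).
#' @param mu mean proportion, in (0, 1); scalar or per-observation.
#' @param phi overdispersion, in (0, 1); scalar or per-observation.
#' @return the summed log-likelihood.
#' @export
betabinom_loglik <- function(y, n, mu, phi) {
  if (any(y < 0) || any(y > n)) stopf("`y` must lie in [0, n]")
  if (any(mu <= 0) || any(mu >= 1) || any(phi <= 0) || any(phi >= 1))
    stopf("`mu` and `phi` must lie strictly inside (0, 1)")
  a <- mu * (1 - phi) / phi
  b <- (1 - mu) * (1 - phi) / phi
  sum(lchoose(n, y) + lbeta(y + a, n - y + b) - lbeta(a, b))
}

# MLE of a beta-binomial with mu (optionally per group) and phi (optionally
# per group) on logit scales; returns par estimates and maximised loglik
fit_bb_model <- function(y, n, group, mu_by_group, phi_by_group,
                         n_restarts = 3) {
  g <- as.integer(group)
  n_g <- max(g)
  k_mu <- if (mu_by_group) n_g else 1
  k_phi <- if (phi_by_group) n_g else 1
  nll <- function(par) {
    mu <- inv_logit(par[seq_len(k_mu)])
    phi <- inv_logit(par[k_mu + seq_len(k_phi)])
    mu_i <- if (mu_by_group) mu[g] else mu
    phi_i <- if (phi_by_group) phi[g] else phi
    -betabinom_loglik(y, n, pmin(pmax(mu_i, 1e-12), 1 - 1e-12),
                      pmin(pmax(phi_i, 1e-12), 1 - 1e-12))
  }
  p_hat <- max(min(sum(y) / sum(n), 1 - 1e-6), 1e-6)
  start0 <- c(rep(logit(p_hat), k_mu), rep(logit(0.05), k_phi))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    start <- if (r == 1) start0 else
      start0 + c(rep(0, k_mu), rep(0, k_phi)) + (r - 2) * 1.5
    fit <- tryCatch(
      stats::optim(start, nll, method = "L-BFGS-B",
                   lower = rep(-30, k_mu + k_phi),
                   upper = rep(30, k_mu + k_phi),
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) return(NULL)
  list(mu = inv_logit(best$par[seq_len(k_mu)]),
       phi = inv_logit(best$par[k_mu + seq_len(k_phi)]),
       loglik = -best$value, convergence = best$convergence)
}

#' Beta-binomial tests of differential abundance and dispersion
#'
#' For one taxon's counts across samples, fits nested beta-binomial models by
#' maximum likelihood (bounded quasi-Newton on logit-transformed parameters,
#' three restarts) and performs two likelihood-ratio tests:
#' \describe{
#'   \item{abundance}{group-specific means vs a shared mean (shared
#'     dispersion), chi-squared with `groups - 1` df;}
#'   \item{dispersion}{group-specific dispersions vs a shared dispersion
#'     (group-specific means), chi-squared with `groups - 1` df.}
#' }
#'
#' @param y taxon counts per sample.
#' @param totals library size per sample.
#' @param groups grouping vector (>= 2 samples per group).
#' @return one-row data.frame: per-group `mu` and `phi` estimates (columns
#'   `mu.<level>`, `phi.<level>`), `lrt_abundance`, `p_abundance`,
#'   `lrt_dispersion`, `p_dispersion`. Degenerate taxa (all-zero or
#'   non-converged fits) yield NA statistics.
#' @export
fit_betabinom_test <- function(y, totals, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stopf("need at least two groups")
  if (any(table(groups) < 2)) stopf("need >= 2 samples per group")
  lv <- levels(groups)
  na_row <- function() {
    out <- data.frame(t(rep(NA_real_, 2 * length(lv))))
    names(out) <- c(paste0("mu.", lv), paste0("phi.", lv))
    cbind(out, lrt_abundance = NA_real_, p_abundance = NA_real_,
          lrt_dispersion = NA_real_, p_dispersion = NA_real_,
          degenerate = TRUE)
  }
  if (sum(y) == 0 || all(y == totals)) return(na_row())
  m_null <- fit_bb_model(y, totals, groups, FALSE, FALSE)
  m_mu <- fit_bb_model(y, totals, groups, TRUE, FALSE)
  m_full <- fit_bb_model(y, totals, groups, TRUE, TRUE)
  if (is.null(m_null) || is.null(m_mu) || is.null(m_full)) return(na_row())
  df <- nlevels(groups) - 1
  lrt_ab <- max(0, 2 * (m_mu$loglik - m_null$loglik))
  lrt_disp <- max(0, 2 * (m_full$loglik - m_mu$loglik))
  out <- data.frame(t(c(m_full$mu, m_full$phi)))
  names(out) <- c(paste0("mu.", lv), paste0("phi.", lv))
  cbind(out,
        lrt_abundance = lrt_ab,
        p_abundance = stats::pchisq(lrt_ab, df, lower.tail = FALSE),
        lrt_dispersion = lrt_disp,
        p_dispersion = stats::pchisq(lrt_disp, df, lower.tail = FALSE),
        degenerate = FALSE)
}

#' Per-taxon differential abundance/dispersion across a count table
#'
#' Applies [fit_betabinom_test()] to every ASV (column) of a count table,
#' with library sizes as trials, and adjusts both p-value families across
#' taxa by Benjamini-Hochberg.
#'
#' @param counts samples x ASVs matrix.
#' @param groups per-sample grouping vector.
#' @return data.frame, one row per taxon, sorted by `q_abundance`.
#' @export
taxa_betabinom_tests <- function(counts, groups) {
  totals <- rowSums(counts)
  rows <- lapply(colnames(counts), function(a)
    cbind(taxon = a, fit_betabinom_test(counts[, a], totals, groups)))
  out <- do.call(rbind, rows)
  out$q_abundance <- bh_adjust(out$p_abundance)
  out$q_dispersion <- bh_adjust(out$p_dispersion)
  out[order(out$q_abundance), ]
}
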