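#' Simulate per-individual relative abundances with a core/unique structure
#'
#' Draws an individuals x taxa relative-abundance matrix realising an exact
#' prevalence structure: `core_count` taxa occur in every individual,
#' `unique_count` taxa in exactly one, `relaxed_core_count` taxa (including
#' the strict core) in at least 80 % of individuals, and all remaining taxa in
#' an intermediate number. Nonzero abundances are log-normal; prevalent taxa
#' receive a higher log-mean (occupancy-abundance relation), so the core
#' carries a realistic share of community mass. Rows are normalised to sum
#' to 1.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to the config seed.
#' @return matrix (individuals x taxa, rows `I01...`, columns `ASV0001...`)
#'   with attributes `status` (per-taxon `"core"`, `"relaxed"`, `"mid"` or
#'   `"unique"`) and `presence` (logical matrix of the same shape).
#' @export
simulate_abundances <- function(config, seed = config$seed) {
  n_i <- config$n_individuals
  n_t <- config$n_taxa
  n_core <- config$core_count
  n_unique <- config$unique_count
  n_relaxed_extra <- config$relaxed_core_count - n_core
  n_mid <- n_t - n_core - n_unique - n_relaxed_extra
  if (n_mid < 0) stopf("prevalence structure infeasible: counts exceed n_taxa")
  relaxed_lo <- ceiling(0.8 * n_i)  # "present in >= 8 of 10"
  if (n_relaxed_extra > 0 && relaxed_lo > n_i - 1)
    stopf("no room for relaxed-core prevalences below n_individuals")
  if (n_mid > 0 && relaxed_lo - 1 < 2)
    stopf("no room for intermediate prevalences in 2..%d", relaxed_lo - 1)

  with_seed(seed, {
    status <- rep(c("core", "relaxed", "mid", "unique"),
                  c(n_core, n_relaxed_extra, n_mid, n_unique))
    status <- status[sample.int(n_t)]  # decouple status from clade order
    presence <- matrix(FALSE, n_i, n_t)
    for (t in seq_len(n_t)) {
      pick1 <- function(v) if (length(v) == 1) v else sample(v, 1)
      k <- switch(status[t],
        core = n_i,
        relaxed = pick1(relaxed_lo:(n_i - 1)),
        mid = pick1(2:(relaxed_lo - 1)),
        unique = 1L)
      presence[sample.int(n_i, k), t] <- TRUE
    }
    # occupancy-abundance: prevalent taxa are also the abundant ones, and
    # core/relaxed-core taxa are conserved -- they keep a taxon-level
    # log-mean across individuals with only modest individual scatter,
    # whereas transient (mid/unique) taxa vary with the full log-normal SD
    sigma <- config$abundance_lognormal_sigma
    taxon_meanlog <- c(core = 2, relaxed = 1, mid = 0, unique = 0)[status] +
      stats::rnorm(n_t, 0, ifelse(status %in% c("core", "relaxed"), 1, 0))
    ind_sdlog <- ifelse(status == "core", 0.3,
                        ifelse(status == "relaxed", 0.5, sigma))
    ab <- matrix(0, n_i, n_t,
                 dimnames = list(sprintf("I%02d", seq_len(n_i)),
                                 sprintf("ASV%04d", seq_len(n_t))))
    nz <- which(presence)
    ab[nz] <- stats::rlnorm(length(nz),
                            meanlog = rep(taxon_meanlog, each = n_i)[nz],
                            sdlog = rep(ind_sdlog, each = n_i)[nz])
    ab <- ab / rowSums(ab)
    # floor present-taxon proportions so presence survives multinomial
    # sequencing at typical depths (the prevalence structure is exact)
    floor_p <- min(5e-4, 0.5 / max(rowSums(presence)))
    for (k in 1:2) {
      low <- presence & ab < floor_p
      ab[low] <- floor_p
      ab <- ab / rowSums(ab)
    }
    names(status) <- colnames(ab)
    attr(ab, "status") <- status
    attr(ab, "presence") <- presence
    ab
  })
}

#' Draw correlated cytometric fraction proportions
#'
#' Per individual, the triple (HNA, BONCAT+, PI+) of gate percentages is
#' drawn from a Gaussian copula with truncated-normal marginals on
#' `[0, 100]`. So that the generated cohort *realises* the configured
#' moments -- the graded summary statistics of the emulated study -- the
#' marginal location/scale parameters are solved per gate so the truncated
#' normal has exactly the target mean and SD (truncation otherwise shifts
#' them: a marginal with mean 15.73 and SD 14.58 has ~14 % of its mass below
#' zero), and each pairwise latent correlation is root-found so the realised
#' Pearson correlation equals the configured one (the NORTA construction).
#' Calibration is deterministic and cached; it involves no user-seeded
#' randomness. LNA is the complement `100 - HNA`.
#'
#' @param config a [sim_config()].
#' @param n number of individuals to draw (defaults to the configured cohort
#'   size).
#' @param seed integer seed.
#' @return matrix (n x 4) with columns HNA, LNA, BONCATpos, PIpos, percent.
#' @export
draw_fraction_proportions <- function(config, n = config$n_individuals,
                                      seed = config$seed) {
  mu <- config$fraction_means[GATE_FRACTIONS]
  sd <- config$fraction_sds[GATE_FRACTIONS]
  corr <- config$fraction_corr
  check_corr_matrix(corr)
  if (all(sd == 0)) {          # degenerate copula: every draw is the mean
    out <- matrix(rep(mu, each = n), n, 3,
                  dimnames = list(NULL, GATE_FRACTIONS))
    return(cbind(HNA = out[, "HNA"], LNA = 100 - out[, "HNA"],
                 BONCATpos = out[, "BONCATpos"], PIpos = out[, "PIpos"]))
  }
  lat <- calibrate_truncated_copula(mu, sd, corr)
  fac <- psd_factor(lat$corr)
  with_seed(seed, {
    z <- matrix(stats::rnorm(3 * n), n, 3) %*% t(fac)
    out <- matrix(NA_real_, n, 3, dimnames = list(NULL, GATE_FRACTIONS))
    for (k in 1:3)
      out[, k] <- qtruncnorm(stats::pnorm(z[, k]),
                             lat$m[k], lat$s[k], 0, 100)
    cbind(HNA = out[, "HNA"], LNA = 100 - out[, "HNA"],
          BONCATpos = out[, "BONCATpos"], PIpos = out[, "PIpos"])
  })
}

# PSD factor (eigen, not Cholesky: completed correlation may be singular)
psd_factor <- function(corr) {
  ev <- eigen(corr, symmetric = TRUE)
  ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(corr))
}

# --- truncated-normal machinery (location m, scale s, bounds lo/hi) -------

truncnorm_moments <- function(m, s, lo = 0, hi = 100) {
  a <- (lo - m) / s; b <- (hi - m) / s
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  mean <- m + s * (da - db) / Z
  var <- s^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  c(mean = mean, sd = sqrt(max(var, 0)))
}

qtruncnorm <- function(u, m, s, lo = 0, hi = 100) {
  pa <- stats::pnorm(lo, m, s); pb <- stats::pnorm(hi, m, s)
  stats::qnorm(pa + u * (pb - pa), m, s)
}

# solve (m, s) so the [lo,hi]-truncated normal has the target mean and SD
solve_truncnorm_params <- function(target_mean, target_sd, lo = 0, hi = 100) {
  obj <- function(par) {
    mo <- truncnorm_moments(par[1], exp(par[2]), lo, hi)
    (mo["mean"] - target_mean)^2 + (mo["sd"] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  mo <- truncnorm_moments(fit$par[1], exp(fit$par[2]), lo, hi)
  if (abs(mo["mean"] - target_mean) > 1e-4 * (hi - lo) ||
      abs(mo["sd"] - target_sd) > 1e-3 * target_sd)
    stopf("no truncated normal on [%g, %g] has mean %.4g and SD %.4g",
          lo, hi, target_mean, target_sd)
  c(m = fit$par[1], s = exp(fit$par[2]))
}

# cache: latent parameters are a pure function of the targets
.trunc_cache <- new.env(parent = emptyenv())

# NORTA calibration: exact truncated-normal marginals plus pairwise latent
# correlations root-found (against a fixed-seed common-random-number panel)
# so the realised Pearson correlations equal the targets.
calibrate_truncated_copula <- function(mu, sd, corr, n_mc = 200000) {
  key <- paste(signif(c(mu, sd, corr), 10), collapse = ",")
  hit <- .trunc_cache[[key]]
  if (!is.null(hit)) return(hit)
  k <- length(mu)
  par <- vapply(seq_len(k), function(i)
    solve_truncnorm_params(mu[[i]], sd[[i]]), numeric(2))
  z <- with_seed(202400, matrix(stats::rnorm(2 * n_mc), n_mc, 2))
  lat <- diag(k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    target <- corr[i, j]
    if (abs(target) < 1e-12) next
    g_i <- qtruncnorm(stats::pnorm(z[, 1]), par["m", i], par["s", i])
    r_of <- function(rho) {
      w2 <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
      stats::cor(g_i, qtruncnorm(stats::pnorm(w2), par["m", j], par["s", j])) -
        target
    }
    lat[i, j] <- lat[j, i] <- stats::uniroot(r_of, c(-0.9999, 0.9999),
                                             tol = 1e-5)$root
  }
  # ensure the assembled latent matrix is a valid correlation matrix
  ev <- eigen(lat, symmetric = TRUE)
  if (min(ev$values) < 0) {
    lat <- ev$vectors %*% diag(pmax(ev$values, 1e-8)) %*% t(ev$vectors)
    d <- sqrt(diag(lat))
    lat <- lat / (d %o% d)
  }
  out <- list(m = par["m", ], s = par["s", ], corr = lat)
  .trunc_cache[[key]] <- out
  out
}

#' Calibrate an individual-level propensity offset
#'
#' Given one individual's taxon relative abundances `a_t` and per-taxon gate
#' propensities `theta_t`, finds the single additive logit-scale offset
#' `delta` such that the aggregate gate membership
#' `sum_t a_t * plogis(qlogis(theta_t) + delta)` equals the target percentage
#' `target_pi / 100`. The aggregate is strictly increasing in `delta`, so the
#' root is unique and found by bisection (via [stats::uniroot()]) to within
#' `1e-10`.
#'
#' @param abundance_row relative abundances summing to 1.
#' @param theta per-taxon propensities, strictly inside (0, 1).
#' @param target_pi target gate percentage in (0, 100).
#' @return the scalar offset `delta`.
#' @export
calibrate_propensities <- function(abundance_row, theta, target_pi) {
  if (abs(sum(abundance_row) - 1) > 1e-6)
    stopf("abundances must sum to 1")
  if (any(theta <= 0) || any(theta >= 1))
    stopf("propensities must lie strictly inside (0, 1)")
  if (target_pi <= 0 || target_pi >= 100)
    stopf("target percentage outside the reachable range (0, 100)")
  lt <- logit(theta)
  f <- function(d) sum(abundance_row * inv_logit(lt + d)) - target_pi / 100
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0) stopf("target percentage unreachable")
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}
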