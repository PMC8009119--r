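test_that("beta-binomial likelihood matches its oracles", {
  # numeric integration of the beta mixture
  for (case in list(c(y = 3, n = 10, mu = 0.3, phi = 0.1),
                    c(y = 0, n = 7, mu = 0.6, phi = 0.4),
                    c(y = 12, n = 15, mu = 0.8, phi = 0.05))) {
    a <- case["mu"] * (1 - case["phi"]) / case["phi"]
    b <- (1 - case["mu"]) * (1 - case["phi"]) / case["phi"]
    num <- integrate(function(p)
      dbinom(case["y"], case["n"], p) * dbeta(p, a, b), 0, 1,
      rel.tol = 1e-12)$value
    expect_equal(betabinom_loglik(case["y"], case["n"], case["mu"],
                                  case["phi"]),
                 log(num), tolerance = 1e-8, ignore_attr = TRUE)
  }
  # phi -> 0 limit is the binomial likelihood
  expect_equal(betabinom_loglik(3, 10, 0.3, 1e-8),
               dbinom(3, 10, 0.3, log = TRUE), tolerance = 1e-4)
  expect_equal(betabinom_loglik(0, 1, 0.25, 1e-8), log(0.75),
               tolerance = 1e-4)
  expect_error(betabinom_loglik(3, 10, 1.2, 0.1), "strictly inside")
  expect_error(betabinom_loglik(11, 10, 0.5, 0.1), "\\[0, n\\]")
})

test_that("beta-binomial fits recover simulation parameters", {
  set.seed(21)
  g <- rep(c("a", "b"), each = 20)
  y <- c(rbetabinom(20, 50, 0.6, 0.1), rbetabinom(20, 50, 0.8, 0.1))
  fit <- fit_betabinom_test(y, rep(50, 40), g)
  expect_lt(abs(fit$mu.a - 0.6), 0.05)
  expect_lt(abs(fit$mu.b - 0.8), 0.05)
  expect_lt(fit$p_abundance, 0.01)
  # all-zero taxon flagged as degenerate
  z <- fit_betabinom_test(rep(0, 8), rep(30, 8), rep(c("a", "b"), each = 4))
  expect_true(z$degenerate)
  expect_true(is.na(z$p_abundance))
})

test_that("dispersion LRT detects differential overdispersion", {
  set.seed(33)
  g <- rep(c("a", "b"), each = 30)
  y <- c(rbetabinom(30, 200, 0.4, 0.01), rbetabinom(30, 200, 0.4, 0.4))
  fit <- fit_betabinom_test(y, rep(200, 60), g)
  expect_lt(fit$p_dispersion, 0.01)
  expect_gt(fit$phi.b, fit$phi.a)
})

test_that("Kruskal-Wallis wrapper handles ties and degenerate input", {
  v <- c(1, 2, 3, 4, 5, 6, 2, 4, 6)
  g <- rep(c("A", "B", "C"), each = 3)
  kw <- kruskal_wallis(v, g)
  ref <- kruskal.test(v, factor(g))
  expect_equal(kw$H, unname(ref$statistic))
  expect_equal(kw$p, ref$p.value)
  # rank statistic is invariant to monotone transforms
  expect_equal(kruskal_wallis(exp(v), g)$H, kw$H)
  expect_equal(kruskal_wallis(rep(2, 6), rep(c("a", "b"), 3)),
               list(H = 0, p = 1, df = 1))
})

test_that("Dunn post hoc matches the hand-computed z statistics", {
  # groups A=(1,2,3), B=(4,5,6), C=(2,4,6): mean ranks 2.5, 7, 5.5;
  # three tied pairs give sum(t^3-t)=18, tie term 18/(12*8)=0.1875,
  # variance factor (7.5 - 0.1875) * 2/3 = 4.875
  v <- c(1, 2, 3, 4, 5, 6, 2, 4, 6)
  g <- rep(c("A", "B", "C"), each = 3)
  d <- dunn_posthoc(v, g)
  se <- sqrt(4.875)
  expect_equal(d$z, c(-4.5, -3, 1.5) / se, tolerance = 1e-12)
  expect_equal(d$p, 2 * pnorm(-abs(c(-4.5, -3, 1.5) / se)),
               tolerance = 1e-12)
  expect_equal(d$q, p.adjust(d$p, "BH"))
  # relabelling swaps signs, not p-values
  g2 <- rep(c("B", "A", "C"), each = 3)
  d2 <- dunn_posthoc(v, g2)
  expect_equal(d2$z[1], -d$z[1])
  expect_equal(sort(d2$p), sort(d$p))
})

test_that("Pearson test matches the covariance-formula oracle", {
  x <- c(1, 3, 4, 6, 8)
  y <- c(2, 3, 7, 8, 9)
  res <- pearson_test(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  t_stat <- r_hand * sqrt(3) / sqrt(1 - r_hand^2)
  expect_equal(res$p, 2 * pt(-abs(t_stat), df = 3), tolerance = 1e-12)
  expect_equal(pearson_test(1:5, 2 * (1:5) + 1)$r, 1)
  expect_equal(pearson_test(1:5, -(1:5))$r, -1)
  expect_error(pearson_test(1:5, rep(2, 5)), "constant")
})

test_that("ANOVA vs control reduces to t^2 with two groups", {
  set.seed(2)
  v <- c(rnorm(5, 0), rnorm(5, 1))
  g <- rep(c("Control", "Glucose"), each = 5)
  res <- anova_vs_control(v, g)
  tt <- t.test(v[g == "Glucose"], v[g == "Control"], var.equal = TRUE)
  expect_equal(res$anova$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$vs_control$treatment, "Glucose")
  expect_error(anova_vs_control(v, rep(c("a", "b"), each = 5)), "absent")
  # degenerate: no variance at all
  flat <- anova_vs_control(rep(3, 6), rep(c("Control", "Glucose"), each = 3))
  expect_equal(flat$vs_control$p, 1)
})

test_that("BH adjustment matches the step-up hand computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(5)
  p <- runif(20)
  q <- bh_adjust(p)
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-12))
  expect_true(all(q >= p - 1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
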