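test_that("spearman matches the d-squared formula on tie-free data", {
  r <- spearman(1:5, c(1, 3, 2, 5, 4))
  expect_equal(r$rho, 1 - 6 * 4 / (5 * 24))  # = 0.8
  expect_equal(spearman(1:10, 1:10)$rho, 1)
  expect_equal(spearman(1:10, 10:1)$rho, -1)
  set.seed(2)
  for (i in 1:20) {
    x <- sample(100, 30); y <- sample(1000, 30)
    d2 <- sum((rank(x) - rank(y))^2)
    expect_equal(spearman(x, y)$rho, 1 - 6 * d2 / (30 * (30^2 - 1)),
                 tolerance = 1e-12)
  }
  expect_error(spearman(c(1, 2), c(3, 4)), "fewer than 3")
  expect_error(spearman(rep(1, 5), 1:5), "zero variance")
})

test_that("rank statistics are invariant under strictly monotone transforms", {
  set.seed(3)
  x <- rnorm(40); y <- rnorm(40)
  expect_equal(spearman(exp(x), y)$rho, spearman(x, y)$rho)
  g <- list(rnorm(10), rnorm(12) + 1, rnorm(9) - 1)
  expect_equal(kruskal_wallis(lapply(g, exp))$H, kruskal_wallis(g)$H,
               tolerance = 1e-12)
})

test_that("partial spearman equals the closed-form partial correlation", {
  set.seed(4)
  for (i in 1:25) {
    x <- rnorm(50); y <- rnorm(50); z <- rnorm(50)
    res <- partial_spearman(x, y, z)
    rx <- rank(x); ry <- rank(y); rz <- rank(z)
    rxy <- cor(rx, ry); rxz <- cor(rx, rz); ryz <- cor(ry, rz)
    closed <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    expect_equal(res$rho, closed, tolerance = 1e-10)
  }
})

test_that("partial spearman handles degenerate covariates", {
  set.seed(5)
  x <- rnorm(30); y <- rnorm(30)
  expect_warning(res <- partial_spearman(x, y, rep(1, 30)), "zero rank")
  expect_equal(res$rho, spearman(x, y)$rho)
  # y = x with a non-collinear covariate gives rho 1
  expect_equal(partial_spearman(x, x + 0, rnorm(30))$rho, 1, tolerance = 1e-12)
  # rank-collinear covariate is refused
  expect_error(partial_spearman(x, y, x), "collinear")
})

test_that("residualization is orthogonal to the covariate", {
  set.seed(6)
  x <- rnorm(40); cov <- rnorm(40)
  r <- residualize_on(x, cov)
  expect_lt(abs(sum(r * cov)), 1e-10 * sd(x) * 40)
  expect_equal(residualize_on(2 * cov + 3, cov), rep(0, 40),
               tolerance = 1e-10)
  expect_warning(rc <- residualize_on(x, rep(2, 40)), "constant")
  expect_equal(rc, x - mean(x))
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.002)),
               c(0.02, 0.04, 0.04, 0.008))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  # adjusted values preserve the ordering of the raw p-values
  set.seed(1)
  p <- runif(25)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= 0))
  expect_true(all(q >= p) && all(q <= 1))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("Fisher z comparison of correlations", {
  eq <- fisher_z_compare(0.4, 50, 0.4, 80)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)
  r <- fisher_z_compare(0.5, 103, 0, 103)
  expect_equal(r$z, atanh(0.5) / sqrt(2 / 100), tolerance = 1e-12)
  expect_equal(round(r$z, 3), 3.884)
  expect_equal(fisher_z_compare(0, 103, 0.5, 103)$z, -r$z)
  expect_error(fisher_z_compare(1, 50, 0.2, 50), "< 1")
})

test_that("Kruskal-Wallis H matches hand ranks and degenerates to zero", {
  r <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(r$H, 32 / 7, tolerance = 1e-12)  # = 4.571
  expect_equal(r$df, 2)
  same <- kruskal_wallis(list(c(1, 2, 3), c(2, 3, 1)))
  expect_equal(same$H, 0, tolerance = 1e-12)
  expect_error(kruskal_wallis(list(rep(1, 3), rep(1, 4))), "identical")
})

test_that("Dunn post-hoc matches the brute-force mean-rank formula", {
  set.seed(7)
  g <- list(a = rnorm(8), b = rnorm(10) + 1, c = rnorm(6))
  d <- dunn_posthoc(g)
  expect_equal(nrow(d), 3L)  # k(k-1)/2
  pooled <- unlist(g)
  N <- length(pooled)
  rk <- rank(pooled)
  idx <- rep(1:3, lengths(g))
  mr <- tapply(rk, idx, mean)
  se_ab <- sqrt(N * (N + 1) / 12 * (1 / 8 + 1 / 10))
  expect_equal(d$z[d$group1 == "a" & d$group2 == "b"],
               unname((mr[1] - mr[2]) / se_ab), tolerance = 1e-12)
  # identical groups give z = 0
  twin <- dunn_posthoc(list(x = c(1, 2, 3), y = c(1, 2, 3)))
  expect_equal(twin$z, 0)
})

test_that("Mann-Whitney exact p and the U identity", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  set.seed(8)
  a <- rnorm(7); b <- rnorm(9)
  expect_equal(mann_whitney(a, b)$U + mann_whitney(b, a)$U, 7 * 9)
  same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$U, 16 / 2)
})

test_that("chi-squared without continuity correction", {
  r <- chi_squared(matrix(c(10, 20, 20, 10), nrow = 2))
  expect_equal(r$statistic, 20 / 3, tolerance = 1e-12)  # = 6.667
  expect_equal(chi_squared(matrix(c(10, 20, 30, 60), nrow = 2))$statistic, 0,
               tolerance = 1e-12)
  expect_equal(chi_squared(matrix(1:8, nrow = 2))$df, 3)
  expect_error(chi_squared(matrix(c(0, 0, 5, 5), nrow = 2)), "marginal")
})

test_that("OLS recovers exact coefficients and reports uniform null p", {
  x <- 1:20
  fit <- suppressWarnings(ols_fit(2 * x + 3, list(x = x)))  # exact fit
  expect_equal(unname(fit$coefficients["x"]), 2, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["(Intercept)"]), 3, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  set.seed(9)
  ps <- replicate(300, {
    y <- rnorm(40)
    ols_fit(y, list(x = rnorm(40)))$p_values[["x"]]
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_error(ols_fit(rnorm(10), list(a = 1:10, b = 2 * (1:10))),
               "rank-deficient")
})

test_that("a planted positive exhaustion effect is recovered in adjusted OLS", {
  # within fixed immune context, clonality raises exhaustion: beta +0.5
  set.seed(10)
  n <- 400
  immune <- rnorm(n)
  clonality <- -0.5 * immune + sqrt(0.75) * rnorm(n)
  tmb <- rnorm(n)
  exhaustion <- 2 * immune + 0.5 * clonality + 0.1 * tmb + rnorm(n, 0, 0.5)
  fit <- ols_fit(exhaustion, list(clonality = clonality, immune = immune,
                                  tmb = tmb))
  expect_gt(fit$coefficients[["clonality"]], 0)
  expect_lt(fit$p_values[["clonality"]], 0.01)
  # unadjusted association is negative (the confounded marginal)
  expect_lt(spearman(clonality, exhaustion)$rho, 0)
})

test_that("the correlation battery dispatches and shares one BH family", {
  set.seed(12)
  cohort <- data.frame(a = rnorm(60), b = rnorm(60), c = rnorm(60))
  one <- correlation_battery(cohort, data.frame(x = "a", y = "b"))
  expect_equal(one$q_value, one$p_value)
  spec <- data.frame(x = "a", y = c("b", "c"),
                     covariate = c(NA, "b"), stringsAsFactors = FALSE)
  res <- correlation_battery(cohort, spec)
  expect_equal(res$covariate, c("", "b"))
  expect_equal(res$rho[2], partial_spearman(cohort$a, cohort$c, cohort$b)$rho)
  expect_error(correlation_battery(cohort, data.frame(x = "a", y = "zz")),
               "unknown column")
})
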