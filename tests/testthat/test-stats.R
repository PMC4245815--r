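test_that("expression summaries log-normalize and measure breadth", {
  fpkm <- rbind(g1 = c(0, 0, 2, 8), g2 = c(0, 0, 0, 0), g3 = c(5, 5, 5, 5))
  es <- expression_summaries(fpkm)
  expect_equal(es$breadth, c(0.5, 0, 1))
  expect_equal(es$max_expr[1], log2(9))
  expect_equal(es$med_expr[1], (0 + log2(3)) / 2)
  expect_equal(es$max_expr[2], 0)
  # single tissue: max equals median
  one <- expression_summaries(matrix(3, 1, 1,
                                     dimnames = list("g1", "t1")))
  expect_equal(one$max_expr, one$med_expr)
  expect_error(expression_summaries(rbind(a = c(-1, 2))), "non-negative")
})

test_that("spearman correlation matches the rank-formula computation", {
  expect_equal(spearman(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman(1:10, -(1:10))$rho, -1)
  x <- c(3, 1, 4, 1.5, 9); y <- c(2, 7, 1, 8, 3)
  expect_equal(spearman(x, y)$rho, cor(rank(x), rank(y)))
})

test_that("partial correlation matches the recursive closed form", {
  set.seed(12)
  n <- 60
  z <- rnorm(n)
  df <- data.frame(x = z + rnorm(n), y = 0.5 * z + rnorm(n), z = z)
  pc <- partial_correlation(df, "x", "y", "z", method = "pearson")
  r <- cor(df)
  expect_equal(pc$rho, recursive_partial(r["x", "y"], r["x", "z"],
                                         r["y", "z"]),
               tolerance = 1e-12)
  # spearman flavour: same identity on ranks
  pcs <- partial_correlation(df, "x", "y", "z", method = "spearman")
  rs <- cor(apply(df, 2, rank))
  expect_equal(pcs$rho, recursive_partial(rs["x", "y"], rs["x", "z"],
                                          rs["y", "z"]),
               tolerance = 1e-12)
  # no controls: plain correlation
  pc0 <- partial_correlation(df, "x", "y", method = "pearson")
  expect_equal(pc0$rho, r["x", "y"], tolerance = 1e-12)
})

test_that("controlling for a shared driver removes its correlation", {
  set.seed(77)
  n <- 1000
  z <- rnorm(n)
  df <- data.frame(x = z + 0.8 * rnorm(n), y = z + 0.01 * rnorm(n),
                   z = z)
  expect_gt(abs(spearman(df$x, df$y)$rho), 0.5)
  expect_lt(abs(partial_correlation(df, "x", "y", "z")$rho), 0.05)
  # perfectly collinear controls are reported as singular
  df$z2 <- df$z
  expect_error(partial_correlation(df, "x", "y", c("z", "z2")), "singular")
})

test_that("the correlation report flags only the planted predictor", {
  set.seed(21)
  n <- 600
  tab <- data.frame(evolutionary_rate = NA, ese_density = runif(n),
                    max_expr = rnorm(n), breadth = runif(n))
  tab$evolutionary_rate <- -0.6 * tab$ese_density + rnorm(n, sd = 0.3)
  rep14 <- correlation_report(tab, family = 14)
  expect_true(rep14$significant[rep14$predictor == "ese_density"])
  expect_lt(rep14$partial_rho[rep14$predictor == "ese_density"], 0)
  expect_false(any(rep14$significant[rep14$predictor != "ese_density"]))
  # family size 1: adjusted threshold equals the raw 0.05 level
  rep1 <- correlation_report(tab, family = 1)
  expect_equal(rep1$significant, rep1$p < 0.05)
})

test_that("local regression is exact on lines and reduces to OLS", {
  set.seed(5)
  x <- sort(runif(40)); y <- 2 + 3 * x
  for (k in c("tricube", "epanechnikov", "gaussian", "uniform")) {
    fit <- loess_fit(x, y, span = 0.5, kernel = k)
    expect_lt(max(abs(fit$residuals)), 1e-10)
  }
  yn <- y + rnorm(40)
  fit_u <- loess_fit(x, yn, span = 1, degree = 1, kernel = "uniform")
  ols <- stats::lm(yn ~ x)
  expect_equal(fit_u$fitted, unname(fitted(ols)), tolerance = 1e-10)
  # deterministic
  expect_identical(loess_fit(x, yn, 0.4), loess_fit(x, yn, 0.4))
  expect_error(loess_fit(x[1:2], yn[1:2], span = 0.1), "span too small")
})

test_that("group residual comparison recovers a planted offset", {
  set.seed(9)
  n <- 120
  x <- runif(n, 0, 10)
  grp <- rep(c("active", "inactive"), length.out = n)
  y <- sin(x) + ifelse(grp == "active", 1, 0) + rnorm(n, sd = 0.3)
  res <- residual_group_comparison(x, y, grp)
  expect_equal(nrow(res), 4L)
  expect_true(all(res$median_diff > 0))
  expect_true(all(res$p_value < 0.01))
})

test_that("subsample correlation fractions hit their trivial bounds", {
  set.seed(2)
  x <- rnorm(200); y <- rnorm(200)
  expect_equal(subsample_correlation_fraction(x, y, 50, 50, -1.01,
                                              seed = 1)$fraction, 0)
  expect_equal(subsample_correlation_fraction(x, y, 50, 50, 1,
                                              seed = 1)$fraction, 1)
  r1 <- subsample_correlation_fraction(x, y, 50, 100, -0.05, seed = 7)
  r2 <- subsample_correlation_fraction(x, y, 50, 100, -0.05, seed = 7)
  expect_identical(r1, r2)
})

test_that("null subsample fractions match the normal approximation", {
  set.seed(3)
  n <- 2000; k <- 100
  x <- rnorm(n); y <- rnorm(n)
  res <- subsample_correlation_fraction(x, y, k, 400, -0.05, seed = 11)
  expected <- pnorm(-0.05 * sqrt(k - 1))
  expect_lt(abs(res$fraction - expected),
            3 * sqrt(expected * (1 - expected) / 400) + 0.02)
})

test_that("top-fraction filtering keeps the highest keys, stably", {
  tab <- data.frame(gene = letters[1:10], max_expr = c(5, 3, 8, 1, 9, 2,
                                                       7, 4, 6, 0))
  top <- top_fraction_filter(tab, "max_expr", 0.5)
  expect_equal(sort(top$max_expr), c(5, 6, 7, 8, 9))
  expect_identical(top_fraction_filter(tab, "max_expr", 1), tab)
})

test_that("the three-way interaction ANOVA detects a planted interaction", {
  set.seed(10)
  n <- 400
  mx <- rnorm(n); md <- rnorm(n); br <- rnorm(n)
  stab <- 0.5 * mx * md * br + rnorm(n, sd = 0.5)
  res <- ols_interaction_anova(stab, mx, md, br)
  expect_lt(res$p_value, 1e-6)
  expect_error(ols_interaction_anova(stab, mx, mx, br), "collinear")
})
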