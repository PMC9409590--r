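test_that("Kruskal-Wallis H matches the hand formula with tied ranks", {
  x <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  got <- kruskal_wallis(x, g)
  # identical distributions: rank sums equal, H = 0
  expect_equal(got$statistic, 0, tolerance = 1e-12)
  expect_equal(got$p_value, 1, tolerance = 1e-12)

  # brute-force H for {1,2} vs {3,4}: ranks 1..4, no ties
  x2 <- c(1, 2, 3, 4)
  g2 <- c("a", "a", "b", "b")
  r <- rank(x2)
  n <- 4
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, g2, function(ri) length(ri) *
                 (mean(ri) - (n + 1) / 2)^2))
  expect_equal(kruskal_wallis(x2, g2)$statistic, H, tolerance = 1e-12)

  # a strongly shifted group is detected
  set.seed(1)
  v <- c(rnorm(10), rnorm(10) + 10)
  expect_lt(kruskal_wallis(v, rep(c("a", "b"), each = 10))$p_value, 0.01)
})

test_that("pairwise Wilcoxon applies the Bonferroni multiplier", {
  set.seed(2)
  x <- c(rnorm(8), rnorm(8) + 5, rnorm(8))
  g <- rep(c("a", "b", "c"), each = 8)
  pw <- pairwise_wilcoxon_bonferroni(x, g)
  expect_equal(nrow(pw), 3)
  expect_equal(pw$p_value, pmin(1, pw$p_raw * 3))
  # identical groups cap at p = 1
  same <- pairwise_wilcoxon_bonferroni(rep(c(1, 2, 3), 2),
                                       rep(c("a", "b"), each = 3))
  expect_equal(same$p_value, 1)
  # small tie-free pair agrees with exact enumeration
  xa <- c(1.1, 2.2, 3.3)
  xb <- c(4.4, 5.5, 6.6)
  pw2 <- pairwise_wilcoxon_bonferroni(c(xa, xb), rep(c("a", "b"), each = 3))
  expect_equal(pw2$p_raw, 2 / choose(6, 3), tolerance = 1e-12)
})

test_that("Welch's ANOVA on ranks matches a hand computation", {
  x <- c(1, 2, 3, 4, 10, 20, 30, 40)
  g <- rep(c("a", "b"), each = 4)
  r <- rank(x)   # 1..8, no ties
  mt <- tapply(r, g, mean)
  vt <- tapply(r, g, var)
  nt <- tapply(r, g, length)
  w <- nt / vt
  mw <- sum(w * mt) / sum(w)
  k <- 2
  A <- sum(w * (mt - mw)^2) / (k - 1)
  lam <- sum((1 - w / sum(w))^2 / (nt - 1))
  Fw <- A / (1 + 2 * (k - 2) / (k^2 - 1) * lam)
  got <- welch_anova_ranks(x, g)
  expect_equal(got$statistic, Fw, tolerance = 1e-9)
  # identical groups of distinct values: F ~ 0
  sym <- welch_anova_ranks(c(1, 2, 3, 4, 1.5, 2.5, 3.5, 4.5),
                           rep(c("a", "b"), each = 4))
  expect_lt(sym$statistic, 0.5)
  expect_gt(sym$p_value, 0.5)
  expect_error(welch_anova_ranks(c(1, 1, 2, 3), rep(c("a", "b"), each = 2)),
               "zero within-group rank variance")
})

test_that("Games-Howell matches an independent textbook computation", {
  set.seed(3)
  x <- list(a = c(5.1, 6.2, 7.3, 5.8, 6.6),
            b = c(8.2, 9.9, 11.3, 10.4, 9.1),
            c = c(5.0, 5.4, 6.1, 5.9, 5.6))
  vals <- unlist(x)
  labs <- rep(names(x), lengths(x))
  got <- games_howell(vals, labs)
  # independent implementation straight from the formulas
  for (i in seq_len(nrow(got))) {
    g1 <- x[[got$group1[i]]]
    g2 <- x[[got$group2[i]]]
    se2 <- var(g1) / length(g1) + var(g2) / length(g2)
    tt <- abs(mean(g1) - mean(g2)) / sqrt(se2)
    df <- se2^2 / ((var(g1) / length(g1))^2 / (length(g1) - 1) +
                     (var(g2) / length(g2))^2 / (length(g2) - 1))
    p <- ptukey(tt * sqrt(2), nmeans = 3, df = df, lower.tail = FALSE)
    expect_equal(got$t[i], tt, tolerance = 1e-9)
    expect_equal(got$df[i], df, tolerance = 1e-9)
    expect_equal(got$p_value[i], p, tolerance = 1e-9)
  }
  expect_lt(got$p_value[got$group1 == "a" & got$group2 == "b"], 0.01)
  # near-identical groups: p near 1
  same <- games_howell(c(1, 2, 3, 4, 1.1, 2.1, 3.1, 4.1),
                       rep(c("a", "b"), each = 4))
  expect_gt(same$p_value, 0.9)
})

test_that("rank tests are invariant under monotone transformation", {
  set.seed(6)
  x <- rexp(30)
  g <- rep(c("a", "b", "c"), 10)
  for (f in list(function(z) z, log, function(z) z^3)) {
    expect_equal(kruskal_wallis(f(x), g)$statistic,
                 kruskal_wallis(x, g)$statistic, tolerance = 1e-12)
    expect_equal(welch_anova_ranks(f(x), g)$statistic,
                 welch_anova_ranks(x, g)$statistic, tolerance = 1e-12)
  }
})

test_that("the workflow helper picks the path the variance screen implies", {
  set.seed(8)
  hetero <- c(rnorm(15, sd = 0.2), rnorm(15, sd = 8))
  g <- rep(c("a", "b"), each = 15)
  ch <- choose_rank_test(hetero, g)
  expect_equal(ch$choice, "welch")
  homo <- c(rnorm(15), rnorm(15) + 1)
  ch2 <- choose_rank_test(homo, g)
  expect_equal(ch2$choice, "kruskal")
  # the screen itself agrees with the reference Levene implementation
  skip_if_not_installed("car")
  bf <- tunadiet:::brown_forsythe(hetero, g)
  lv <- car::leveneTest(hetero ~ factor(g), center = median)
  expect_equal(bf$statistic, lv$`F value`[1], tolerance = 1e-9)
  expect_equal(bf$p_value, lv$`Pr(>F)`[1], tolerance = 1e-9)
})

test_that("covariate correlations hit their closed-form anchors", {
  d <- tibble::tibble(a = 1:10, b = -(1:10), c = rnorm(10))
  cc <- covariate_correlations(d)
  expect_equal(unname(diag(cc)), rep(1, 3))
  expect_equal(cc["a", "b"], -1)
  set.seed(10)
  big <- tibble::tibble(x = rnorm(1000), y = rnorm(1000))
  expect_lt(abs(covariate_correlations(big)["x", "y"]), 0.1)
  # pairwise-complete handling of missing values
  d$a[3] <- NA
  expect_false(anyNA(covariate_correlations(d)))
})
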