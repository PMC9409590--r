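rand_comp <- function(n, g) {
  m <- matrix(rexp(n * g), n)
  m / rowSums(m)
}

test_that("node impurity matches the brute-force definition", {
  expect_equal(node_impurity(rbind(c(0.5, 0.5), c(0.5, 0.5))), 0)
  expect_equal(node_impurity(rbind(c(1, 0), c(0, 1))), 1)
  set.seed(5)
  for (i in 1:5) {
    m <- rand_comp(10, 4)
    expect_equal(node_impurity(m), oracle_impurity(m), tolerance = 1e-12)
  }
})

test_that("best_split equals the exhaustive-search oracle", {
  set.seed(11)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    Y <- rand_comp(n, sample(2:4, 1))
    X <- data.frame(a = sample(1:5, n, TRUE),
                    b = runif(n),
                    c = sample(2008:2016, n, TRUE))[, 1:sample(1:3, 1),
                                                    drop = FALSE]
    got <- best_split(Y, X, min_bucket = 1L)
    want <- oracle_best_split(Y, X, min_bucket = 1L)
    if (is.null(want) || want$decrease <= 1e-12) {
      expect_null(got)
    } else {
      expect_equal(got$var, want$var, label = sprintf("case %d var", i))
      expect_equal(got$threshold, want$threshold, tolerance = 1e-9)
      expect_equal(got$decrease, want$decrease, tolerance = 1e-9)
    }
  }
})

test_that("degenerate nodes do not split", {
  Y <- rbind(c(0.5, 0.5), c(0.5, 0.5), c(0.5, 0.5), c(0.5, 0.5))
  X <- data.frame(year = c(1, 2, 3, 4))
  expect_null(best_split(Y, X, min_bucket = 1L))
})

test_that("a clean two-group year split recovers the between-group SS", {
  Y <- rbind(matrix(rep(c(0.8, 0.2), 3), 3, byrow = TRUE),
             matrix(rep(c(0.1, 0.9), 3), 3, byrow = TRUE))
  X <- data.frame(year = c(2008, 2008, 2008, 2015, 2015, 2015))
  sp <- best_split(Y, X, min_bucket = 1L)
  expect_equal(sp$var, "year")
  expect_equal(sp$threshold, (2008 + 2015) / 2)
  # decrease equals total impurity (children are pure)
  expect_equal(sp$decrease, node_impurity(Y), tolerance = 1e-12)
})

test_that("surrogate agreement behaves at its extremes", {
  set.seed(3)
  n <- 40
  x <- rnorm(n)
  go_left <- x < 0
  X <- data.frame(x = x, same = x, indep = rnorm(n))
  s <- surrogate_splits(X, "x", go_left)
  vars <- vapply(s, `[[`, character(1), "var")
  expect_true("same" %in% vars)
  expect_equal(s[[which(vars == "same")]]$agreement, 1)
  # independent covariates rarely agree above the majority baseline; when
  # kept their agreement is small
  if ("indep" %in% vars)
    expect_lt(s[[which(vars == "indep")]]$agreement, 0.5)
  # a perfectly anti-aligned covariate is used with flipped orientation
  X2 <- data.frame(x = x, neg = -x)
  s2 <- surrogate_splits(X2, "x", go_left)
  expect_equal(s2[[1]]$var, "neg")
  expect_equal(s2[[1]]$agreement, 1)
  expect_false(s2[[1]]$left_if_yes)
})

test_that("tiny or pure inputs give a root-only tree", {
  st <- three_regime_fixture(seed = 2, n_stomachs = 30)
  dm <- diet_matrix(st)
  cov <- st$stomachs[, c("stomach_id", "year")]
  fit <- fit_diet_cart(dm[1:5, ], cov, control = cart_control(min_split = 20),
                       folds = 3, seed = 1)
  expect_equal(fit$selected$size, 1L)
  expect_equal(unique(fit$groups$group), "node_1")
  expect_true(all(variable_importance(fit) == 0))
})

test_that("shuffled-year null data prune back to the root", {
  set.seed(8)
  wins <- 0
  for (s in 1:5) {
    st <- three_regime_fixture(seed = 100 + s, n_stomachs = 120)
    dm <- diet_matrix(st)
    cov <- st$stomachs[, c("stomach_id", "year")]
    cov$year <- sample(cov$year)   # break the association
    fit <- fit_diet_cart(dm, cov, folds = 10, seed = s)
    wins <- wins + (fit$selected$size == 1L)
  }
  expect_gte(wins, 4)
})

test_that("the fixture recovers three year-split terminals", {
  st <- three_regime_fixture(seed = 77)
  fit <- diet_cart(st, folds = 10, seed = 77)
  td <- tidy(fit)
  splits <- td$split[!td$terminal]
  expect_equal(fit$selected$size, 3L)
  expect_true(all(grepl("^year", splits)))
  expect_equal(fit$importance[["year"]], 1)
  expect_lt(max(fit$importance[c("lat", "lon", "fl_cm")]), 0.2)
  # R-squared identity
  expect_equal(fit$r_squared, 1 - fit$selected$cv_error, tolerance = 1e-12)
  # cp table invariants: root relative error is 1, decreases are nested
  expect_equal(fit$cptable$rel_error[nrow(fit$cptable)], 1)
  expect_true(all(diff(fit$cptable$alpha) >= -1e-12))
  # assignment recovers the true regimes
  truth <- st$stomachs$regime[match(fit$groups$stomach_id,
                                    st$stomachs$stomach_id)]
  agreement <- sum(vapply(split(truth, fit$groups$group),
                          function(x) max(table(x)), numeric(1))) /
    length(truth)
  expect_gte(agreement, 0.95)
})

test_that("month surrogate routes stomachs with missing year", {
  st <- three_regime_fixture(seed = 31)
  # make month a deterministic proxy of the regime so it can stand in
  st$stomachs$month <- ifelse(st$stomachs$regime == "2008", 10,
                              ifelse(st$stomachs$regime == "2009-14", 6, 2))
  dm <- diet_matrix(st)
  cov <- st$stomachs[, c("stomach_id", "year", "month")]
  fit <- fit_diet_cart(dm, cov, folds = 10, seed = 31)
  td <- tidy(fit)
  surro <- td$surrogates[!td$terminal]
  expect_true(any(grepl("month", surro)))
  # drop year for a third of the stomachs: they still route to a terminal
  cov2 <- cov
  miss <- seq(1, nrow(cov2), by = 3)
  cov2$year[miss] <- NA
  asg <- assign_groups(fit, cov2)
  expect_false(any(is.na(asg$assignments$node_id)))
  # with the deterministic month proxy, routing matches the full-data one
  asg_full <- assign_groups(fit, cov)
  expect_gte(mean(asg$assignments$node_id == asg_full$assignments$node_id),
             0.95)
})

test_that("duplicated covariates share importance through surrogacy", {
  st <- three_regime_fixture(seed = 13, n_stomachs = 150)
  dm <- diet_matrix(st)
  cov <- st$stomachs[, c("stomach_id", "year")]
  cov$year_copy <- cov$year
  fit <- fit_diet_cart(dm, cov, folds = 10, seed = 13)
  imp <- fit$importance
  expect_equal(max(imp), 1)
  expect_gt(imp[["year"]], 0)
  expect_gt(imp[["year_copy"]], 0)
})

test_that("tidiers and prediction expose the fitted tree", {
  st <- three_regime_fixture(seed = 19, n_stomachs = 150)
  fit <- diet_cart(st, folds = 5, seed = 19)
  g <- glance(fit)
  expect_equal(g$n_leaves, fit$selected$size)
  td <- tidy(fit)
  expect_equal(sum(td$terminal), g$n_leaves)
  # child sizes sum to parent size at the root
  ch <- td$n[td$parent == 1 & !is.na(td$parent)]
  if (length(ch) == 2) expect_equal(sum(ch), td$n[td$node_id == 1])
  pred <- predict(fit)
  expect_equal(nrow(pred), g$n)
  expect_true(all(abs(rowSums(as.matrix(pred)) - 1) < 1e-9))
  expect_s3_class(autoplot(fit), "ggplot")
})
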