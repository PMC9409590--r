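pres_to_inc <- function(pres) {
  m <- pres * 1
  rownames(m) <- sprintf("u%d", seq_len(nrow(m)))
  colnames(m) <- sprintf("g%d", seq_len(ncol(m)))
  dm <- tibble::as_tibble(m)
  dm <- tibble::add_column(dm, stomach_id = rownames(m), .before = 1)
  incidence_freq(dm)
}

test_that("degenerate incidence patterns give the forced diversities", {
  # one group present in every unit
  inc1 <- pres_to_inc(matrix(1, 5, 1))
  expect_equal(hill_shannon(inc1, 1:5), rep(1, 5))
  # two groups with equal incidence at t = T
  inc2 <- pres_to_inc(cbind(rep(1, 4), rep(1, 4)))
  expect_equal(hill_shannon(inc2, 4), 2)
})

test_that("interpolated diversity equals the exhaustive subsample oracle", {
  set.seed(42)
  for (i in 1:10) {
    Tn <- sample(4:6, 1)
    G <- sample(2:5, 1)
    pres <- matrix(rbinom(Tn * G, 1, 0.6), Tn, G)
    pres[rowSums(pres) == 0, sample(G, 1)] <- 1
    pres <- pres[, colSums(pres) > 0, drop = FALSE]
    inc <- pres_to_inc(pres)
    for (t in 1:Tn) {
      expect_equal(hill_shannon(inc, t), oracle_hill_shannon(pres, t),
                   tolerance = 1e-9,
                   label = sprintf("case %d t=%d", i, t))
    }
  }
})

test_that("coverage matches its leave-one-out subsample oracle", {
  set.seed(7)
  for (i in 1:8) {
    Tn <- sample(4:6, 1)
    G <- sample(2:5, 1)
    pres <- matrix(rbinom(Tn * G, 1, 0.6), Tn, G)
    pres[rowSums(pres) == 0, sample(G, 1)] <- 1
    pres <- pres[, colSums(pres) > 0, drop = FALSE]
    inc <- pres_to_inc(pres)
    for (t in 1:(Tn - 1)) {
      expect_equal(sample_coverage(inc, t), oracle_coverage(pres, t),
                   tolerance = 1e-9,
                   label = sprintf("case %d t=%d", i, t))
    }
  }
})

test_that("coverage estimator hits its closed-form anchors", {
  # no singletons: complete coverage at t = T
  inc <- pres_to_inc(cbind(c(1, 1, 0, 0), c(0, 1, 1, 0), c(1, 1, 1, 1)))
  expect_equal(sample_coverage(inc, 4), 1)
  # singletons leave estimated coverage below 1
  inc2 <- pres_to_inc(cbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(1, 1, 1, 1)))
  expect_lt(sample_coverage(inc2, 4), 1)
})

test_that("diversity and coverage curves are monotone and bounded", {
  st <- three_regime_fixture(seed = 23, n_stomachs = 120)
  dm <- diet_matrix(st)
  for (rg in unique(st$stomachs$regime)) {
    ids <- st$stomachs$stomach_id[st$stomachs$regime == rg]
    inc <- incidence_freq(dm, ids)
    ts <- seq_len(2 * inc$T)
    qd <- suppressWarnings(hill_shannon(inc, ts))
    cv <- sample_coverage(inc, ts)
    expect_true(all(qd >= 1))
    expect_lte(max(qd[ts <= inc$T]), length(inc$Y))
    expect_true(all(diff(qd[ts <= inc$T]) > -1e-9))
    expect_true(all(diff(cv) > -1e-9))
    expect_true(all(cv >= 0 & cv <= 1))
  }
})

test_that("size_at_coverage scans the curve correctly", {
  inc <- pres_to_inc(cbind(c(1, 1, 1, 1), c(1, 1, 0, 0), c(0, 1, 1, 0)))
  t99 <- size_at_coverage(inc, 0.99)
  cv <- sample_coverage(inc, seq_len(2 * inc$T))
  expect_equal(t99, min(which(cv >= 0.99)))
  # an even community reaches a target coverage no later than an uneven one
  even <- pres_to_inc(matrix(1, 5, 3))
  skew <- pres_to_inc(cbind(rep(1, 5), c(1, 0, 0, 0, 0), c(0, 1, 0, 0, 0)))
  expect_lte(size_at_coverage(even, 0.9), size_at_coverage(skew, 0.9))
})

test_that("extrapolation warns beyond doubling and curves assemble", {
  inc <- pres_to_inc(cbind(c(1, 1, 0, 1), c(0, 1, 1, 0)))
  expect_warning(hill_shannon(inc, 9), "twice the sample size")
  st <- three_regime_fixture(seed = 24, n_stomachs = 90)
  dm <- diet_matrix(st)
  grp <- tibble::tibble(stomach_id = st$stomachs$stomach_id,
                        group = st$stomachs$regime)
  dc <- diversity_curve(dm, grp)
  expect_true(all(c("interpolated", "extrapolated") %in% dc$method))
  expect_s3_class(autoplot(dc), "ggplot")
})
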