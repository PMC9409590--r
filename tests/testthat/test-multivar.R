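comp_dm <- function(m) {
  rownames(m) <- sprintf("s%d", seq_len(nrow(m)))
  colnames(m) <- sprintf("g%d", seq_len(ncol(m)))
  dm <- tibble::as_tibble(m)
  tibble::add_column(dm, stomach_id = rownames(m), .before = 1)
}

test_that("Bray-Curtis has its defining values on compositions", {
  m <- rbind(c(0.5, 0.5), c(0.5, 0.5), c(1, 0), c(0, 1))
  D <- as.matrix(bray_curtis(comp_dm(m)))
  expect_equal(D[1, 2], 0)            # identical rows
  expect_equal(D[3, 4], 1)            # disjoint supports
  expect_equal(D[1, 3], 0.5)          # hand arithmetic
  expect_true(isSymmetric(D))
  expect_true(all(D >= 0 & D <= 1))
})

test_that("pseudo-F and exact p match full permutation enumeration", {
  set.seed(31)
  # 4-point toy, 2 + 2
  m <- rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.2, 0.8), c(0.1, 0.9))
  D <- bray_curtis(comp_dm(m))
  labs <- c("a", "a", "b", "b")
  got <- permanova(D, labs, exact = TRUE, pairwise = FALSE)
  want <- oracle_permanova_exact(D, labs)
  expect_equal(got$global$pseudo_F, want$F, tolerance = 1e-12)
  expect_equal(got$global$p_value, want$p, tolerance = 1e-12)
  # larger random instances up to n = 8, three groups
  for (i in 1:3) {
    n <- sample(6:8, 1)
    labs <- sample(rep(c("a", "b", "c"), length.out = n))
    while (min(table(labs)) < 2) labs <- sample(rep(c("a", "b", "c"),
                                                    length.out = n))
    m <- matrix(rexp(n * 3), n)
    m <- m / rowSums(m)
    D <- bray_curtis(comp_dm(m))
    got <- permanova(D, labs, exact = TRUE, pairwise = FALSE)
    want <- oracle_permanova_exact(D, labs)
    expect_equal(got$global$pseudo_F, want$F, tolerance = 1e-10)
    expect_equal(got$global$p_value, want$p, tolerance = 1e-10)
  }
})

test_that("pseudo-F agrees with an independent PERMANOVA implementation", {
  set.seed(4)
  m <- matrix(rexp(60), 20)
  m <- m / rowSums(m)
  labs <- rep(c("a", "b"), each = 10)
  D <- bray_curtis(comp_dm(m))
  got <- permanova(D, labs, n_perm = 99, pairwise = FALSE)
  ad <- vegan::adonis2(D ~ g, data = data.frame(g = labs), permutations = 99)
  expect_equal(got$global$pseudo_F, ad$F[1], tolerance = 1e-9)
})

test_that("well-separated clusters reach the minimal permutation p", {
  set.seed(9)
  m <- rbind(matrix(rep(c(0.98, 0.01, 0.01), 10), 10, byrow = TRUE),
             matrix(rep(c(0.01, 0.98, 0.01), 10), 10, byrow = TRUE))
  m <- m + matrix(runif(60, 0, 1e-3), 20)
  m <- m / rowSums(m)
  D <- bray_curtis(comp_dm(m))
  res <- permanova(D, rep(c("a", "b"), each = 10), n_perm = 199,
                   pairwise = FALSE, seed = 2)
  expect_equal(res$global$p_value, 1 / 200)
  expect_error(permanova(D, c("a", rep("b", 19)), pairwise = FALSE),
               "at least 2")
})

test_that("similarity summaries are percent complements of dissimilarity", {
  m <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  D <- bray_curtis(comp_dm(m))
  res <- permanova(D, c("a", "a", "b", "b"), n_perm = 19, pairwise = FALSE)
  sim <- res$similarity
  expect_equal(sim$mean_similarity_pct[sim$group1 == "a" &
                                         sim$group2 == "a"], 100)
  expect_equal(sim$mean_similarity_pct[sim$group1 == "a" &
                                         sim$group2 == "b"], 0)
})

test_that("permdisp detects dispersion differences, not location shifts", {
  set.seed(15)
  base <- matrix(rexp(40 * 4), 40)
  base <- base / rowSums(base)
  ctr <- colMeans(base)
  tight <- sweep(0.2 * sweep(base, 2, ctr), 2, ctr, "+")   # shrunk spread
  m <- rbind(base[1:20, ], tight[21:40, ])
  D <- stats::dist(m)
  res <- permdisp(D, rep(c("wide", "tight"), each = 20), n_perm = 199,
                  seed = 5)
  expect_lt(res$global$p_value, 0.05)
  expect_equal(nrow(res$pairwise), 1)
  expect_true(is.finite(res$pairwise$t))
  # centroid distances in flat geometry match direct computation
  x <- c(0, 1, 2, 10, 11, 12)
  Dl <- stats::dist(x)
  res2 <- permdisp(Dl, rep(c("a", "b"), each = 3), n_perm = 19, seed = 1)
  expect_equal(sort(unname(res2$model$distances[1:3])),
               sort(abs(x[1:3] - mean(x[1:3]))), tolerance = 1e-9)
})

test_that("PCoA reconstructs Euclidean geometry and reports negative axes", {
  # collinear points: one positive axis reproducing the line up to sign
  x <- c(0, 3, 7)
  p <- pcoa(stats::dist(x))
  expect_equal(sum(p$eigenvalues > 1e-9), 1)
  d_rec <- stats::dist(p$points$Axis1)
  expect_equal(as.numeric(d_rec), as.numeric(stats::dist(x)),
               tolerance = 1e-9)
  # any Euclidean-embeddable distance is reproduced exactly
  set.seed(2)
  m <- matrix(rnorm(30), 10)
  p2 <- pcoa(stats::dist(m))
  coords <- as.matrix(p2$points[, -1])
  expect_equal(as.numeric(stats::dist(coords)),
               as.numeric(stats::dist(m)), tolerance = 1e-8)
  # Bray-Curtis is semi-metric: negative eigenvalues reported, none used
  mm <- matrix(rexp(60), 20)
  mm <- mm / rowSums(mm)
  p3 <- pcoa(bray_curtis(comp_dm(mm)))
  expect_true(any(p3$eigenvalues < -1e-9))
  expect_equal(ncol(p3$points) - 1, sum(p3$eigenvalues >
                                          max(abs(p3$eigenvalues)) * 1e-9))
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)),
               class = "tunadiet_domain_error")
})
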