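test_that("proportional abundance is the within-stomach count fraction", {
  expect_equal(proportional_abundance(c(A = 2, B = 6)),
               tibble::tibble(group = c("A", "B"), p = c(0.25, 0.75)))
  one <- proportional_abundance(c(OnlyGroup = 7))
  expect_equal(one$p, 1)
  expect_error(proportional_abundance(c(A = 0)),
               class = "tunadiet_domain_error")
  # hand-enumerated three-stomach matrix
  st <- mini_stomachs(3)
  prey <- mini_prey(
    c("s01", "s01", "s02", "s03", "s03", "s03"),
    c("Myctophidae", "Engraulidae", "Myctophidae",
      "Engraulidae", "Engraulidae", "Munididae"),
    c("fish", "fish", "fish", "fish", "fish", "crustacean"),
    n_each = c(3, 1, 2, 1, 1, 2))
  study <- diet_study(st, prey)
  dm <- diet_matrix(study, lump_threshold = NULL)
  m <- as.matrix(dm[, -1])[order(dm$stomach_id), sort(colnames(dm)[-1])]
  expect_equal(unname(m),
               rbind(c(0.25, 0, 0.75),
                     c(0, 0, 1),
                     c(0.5, 0.5, 0)))
})

test_that("diet matrix rows sum to one and empty stomachs have no row", {
  st <- three_regime_fixture(seed = 14, n_stomachs = 80)
  dm <- diet_matrix(st)
  m <- as.matrix(dm[, -1])
  expect_true(all(abs(rowSums(m) - 1) < 1e-9))
  expect_true(all(m >= 0 & m <= 1))
  expect_false(any(st$stomachs$stomach_id[st$stomachs$is_empty] %in%
                     dm$stomach_id))
})

test_that("mean proportional abundance averages rows unweighted", {
  m <- tibble::tibble(stomach_id = c("a", "b"),
                      X = c(1, 0), Y = c(0, 1))
  class(m) <- c("diet_matrix", class(m))
  pb <- mean_proportional_abundance(m)
  expect_equal(pb$p_bar, c(0.5, 0.5))
  expect_equal(sum(pb$p_bar), 1)
  one <- mean_proportional_abundance(m, "a")
  expect_equal(one$p_bar, c(1, 0))
})

test_that("rare families lump into Other per broad group, unidentified never", {
  pb <- tibble::tibble(
    group = c("famA", "famB", "famC", "Unidentified fishes"),
    broad_group = c("fish", "fish", "cephalopod", "fish"),
    p_bar = c(0.02, 0.005, 0.009, 0.001))
  mp <- lump_rare_families(pb, 0.01)
  expect_equal(unname(mp[c("famA", "famB", "famC")]),
               c("famA", "Other fishes", "Other cephalopods"))
  expect_equal(unname(mp[["Unidentified fishes"]]), "Unidentified fishes")
  # all above threshold: identity
  pb$p_bar <- c(0.4, 0.3, 0.2, 0.1)
  expect_equal(unname(lump_rare_families(pb, 0.01)), pb$group)
  # exactly at the threshold is lumped (strictly-greater survives)
  pb$p_bar <- c(0.01, 0.5, 0.39, 0.1)
  expect_equal(unname(lump_rare_families(pb, 0.01)[["famA"]]),
               "Other fishes")
})

test_that("percent_N and percent_FO satisfy their accounting identities", {
  st <- three_regime_fixture(seed = 9, n_stomachs = 100)
  pn <- percent_N(st, "regime")
  sums <- tapply(pn$pct_N, pn$group, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  fo <- percent_FO(st, "regime")
  expect_true(all(fo$pct_FO > 0 & fo$pct_FO <= 100))
  expect_true(all(fo$occ <= fo$n_stomachs))
  ne <- table(st$stomachs$regime[!st$stomachs$is_empty])
  expect_equal(unname(fo$n_stomachs[match(names(ne), fo$group)]),
               as.vector(ne))
  # single prey item in its own group
  st2 <- diet_study(mini_stomachs(1),
                    mini_prey("s01", "Munididae", "crustacean"))
  pn2 <- percent_N(st2, "year")
  fo2 <- percent_FO(st2, "year")
  expect_equal(pn2$pct_N, 100)
  expect_equal(fo2$pct_FO, 100)
})

test_that("diet_summary joins %N and %FO per taxon", {
  st <- three_regime_fixture(seed = 9, n_stomachs = 60)
  ds <- diet_summary(st, "regime")
  expect_true(all(c("pct_N", "pct_FO", "n", "occ") %in% names(ds)))
  expect_true(all(ds$occ <= ds$n))
})
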