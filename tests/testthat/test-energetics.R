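test_that("hard-part lengths follow the resolved regression", {
  st <- mini_stomachs(1)
  prey <- mini_prey("s01", "Myctophidae", "fish",
                    measurement_kind = "hard_part", measured_value_mm = 3)
  study <- diet_study(st, prey, regressions = mini_regressions())
  study <- hardpart_lengths(study, quiet = TRUE)
  expect_equal(study$prey$length_mm, 30)          # linear a=0, b=10
  expect_equal(study$prey$length_source, "hardpart_regression")
  # taxon without a regression stays unmeasured and is reported
  prey2 <- mini_prey("s01", "Gonatidae", "cephalopod",
                     measurement_kind = "hard_part", measured_value_mm = 3)
  study2 <- diet_study(st, prey2, regressions = mini_regressions())
  expect_message(study2 <- hardpart_lengths(study2), "unmeasured")
  expect_true(is.na(study2$prey$length_mm))
})

test_that("unidentified squid beaks average over all cephalopod regressions", {
  reg <- validate_regressions(tibble::tibble(
    scope_level = "family",
    scope_value = c("Gonatidae", "Loliginidae"),
    kind = "hardpart_to_length", form = "linear",
    a = 0, b = c(10, 20), input_unit = "mm", output_unit = "mm"))
  st <- mini_stomachs(1)
  prey <- dplyr::bind_rows(
    mini_prey("s01", "Gonatidae", "cephalopod"),
    mini_prey("s01", "Loliginidae", "cephalopod"),
    mini_prey("s01", "Unidentified squids", "cephalopod",
              measurement_kind = "hard_part", measured_value_mm = 2))
  prey$prey_id <- c("p1", "p2", "p3")
  study <- diet_study(st, prey, regressions = reg)
  study <- hardpart_lengths(study, quiet = TRUE)
  expect_equal(study$prey$length_mm[3], mean(c(20, 40)))
})

test_that("length imputation follows the stomach > year > group hierarchy", {
  st <- mini_stomachs(2, year = c(2010, 2010))
  prey <- mini_prey(c("s01", "s01", "s01"), "Myctophidae", "fish",
                    measurement_kind = c("whole_length", "whole_length",
                                         "unmeasured"),
                    measured_value_mm = c(40, 60, NA))
  study <- diet_study(st, prey, regressions = mini_regressions())
  grp <- tibble::tibble(stomach_id = c("s01", "s02"), group = "g1")
  study <- reconstruct_prey(study, grp, quiet = TRUE)
  expect_equal(study$prey$length_mm[3], 50)
  expect_equal(study$prey$length_source[3], "imputed_stomach")
  # all measured: nothing changes
  study2 <- diet_study(mini_stomachs(1),
                       mini_prey("s01", "Myctophidae", "fish",
                                 measurement_kind = "whole_length",
                                 measured_value_mm = 42),
                       regressions = mini_regressions())
  study2 <- impute_lengths(hardpart_lengths(study2, quiet = TRUE),
                           grp, quiet = TRUE)
  expect_equal(study2$prey$length_mm, 42)
  expect_equal(study2$prey$length_source, "measured")
})

test_that("imputation precedence matches the 8-pattern oracle", {
  # donors placed at (same stomach / same year / same group) according to
  # each presence pattern; recipient sits in stomach s01, year 2010, group gA
  for (mask in 0:7) {
    has_stomach <- bitwAnd(mask, 1L) > 0
    has_year <- bitwAnd(mask, 2L) > 0
    has_group <- bitwAnd(mask, 4L) > 0
    st <- tibble::tibble(
      stomach_id = c("s01", "s02", "s03"),
      year = c(2010, if (has_year) 2010 else 2011, 2012))
    grp <- tibble::tibble(stomach_id = c("s01", "s02", "s03"),
                          group = c("gA", "gB", if (has_group) "gA" else "gC"))
    donors <- list()
    if (has_stomach)
      donors$a <- mini_prey("s01", "Myctophidae", "fish",
                            measurement_kind = "whole_length",
                            measured_value_mm = 40)
    donors$b <- mini_prey("s02", "Myctophidae", "fish",
                          measurement_kind = "whole_length",
                          measured_value_mm = 70)
    donors$c <- mini_prey("s03", "Myctophidae", "fish",
                          measurement_kind = "whole_length",
                          measured_value_mm = 90)
    rec <- mini_prey("s01", "Myctophidae", "fish")
    prey <- dplyr::bind_rows(c(donors, list(rec)))
    prey$prey_id <- sprintf("p%d", seq_len(nrow(prey)))
    study <- diet_study(st, prey, regressions = mini_regressions())
    study <- hardpart_lengths(study, quiet = TRUE)
    study <- impute_lengths(study, grp, quiet = TRUE)
    got <- study$prey$length_source[nrow(prey)]
    expected <- oracle_imputation_level(has_stomach, has_year, has_group)
    expect_equal(got, expected, label = sprintf("pattern %d source", mask))
    expected_val <- if (has_stomach) 40 else if (has_year) 70 else
      if (has_group) 90 else NA_real_
    expect_equal(study$prey$length_mm[nrow(prey)], expected_val,
                 label = sprintf("pattern %d value", mask))
  }
})

test_that("mass conversion uses the beak route for cephalopods", {
  reg <- validate_regressions(tibble::tibble(
    scope_level = c("family", "family", "family"),
    scope_value = c("Gonatidae", "Gonatidae", "Myctophidae"),
    kind = c("beak_to_mass", "length_to_mass", "length_to_mass"),
    form = "power",
    a = c(2, 0.5, 0.01), b = c(2, 3, 3),
    input_unit = "mm", output_unit = "g"))
  st <- mini_stomachs(1)
  prey <- dplyr::bind_rows(
    mini_prey("s01", "Gonatidae", "cephalopod",
              measurement_kind = "hard_part", measured_value_mm = 3),
    mini_prey("s01", "Myctophidae", "fish",
              measurement_kind = "whole_length", measured_value_mm = 10))
  prey$prey_id <- c("p1", "p2")
  study <- diet_study(st, prey, regressions = reg)
  study <- hardpart_lengths(study, quiet = TRUE)
  study$prey$length_mm[1] <- 99   # a length is present but the beak wins
  study <- prey_mass(study, quiet = TRUE)
  expect_equal(study$prey$mass_g[1], 2 * 3^2)
  expect_equal(study$prey$mass_g[2], 0.01 * 10^3)  # 10 g
  # non-positive length is rejected
  study$prey$mass_g <- NA_real_
  study$prey$length_mm[2] <- 0
  study$prey$measurement_kind[2] <- "unmeasured"
  study$prey$measured_value_mm[2] <- NA_real_
  expect_error(prey_mass(study, quiet = TRUE),
               class = "tunadiet_domain_error")
})

test_that("energy densities fall back and average for unidentified prey", {
  en <- validate_energy_densities(tibble::tibble(
    scope_level = c("species", "family"),
    scope_value = c("Alpha beta", "Myctophidae"),
    kj_per_g = c(5, 6)))
  st <- mini_stomachs(1)
  prey <- dplyr::bind_rows(
    mini_prey("s01", "Engraulidae", "fish", species = "Alpha beta"),
    mini_prey("s01", "Myctophidae", "fish", species = "Gamma delta"),
    mini_prey("s01", "Unidentified fishes", "fish"))
  prey$prey_id <- c("p1", "p2", "p3")
  study <- diet_study(st, prey, energy = en)
  study$prey$mass_g <- 10
  grp <- tibble::tibble(stomach_id = "s01", group = "g1")
  study <- prey_energy(study, grp, quiet = TRUE)
  expect_equal(study$prey$energy_kJ[1], 50)   # species density
  expect_equal(study$prey$energy_kJ[2], 60)   # family fallback
  expect_equal(study$prey$energy_kJ[3], 10 * mean(c(5, 6)))  # year mean
})

test_that("the body-mass filter is strict at the 3% boundary", {
  st <- mini_stomachs(3)
  st$mass_kg <- 10
  prey <- mini_prey(c("s01", "s02", "s03"), "Engraulidae", "fish")
  study <- diet_study(st, prey)
  study$prey$mass_g <- c(350, 250, 300)
  tot <- stomach_totals(study, quiet = TRUE)
  tot <- tot[order(tot$stomach_id), ]
  expect_equal(tot$pct_body_mass, c(3.5, 2.5, 3.0))
  expect_equal(tot$excluded, c(TRUE, FALSE, FALSE))
  expect_equal(tot$exclusion_reason[1], "over_bm_threshold")
  # missing predator size is its own category
  st$mass_kg <- c(10, NA, 10)
  study2 <- diet_study(st, prey)
  study2$prey$mass_g <- 100
  tot2 <- stomach_totals(study2, quiet = TRUE)
  expect_equal(tot2$exclusion_reason[order(tot2$stomach_id)][2],
               "no_predator_size")
})

test_that("stomach totals are additive over prey", {
  st <- three_regime_fixture(seed = 17, n_stomachs = 60)
  st <- derive_predator_size(st, quiet = TRUE)
  grp <- tibble::tibble(stomach_id = st$stomachs$stomach_id,
                        group = st$stomachs$regime)
  st <- reconstruct_prey(st, grp, quiet = TRUE)
  tot <- stomach_totals(st, quiet = TRUE)
  by_hand <- tapply(st$prey$mass_g, st$prey$stomach_id,
                    function(x) sum(x, na.rm = TRUE))
  expect_equal(tot$total_mass_g,
               as.numeric(by_hand[tot$stomach_id]))
  expect_equal(sum(tot$total_energy_kJ),
               sum(st$prey$energy_kJ, na.rm = TRUE))
})
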