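# Synthetic stomach-content generator.
#
# Emulates the statistical structure of a multi-year tuna stomach-sampling
# programme: temporal regimes with distinct family-level diet compositions,
# ~25% empty stomachs, overdispersed per-stomach prey totals (negative
# binomial), per-stomach Dirichlet perturbation of the regime composition
# (within-regime dietary heterogeneity), taxon-specific lognormal prey
# lengths, partial measurement (whole lengths, hard parts, unmeasured), and
# predator fork lengths uniform within a regime-specific range. Hard-part
# values are fabricated by inverting the supplied hard-part regressions, so
# reconstruction is exactly invertible, and per-prey true lengths, masses
# and energies are emitted as a hidden ground-truth table for recovery
# experiments.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) g <- alpha
  g / sum(g)
}

# Zero-truncated negative binomial: prey totals of non-empty stomachs.
rztnbinom <- function(n, mu, size) {
  p0 <- stats::pnbinom(0, mu = mu, size = size)
  u <- runif(n, min = p0, max = 1)
  qnbinom(u, mu = mu, size = size)
}

#' Reference prey taxonomy for the synthetic generator
#'
#' Eighteen forage taxa spanning the fish, cephalopod and crustacean prey of
#' juvenile bluefin in the Southern California Bight, with lognormal length
#' parameters (mm; standard length for fishes, mantle length for
#' cephalopods, total length for crustaceans) chosen so typical prey are
#' shorter than 10 cm. Hyperiid amphipods are grouped at suborder level
#' (family label `"Hyperiidea"`).
#'
#' @return Tibble with columns `taxon_id`, `broad_group`, `family`, `genus`,
#'   `species`, `meanlog`, `sdlog`.
#' @export
default_taxa <- function() {
  tribble_ <- function(...) tibble::tribble(...)
  tribble_(
    ~taxon_id, ~broad_group, ~family, ~genus, ~species, ~meanlog, ~sdlog,
    "t_mexicanus", "fish", "Myctophidae", "Triphoturus", "Triphoturus mexicanus", log(40), 0.25,
    "c_townsendi", "fish", "Myctophidae", "Ceratoscopelus", "Ceratoscopelus townsendi", log(45), 0.25,
    "e_mordax", "fish", "Engraulidae", "Engraulis", "Engraulis mordax", log(90), 0.20,
    "s_sagax", "fish", "Clupeidae", "Sardinops", "Sardinops sagax", log(120), 0.20,
    "t_symmetricus", "fish", "Carangidae", "Trachurus", "Trachurus symmetricus", log(60), 0.30,
    "sebastes", "fish", "Sebastidae", "Sebastes", "Sebastes sp.", log(35), 0.30,
    "c_saira", "fish", "Scomberesocidae", "Cololabis", "Cololabis saira", log(110), 0.25,
    "s_japonicus", "fish", "Scombridae", "Scomber", "Scomber japonicus", log(90), 0.30,
    "abraliopsis", "cephalopod", "Enoploteuthidae", "Abraliopsis", "Abraliopsis sp.", log(30), 0.25,
    "gonatus", "cephalopod", "Gonatidae", "Gonatus", "Gonatus sp.", log(35), 0.30,
    "d_opalescens", "cephalopod", "Loliginidae", "Doryteuthis", "Doryteuthis opalescens", log(70), 0.30,
    "octopoteuthis", "cephalopod", "Octopoteuthidae", "Octopoteuthis", "Octopoteuthis sp.", log(40), 0.30,
    "o_borealijaponica", "cephalopod", "Onychoteuthidae", "Onychoteuthis", "Onychoteuthis borealijaponica", log(50), 0.30,
    "o_rubescens", "cephalopod", "Octopodidae", "Octopus", "Octopus rubescens", log(30), 0.30,
    "argonauta", "cephalopod", "Argonautidae", "Argonauta", "Argonauta sp.", log(25), 0.30,
    "hyperiidea", "crustacean", "Hyperiidea", NA, NA, log(15), 0.30,
    "phronima", "crustacean", "Hyperiidea", "Phronima", "Phronima sp.", log(20), 0.30,
    "p_planipes", "crustacean", "Munididae", "Pleuroncodes", "Pleuroncodes planipes", log(60), 0.20)
}

#' Synthetic allometric and energetic conversion tables
#'
#' Family-level hard-part-to-length and length-to-mass regressions, derived
#' beak-to-mass regressions for cephalopods (composed so that the beak route
#' and the length route give identical masses), predator operculum-to-fork
#' length and fork-length-to-mass conversions, and species-level energy
#' densities. Coefficients are round numbers of realistic magnitude; they
#' parameterise the generator and are also what the reconstruction stage
#' resolves, which is what makes recovery experiments exact.
#'
#' @param taxa Taxonomy tibble as from [default_taxa()].
#' @return A list with elements `regressions` and `energy`.
#' @export
default_synth_conversions <- function(taxa = default_taxa()) {
  fams <- unique(taxa[, c("family", "broad_group")])
  hp_b <- c(fish = 25, cephalopod = 12, crustacean = 2.5)
  lm_a <- c(fish = 1e-5, cephalopod = 8e-5, crustacean = 2e-5)
  lm_b <- c(fish = 3.0, cephalopod = 2.9, crustacean = 3.0)
  hard <- tibble::tibble(
    scope_level = "family", scope_value = fams$family,
    kind = "hardpart_to_length", form = "linear",
    a = 0, b = unname(hp_b[fams$broad_group]),
    input_unit = "mm", output_unit = "mm")
  mass <- tibble::tibble(
    scope_level = "family", scope_value = fams$family,
    kind = "length_to_mass", form = "power",
    a = unname(lm_a[fams$broad_group]), b = unname(lm_b[fams$broad_group]),
    input_unit = "mm", output_unit = "g")
  cfam <- fams$family[fams$broad_group == "cephalopod"]
  # beak_to_mass = length_to_mass(hardpart_to_length(beak)):
  # mass = a_m * (b_h * beak)^b_m
  beak <- tibble::tibble(
    scope_level = "family", scope_value = cfam,
    kind = "beak_to_mass", form = "power",
    a = lm_a[["cephalopod"]] * hp_b[["cephalopod"]]^lm_b[["cephalopod"]],
    b = lm_b[["cephalopod"]],
    input_unit = "mm", output_unit = "g")
  predator <- tibble::tibble(
    scope_level = "predator", scope_value = "tuna",
    kind = c("ol_to_fl", "fl_to_mass"), form = c("linear", "power"),
    a = c(0, 2e-5), b = c(4.8, 3),
    input_unit = "cm", output_unit = c("cm", "kg"))
  regressions <- validate_regressions(
    dplyr::bind_rows(hard, mass, beak, predator))
  kj <- c(t_mexicanus = 7.0, c_townsendi = 7.0, e_mordax = 6.5, s_sagax = 7.5,
          t_symmetricus = 5.5, sebastes = 4.5, c_saira = 6.5,
          s_japonicus = 6.0, abraliopsis = 4.5, gonatus = 4.0,
          d_opalescens = 4.0, octopoteuthis = 3.5, o_borealijaponica = 4.5,
          o_rubescens = 4.5, argonauta = 3.5, hyperiidea = 3.0,
          phronima = 3.0, p_planipes = 4.0)
  energy <- validate_energy_densities(tibble::tibble(
    scope_level = ifelse(is.na(taxa$species), "family", "species"),
    scope_value = ifelse(is.na(taxa$species), taxa$family, taxa$species),
    kj_per_g = unname(kj[taxa$taxon_id])))
  energy <- dplyr::distinct(energy)
  list(regressions = regressions, energy = energy)
}

#' Define a sampling regime
#'
#' A regime is a block of sampling years with a common diet composition and
#' sampling intensity; the default study conditions use three regimes with
#' distinct family-level compositions.
#'
#' @param label Regime name.
#' @param years Integer vector of collection years the regime spans.
#' @param n_stomachs Number of stomachs sampled (including empty ones).
#' @param composition Named probability vector over `taxon_id`s; must sum
#'   to 1.
#' @param count_mean,count_dispersion Mean and negative-binomial size
#'   parameter of the per-stomach prey total (totals are overdispersed in
#'   real stomach data).
#' @param empty_fraction Probability a stomach is empty.
#' @param concentration Dirichlet concentration of the per-stomach
#'   composition about the regime composition; smaller values give more
#'   heterogeneous individual diets.
#' @param measured_fraction Probability a prey item carries a usable
#'   measurement (whole length or hard part).
#' @param hardpart_fraction Among measured prey, probability the measurement
#'   is a hard part rather than a whole length. Measured cephalopods are
#'   always represented by beaks.
#' @param predator_fl_range Fork-length range (cm), sampled uniformly.
#' @param month_mean,month_sd Collection month distribution (normal, rounded
#'   and clamped to 1-12); regime-specific means induce the month-year
#'   correlation seen in seasonal fisheries sampling.
#' @param ol_only_fraction Fraction of stomachs for which only the operculum
#'   length was recorded (fork length then derives from it).
#' @return A list with class `"regime_spec"`.
#' @export
regime_spec <- function(label, years, n_stomachs, composition,
                        count_mean, count_dispersion = 1.5,
                        empty_fraction = 0.25, concentration = 3,
                        measured_fraction = 0.3, hardpart_fraction = 0.5,
                        predator_fl_range = c(60, 120),
                        month_mean = 7, month_sd = 1.5,
                        ol_only_fraction = 0.1) {
  if (abs(sum(composition) - 1) > 1e-9)
    abort(sprintf("regime '%s': composition must sum to 1", label))
  fr <- c(empty_fraction, measured_fraction, hardpart_fraction,
          ol_only_fraction)
  if (any(fr < 0 | fr > 1))
    abort(sprintf("regime '%s': fractions must lie in [0, 1]", label))
  structure(list(label = label, years = as.integer(years),
                 n_stomachs = as.integer(n_stomachs),
                 composition = composition, count_mean = count_mean,
                 count_dispersion = count_dispersion,
                 empty_fraction = empty_fraction,
                 concentration = concentration,
                 measured_fraction = measured_fraction,
                 hardpart_fraction = hardpart_fraction,
                 predator_fl_range = predator_fl_range,
                 month_mean = month_mean, month_sd = month_sd,
                 ol_only_fraction = ol_only_fraction),
            class = "regime_spec")
}

#' Default three-regime study conditions
#'
#' The regimes mirror the structure of the 2008-2016 Southern California
#' Bight sampling: a 2008 regime dominated by myctophids and enoploteuthid
#' squids (mean 22.7 prey per stomach, tight within-regime composition), a
#' diverse 2009-2014 regime with hyperiid amphipods at 0.22 mean
#' proportional abundance and the highest per-stomach totals (mean 34.4),
#' and a 2015-2016 regime dominated by pelagic red crab (0.52) and northern
#' anchovy (0.14) with mean 20.1 prey per stomach. Stomach numbers are
#' allocated 88:439:194 across regimes; 25% of stomachs are empty.
#'
#' @param n_stomachs Total stomachs across regimes.
#' @return List of three [regime_spec()]s.
#' @export
default_regimes <- function(n_stomachs = 300) {
  alloc <- round(n_stomachs * c(88, 439, 194) / 721)
  alloc[3] <- n_stomachs - alloc[1] - alloc[2]
  comp1 <- c(abraliopsis = 0.29, t_mexicanus = 0.22, c_townsendi = 0.14,
             hyperiidea = 0.08, gonatus = 0.05, o_borealijaponica = 0.05,
             d_opalescens = 0.03, sebastes = 0.04, t_symmetricus = 0.03,
             c_saira = 0.02, s_sagax = 0.02, o_rubescens = 0.03)
  comp2 <- c(hyperiidea = 0.20, phronima = 0.02, gonatus = 0.08,
             d_opalescens = 0.07, octopoteuthis = 0.05,
             o_borealijaponica = 0.06, o_rubescens = 0.06, argonauta = 0.04,
             abraliopsis = 0.02, t_symmetricus = 0.13, sebastes = 0.08,
             s_japonicus = 0.06, c_saira = 0.04, s_sagax = 0.03,
             e_mordax = 0.04, t_mexicanus = 0.01, c_townsendi = 0.01)
  comp3 <- c(p_planipes = 0.52, e_mordax = 0.14, sebastes = 0.06,
             s_sagax = 0.05, d_opalescens = 0.05, hyperiidea = 0.05,
             t_symmetricus = 0.04, o_borealijaponica = 0.03, gonatus = 0.03,
             s_japonicus = 0.02, c_saira = 0.01)
  list(
    regime_spec("2008", 2008L, alloc[1], comp1, count_mean = 22.7,
                concentration = 12, predator_fl_range = c(61, 93),
                month_mean = 8.5),
    regime_spec("2009-14", 2009:2014, alloc[2], comp2, count_mean = 34.4,
                concentration = 4, predator_fl_range = c(42, 174),
                month_mean = 7),
    regime_spec("2015-16", 2015:2016, alloc[3], comp3, count_mean = 20.1,
                concentration = 8, predator_fl_range = c(50, 150),
                month_mean = 6))
}

#' Simulate a stomach-content study
#'
#' @param regimes List of [regime_spec()]s.
#' @param seed Integer seed; the same seed always yields the same study.
#' @param taxa Taxonomy tibble, see [default_taxa()].
#' @param conversions Regression and energy tables, see
#'   [default_synth_conversions()].
#' @return A [diet_study()] with `regressions`, `energy` and a hidden
#'   ground-truth table `truth` (`prey_id`, `true_length_mm`, `true_mass_g`,
#'   `true_energy_kJ`, plus the regime label per stomach in
#'   `stomachs$regime`).
#' @export
simulate_diet_study <- function(regimes, seed, taxa = default_taxa(),
                                conversions = default_synth_conversions(taxa)) {
  if (length(regimes) == 0) abort("at least one regime is required")
  reg <- conversions$regressions
  en <- conversions$energy
  taxa_idx <- split(taxa, taxa$taxon_id)

  with_seed(seed, {
    st_list <- list()
    prey_list <- list()
    sid <- 0L
    pid <- 0L
    for (rg in regimes) {
      comp_taxa <- names(rg$composition)
      missing_taxa <- setdiff(comp_taxa, taxa$taxon_id)
      if (length(missing_taxa) > 0)
        abort(sprintf("regime '%s' references unknown taxa: %s", rg$label,
                      paste(missing_taxa, collapse = ", ")))
      n <- rg$n_stomachs
      ids <- sprintf("S%04d", sid + seq_len(n))
      sid <- sid + n
      year <- sample(rep(rg$years, length.out = max(n, length(rg$years))), n)
      month <- pmin(12L, pmax(1L, as.integer(round(
        rnorm(n, rg$month_mean, rg$month_sd)))))
      fl <- runif(n, rg$predator_fl_range[1], rg$predator_fl_range[2])
      ol_only <- runif(n) < rg$ol_only_fraction
      ol_fl <- reg[reg$kind == "ol_to_fl", ][1, ]
      ol <- invert_regression_internal(ol_fl, fl, "cm", "cm")
      empty <- runif(n) < rg$empty_fraction
      st_list[[length(st_list) + 1L]] <- tibble::tibble(
        stomach_id = ids, year = year, month = month,
        lat = runif(n, 31.5, 33.5), lon = runif(n, -119.5, -117.0),
        fl_cm = ifelse(ol_only, NA_real_, fl),
        ol_cm = ifelse(ol_only, ol, NA_real_),
        regime = rg$label)
      n_full <- sum(!empty)
      if (n_full == 0) next
      counts <- rztnbinom(n_full, rg$count_mean, rg$count_dispersion)
      full_ids <- ids[!empty]
      for (k in seq_len(n_full)) {
        probs <- rdirichlet1(rg$concentration * rg$composition)
        tx <- sample(comp_taxa, counts[k], replace = TRUE, prob = probs)
        m <- length(tx)
        info <- taxa[match(tx, taxa$taxon_id), ]
        true_len <- rlnorm(m, info$meanlog, info$sdlog)
        u <- runif(m)
        kind <- ifelse(u < rg$measured_fraction * (1 - rg$hardpart_fraction),
                       "whole_length",
                       ifelse(u < rg$measured_fraction, "hard_part",
                              "unmeasured"))
        # measured cephalopods are represented by beaks only
        kind[kind == "whole_length" & info$broad_group == "cephalopod"] <-
          "hard_part"
        prey_list[[length(prey_list) + 1L]] <- list(
          prey_id = sprintf("P%06d", pid + seq_len(m)),
          stomach_id = rep(full_ids[k], m), taxon_id = tx,
          broad_group = info$broad_group, family = info$family,
          genus = info$genus, species = info$species,
          measurement_kind = kind, true_length_mm = true_len)
        pid <- pid + m
      }
    }
    stomachs <- dplyr::bind_rows(st_list)
    prey <- dplyr::bind_rows(lapply(prey_list, tibble::as_tibble))
    if (nrow(prey) == 0) {
      prey <- tibble::tibble(prey_id = character(), stomach_id = character(),
                             taxon_id = character(), broad_group = character(),
                             family = character(), genus = character(),
                             species = character(),
                             measurement_kind = character(),
                             measured_value_mm = numeric(),
                             is_bait = logical(),
                             true_length_mm = numeric())
    }
    # Vectorised per taxon: hard-part fabrication (inverted regression),
    # hidden true mass (length route; the beak route is constructed to
    # agree exactly) and energy (species-level density).
    prey$measured_value_mm <- NA_real_
    prey$is_bait <- FALSE
    truth_mass <- rep(NA_real_, nrow(prey))
    truth_kj <- rep(NA_real_, nrow(prey))
    for (tx_id in unique(prey$taxon_id)) {
      rows <- which(prey$taxon_id == tx_id)
      info <- taxa[taxa$taxon_id == tx_id, ]
      hp <- resolve_regression(reg, "hardpart_to_length",
                               species = info$species, genus = info$genus,
                               family = info$family,
                               broad_group = info$broad_group)
      lm_spec <- resolve_regression(reg, "length_to_mass",
                                    species = info$species,
                                    genus = info$genus, family = info$family,
                                    broad_group = info$broad_group)
      dens <- resolve_energy_density(en, species = info$species,
                                     genus = info$genus, family = info$family,
                                     broad_group = info$broad_group)
      whole <- rows[prey$measurement_kind[rows] == "whole_length"]
      hard <- rows[prey$measurement_kind[rows] == "hard_part"]
      prey$measured_value_mm[whole] <- prey$true_length_mm[whole]
      if (length(hard) > 0)
        prey$measured_value_mm[hard] <- invert_regression_internal(
          hp, prey$true_length_mm[hard], "mm", "mm")
      truth_mass[rows] <- apply_regression_internal(
        lm_spec, prey$true_length_mm[rows], "mm", "g")
      truth_kj[rows] <- truth_mass[rows] * dens
    }
    truth <- tibble::tibble(prey_id = prey$prey_id,
                            true_length_mm = prey$true_length_mm,
                            true_mass_g = truth_mass,
                            true_energy_kJ = truth_kj)
    prey$true_length_mm <- NULL
    diet_study(stomachs, prey, regressions = reg, energy = en, truth = truth)
  })
}

#' Three-regime reference fixture
#'
#' A small synthetic study under the default three-regime conditions
#' ([default_regimes()]), used throughout the test suite: a correctly
#' specified diet tree recovers the three regimes as terminal nodes split on
#' collection year.
#'
#' @param seed Integer seed.
#' @param n_stomachs Total stomachs (default 300).
#' @param ... Passed to [simulate_diet_study()].
#' @return A [diet_study()].
#' @export
three_regime_fixture <- function(seed, n_stomachs = 300, ...) {
  simulate_diet_study(default_regimes(n_stomachs), seed = seed, ...)
}
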