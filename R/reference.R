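# Published diet-composition reference for juvenile Pacific bluefin tuna
# sampled in the Southern California Bight, 2008-2016, as printed: percent
# numerical abundance and percent frequency of occurrence with their raw
# counts, per sampling period (2008, 2009-14, 2015-16). The counts are data;
# the percentages are retained so the pipeline's own %N/%FO computations can
# be validated against the printed table.

#' Reference diet-composition counts (SCB bluefin, 2008-2016)
#'
#' Prey counts (`n_*`) and stomach occurrence counts (`occ_*`) for 48 prey
#' taxa in three sampling periods, together with the percentages as
#' printed (`pN_*`, `pFO_*`; `NA` where the printed table has a dash).
#' `lumped` marks families that fell below 1% mean proportional abundance
#' and were pooled into "Other" groups for similarity analyses. Stated
#' sample sizes: 88, 439 and 194 non-empty stomachs (963 sampled in total,
#' of which 721 contained prey).
#'
#' @return A tibble, one row per prey taxon.
#' @export
scb_reference_counts <- function() {
  out <- tibble::tribble(
    ~broad_group, ~family, ~lumped, ~taxon,
    ~pN_2008, ~n_2008, ~pN_0914, ~n_0914, ~pN_1516, ~n_1516,
    ~pFO_2008, ~occ_2008, ~pFO_0914, ~occ_0914, ~pFO_1516, ~occ_1516,
    "cephalopod", "Argonautidae", FALSE, "Argonauta sp.",
    0.1, 1, 1.9, 268, 0.1, 6, 1.1, 1, 14.6, 64, 4.5, 6,
    "cephalopod", "Enoploteuthidae", FALSE, "Abraliopsis sp.",
    29.6, 590, 0.1, 11, 0.4, 18, 77.3, 68, 0.2, 1, 2.2, 3,
    "cephalopod", "Gonatidae", FALSE, "Gonatopsis sp.",
    0.1, 1, 0.0, 6, 0.1, 4, 1.1, 1, 0.9, 4, 2.2, 3,
    "cephalopod", "Gonatidae", FALSE, "Gonatus sp.",
    1.1, 22, 5.2, 744, 0.7, 33, 9.1, 8, 21.9, 96, 6.7, 9,
    "cephalopod", "Loliginidae", FALSE, "Doryteuthis opalescens",
    0.8, 15, 3.2, 466, 0.4, 20, 5.7, 5, 14.6, 64, 9.0, 12,
    "cephalopod", "Octopodidae", FALSE, "Octopus bimaculatus",
    NA, 0, 0.0, 3, 0.0, 1, NA, 0, 0.2, 1, 0.7, 1,
    "cephalopod", "Octopodidae", FALSE, "Octopus rubescens",
    NA, 0, 3.8, 544, 0.2, 9, NA, 0, 15.9, 70, 2.2, 3,
    "cephalopod", "Octopoteuthidae", FALSE, "Octopoteuthis sp.",
    0.1, 2, 4.3, 625, NA, 0, 2.3, 2, 21.6, 95, NA, 0,
    "cephalopod", "Onychoteuthidae", FALSE, "Onychoteuthis borealijaponica",
    1.1, 22, 3.9, 565, 0.3, 16, 18.2, 16, 18.5, 81, 9.0, 12,
    "cephalopod", "Amphitretidae", TRUE, "Japetella heathi",
    0.1, 2, 0.1, 21, NA, 0, 2.3, 2, 2.1, 9, NA, 0,
    "cephalopod", "Cranchiidae", TRUE, "Leachia sp.",
    NA, 0, NA, 0, 0.0, 1, NA, 0, NA, 0, 0.7, 1,
    "cephalopod", "Histioteuthidae", TRUE, "Histioteuthis heteropsis",
    0.1, 2, 0.0, 5, NA, 0, 1.1, 1, 0.7, 3, NA, 0,
    "cephalopod", "Ommastrephidae", TRUE, "Dosidicus gigas",
    0.8, 16, 0.3, 39, NA, 0, 10.2, 9, 2.7, 12, NA, 0,
    "cephalopod", "Unidentified squids", FALSE, "Unidentified squids",
    1.9, 37, 16.6, 2380, 1.2, 60, 4.5, 4, 42.8, 188, 13.4, 18,
    "fish", "Carangidae", FALSE, "Trachurus symmetricus",
    0.1, 1, 10.5, 1514, 0.6, 31, 1.1, 1, 33.0, 145, 8.2, 11,
    "fish", "Clupeidae", FALSE, "Sardinops sagax",
    0.2, 4, 1.7, 246, 0.9, 44, 3.4, 3, 16.2, 71, 13.4, 18,
    "fish", "Engraulidae", FALSE, "Engraulis mordax",
    0.2, 4, 2.8, 400, 10.4, 500, 3.4, 3, 5.5, 24, 30.6, 41,
    "fish", "Myctophidae", FALSE, "Ceratoscopelus townsendi",
    5.1, 101, 0.0, 6, 0.6, 27, 43.2, 38, 0.2, 1, 1.5, 2,
    "fish", "Myctophidae", FALSE, "Diaphus theta",
    4.3, 86, 0.4, 51, NA, 0, 31.8, 28, 2.5, 11, NA, 0,
    "fish", "Myctophidae", FALSE, "Nannobrachium ritteri",
    0.2, 3, 0.2, 31, 0.0, 1, 3.4, 3, 1.4, 6, 0.7, 1,
    "fish", "Myctophidae", FALSE, "Protomyctophum crockeri",
    0.1, 1, 0.2, 26, NA, 0, 1.1, 1, 1.1, 5, NA, 0,
    "fish", "Myctophidae", FALSE, "Stenobrachius leucopsaurus",
    7.4, 147, 0.2, 22, NA, 0, 37.5, 33, 2.3, 10, NA, 0,
    "fish", "Myctophidae", FALSE, "Symbolophorus californiensis",
    NA, 0, 0.3, 36, 0.0, 1, NA, 0, 3.2, 14, 0.7, 1,
    "fish", "Myctophidae", FALSE, "Tarletonbeania crenularis",
    NA, 0, 0.0, 7, NA, 0, NA, 0, 0.2, 1, NA, 0,
    "fish", "Myctophidae", FALSE, "Triphoturus mexicanus",
    31.4, 627, 0.3, 48, NA, 0, 61.4, 54, 0.2, 1, NA, 0,
    "fish", "Myctophidae", FALSE, "Myctophidae",
    0.1, 1, NA, 0, NA, 0, 1.1, 1, NA, 0, NA, 0,
    "fish", "Scomberesocidae", FALSE, "Cololabis saira",
    0.2, 4, 2.0, 294, 0.2, 11, 3.4, 3, 13.0, 57, 3.7, 5,
    "fish", "Scombridae", FALSE, "Scomber japonicus",
    NA, 0, 4.1, 594, 0.1, 4, NA, 0, 18.0, 79, 1.5, 2,
    "fish", "Sebastidae", FALSE, "Sebastes sp.",
    0.8, 15, 5.0, 722, 2.7, 132, 13.6, 12, 19.6, 86, 15.7, 21,
    "fish", "Argentinidae", TRUE, "Argentina sialis",
    NA, 0, NA, 0, 0.2, 11, NA, 0, NA, 0, 2.2, 3,
    "fish", "Centrolophidae", TRUE, "Icichthys lockingtoni",
    NA, 0, 0.0, 1, NA, 0, NA, 0, 0.2, 1, NA, 0,
    "fish", "Exocoetidae", TRUE, "Cheilopogon pinnatibarbatus",
    NA, 0, NA, 0, 0.0, 2, NA, 0, NA, 0, 1.5, 2,
    "fish", "Labridae", TRUE, "Oxyjulis californica",
    NA, 0, NA, 0, 0.1, 3, NA, 0, NA, 0, 1.5, 2,
    "fish", "Merlucciidae", TRUE, "Merluccius productus",
    NA, 0, 0.4, 52, 0.0, 2, NA, 0, 2.1, 9, 1.5, 2,
    "fish", "Microstomatidae", TRUE, "Nansenia sp.",
    NA, 0, 0.1, 10, NA, 0, NA, 0, 1.4, 6, NA, 0,
    "fish", "Ophidiidae", TRUE, "Chilara taylori",
    NA, 0, 0.1, 20, 0.3, 16, NA, 0, 2.1, 9, 7.5, 10,
    "fish", "Paralepididae", TRUE, "Lestidiops ringens",
    NA, 0, 0.1, 21, NA, 0, NA, 0, 1.8, 8, NA, 0,
    "fish", "Paralepididae", TRUE, "Magnisudis atlantica",
    NA, 0, 0.0, 1, NA, 0, NA, 0, 0.2, 1, NA, 0,
    "fish", "Pleuronectidae", TRUE, "Pleuronichthys decurrens",
    NA, 0, 0.1, 9, NA, 0, NA, 0, 0.5, 2, NA, 0,
    "fish", "Pleuronectiformes", TRUE, "Pleuronectiformes",
    NA, 0, 0.0, 4, NA, 0, NA, 0, 0.5, 2, NA, 0,
    "fish", "Sciaenidae", TRUE, "Seriphus politus",
    NA, 0, 0.0, 2, NA, 0, NA, 0, 0.2, 1, NA, 0,
    "fish", "Scopelarchidae", TRUE, "Rosenblattichthys volucris",
    0.1, 2, NA, 0, NA, 0, 1.1, 1, NA, 0, NA, 0,
    "fish", "Syngnathidae", TRUE, "Syngnathus californiensis",
    0.2, 4, 0.2, 25, 0.0, 1, 2.3, 2, 2.5, 11, 0.7, 1,
    "fish", "Unidentified fishes", FALSE, "Unidentified fishes",
    1.9, 37, 1.7, 243, 1.4, 67, 26.1, 23, 17.5, 77, 17.9, 24,
    "crustacean", "Hyperiidea", FALSE, "Phronima sp.",
    NA, 0, 1.9, 280, 1.0, 50, NA, 0, 11.6, 51, 3.0, 4,
    "crustacean", "Hyperiidea", FALSE, "Hyperiidea",
    NA, 0, 23.3, 3354, 1.5, 74, NA, 0, 47.8, 210, 4.5, 6,
    "crustacean", "Munididae", FALSE, "Pleuroncodes planipes",
    NA, 0, NA, 0, 74.5, 3591, NA, 0, NA, 0, 84.3, 113,
    "crustacean", "Unidentified Malacostraca", FALSE,
    "Unidentified Malacostraca",
    12.4, 247, 4.7, 678, 1.8, 85, 59.1, 52, 20.3, 89, 12.7, 17)
  out$taxon_id <- gsub("[^a-z]+", "_", tolower(out$taxon))
  out
}

#' Stated stomach sample sizes of the reference periods
#'
#' @return Named integer vector of non-empty stomachs per period, plus the
#'   total number of stomachs sampled (`sampled`) across the study.
#' @export
scb_reference_n <- function() {
  c(`2008` = 88L, `2009-14` = 439L, `2015-16` = 194L, sampled = 963L)
}

# Distribute `n` prey over `occ` occupied stomachs chosen cyclically from
# `n_stomachs`, starting at `offset`: each occupied stomach gets one item,
# the surplus piles onto the first. Cycling different taxa from different
# offsets covers every stomach, so occurrence counts and the non-empty
# total are both preserved.
allocate_occurrences <- function(n, occ, n_stomachs, offset) {
  idx <- ((offset + seq_len(occ) - 1L) %% n_stomachs) + 1L
  counts <- rep(1L, occ)
  counts[1] <- counts[1] + (n - occ)
  list(stomach = idx, count = counts)
}

#' Reconstruct a per-stomach dataset from the reference counts
#'
#' Builds a [diet_study()] whose per-period prey counts and occurrence
#' counts equal the published reference table exactly, so that
#' [percent_N()] and [percent_FO()] recompute the printed percentages. The
#' allocation of items to individual stomachs is deterministic (cyclic) and
#' is immaterial for %N and %FO, which depend only on totals and occurrence
#' counts. 242 additional empty stomachs bring the study to its stated 963
#' sampled stomachs.
#'
#' @return A [diet_study()] with a `period` column on `stomachs`.
#' @export
scb_reference_study <- function() {
  counts <- scb_reference_counts()
  nn <- scb_reference_n()
  periods <- tibble::tibble(
    period = c("2008", "2009-14", "2015-16"),
    n_col = c("n_2008", "n_0914", "n_1516"),
    occ_col = c("occ_2008", "occ_0914", "occ_1516"),
    n_stomachs = as.integer(nn[1:3]),
    years = list(2008L, 2009:2014, 2015:2016))
  st_list <- list()
  prey_list <- list()
  pid <- 0L
  for (i in seq_len(nrow(periods))) {
    p <- periods[i, ]
    ids <- sprintf("%s_S%03d", gsub("-", "", p$period), seq_len(p$n_stomachs))
    st_list[[i]] <- tibble::tibble(
      stomach_id = ids,
      year = rep(p$years[[1]], length.out = p$n_stomachs),
      period = p$period)
    offset <- 0L
    for (j in seq_len(nrow(counts))) {
      n <- counts[[p$n_col]][j]
      occ <- counts[[p$occ_col]][j]
      if (occ == 0) next
      al <- allocate_occurrences(n, occ, p$n_stomachs, offset)
      offset <- offset + occ
      prey_list[[length(prey_list) + 1L]] <- tibble::tibble(
        stomach_id = ids[al$stomach],
        taxon_id = counts$taxon_id[j],
        broad_group = counts$broad_group[j],
        family = counts$family[j],
        item_count = al$count)
    }
  }
  prey <- dplyr::bind_rows(prey_list)
  prey <- prey[rep(seq_len(nrow(prey)), prey$item_count), ]
  prey$item_count <- NULL
  prey$prey_id <- sprintf("RP%06d", seq_len(nrow(prey)))
  prey$genus <- NA_character_
  prey$species <- NA_character_
  prey$measurement_kind <- "unmeasured"
  prey$measured_value_mm <- NA_real_
  prey$is_bait <- FALSE
  stomachs <- dplyr::bind_rows(st_list)
  # stomachs sampled but containing no prey
  n_empty <- nn[["sampled"]] - sum(periods$n_stomachs)
  empties <- tibble::tibble(
    stomach_id = sprintf("EMPTY_S%03d", seq_len(n_empty)),
    year = rep(c(2008L, 2009:2016), length.out = n_empty),
    period = NA_character_)
  diet_study(dplyr::bind_rows(stomachs, empties), prey)
}

#' Find the stomach count implied by printed %FO values
#'
#' Given occurrence counts and the %FO percentages printed alongside them,
#' scans candidate denominators and returns those for which every printed
#' value equals `100 * occ / n` rounded (half away from zero) to one
#' decimal. Used to surface internal inconsistencies in published tables.
#'
#' @param occ Occurrence counts.
#' @param printed Printed %FO values (1 decimal); `NA`s are ignored.
#' @param n_max Largest denominator to consider.
#' @return Integer vector of consistent denominators (possibly empty).
#' @export
implied_fo_denominator <- function(occ, printed, n_max = 2000L) {
  keep <- !is.na(printed) & occ > 0
  occ <- occ[keep]
  printed <- printed[keep]
  lo <- max(occ, 1L)
  cand <- seq.int(lo, n_max)
  ok <- vapply(cand, function(n) {
    all(abs(round_half_up(100 * occ / n, 1) - printed) < 1e-9)
  }, logical(1))
  cand[ok]
}

#' Check printed %FO values against stated sample sizes
#'
#' Recomputes %FO from the reference occurrence counts with each period's
#' stated number of non-empty stomachs and warns for any period whose
#' printed percentages are inconsistent with that denominator, reporting
#' the denominators that would reproduce them.
#'
#' @return Tibble with one row per period: stated n, whether the printed
#'   values match it, and the implied denominators; invisibly.
#' @export
check_reference_fo_consistency <- function() {
  counts <- scb_reference_counts()
  nn <- scb_reference_n()
  cols <- list(`2008` = c("occ_2008", "pFO_2008"),
               `2009-14` = c("occ_0914", "pFO_0914"),
               `2015-16` = c("occ_1516", "pFO_1516"))
  res <- purrr::imap(cols, function(cl, period) {
    occ <- counts[[cl[1]]]
    printed <- counts[[cl[2]]]
    stated <- nn[[period]]
    consistent <- all(abs(round_half_up(
      100 * occ[occ > 0] / stated, 1) - printed[occ > 0]) < 1e-9,
      na.rm = TRUE)
    implied <- implied_fo_denominator(occ, printed)
    tibble::tibble(period = period, stated_n = stated,
                   consistent = consistent,
                   implied = paste(implied, collapse = ","))
  })
  res <- dplyr::bind_rows(res)
  bad <- res[!res$consistent, ]
  if (nrow(bad) > 0) {
    warn(sprintf(
      "printed %%FO values for period(s) %s are inconsistent with the stated stomach counts (%s); they imply denominator(s) %s",
      paste(bad$period, collapse = ", "),
      paste(bad$stated_n, collapse = ", "),
      paste(bad$implied, collapse = "; ")))
  }
  invisible(res)
}
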