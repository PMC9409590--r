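#' Assemble a diet study from stomach and prey tables
#'
#' A *diet study* is the unit all analyses operate on: one row per sampled
#' predator stomach and one row per prey item, joined on `stomach_id`.
#' Construction validates the schema, checks referential integrity, flags
#' bait items (excluded from every analysis) and marks stomachs that are
#' empty once bait is removed.
#'
#' @param stomachs Data frame with columns `stomach_id`, `year` and optionally
#'   `month`, `lat`, `lon`, `fl_cm` (fork length, cm), `ol_cm` (operculum
#'   length, cm), `mass_kg`.
#' @param prey Data frame with columns `prey_id`, `stomach_id`, `taxon_id`,
#'   `broad_group` (`"fish"`, `"cephalopod"` or `"crustacean"`), `family`,
#'   `genus`, `species`, `measurement_kind` (`"whole_length"`, `"hard_part"`
#'   or `"unmeasured"`), `measured_value_mm`, `is_bait`.
#' @param regressions Optional regression-parameter table, see
#'   [read_regressions()].
#' @param energy Optional energy-density table, see [read_energy_densities()].
#' @param truth Optional hidden ground-truth table from the synthetic
#'   generator (per-prey true length/mass/energy), used only for recovery
#'   experiments.
#' @return A list with class `"diet_study"` holding tibbles `stomachs`,
#'   `prey` (bait rows removed, kept aside in `bait`), `regressions`,
#'   `energy` and `truth`.
#' @export
diet_study <- function(stomachs, prey, regressions = NULL, energy = NULL,
                       truth = NULL) {
  stomachs <- tibble::as_tibble(stomachs)
  prey <- tibble::as_tibble(prey)
  assert_columns(stomachs, c("stomach_id", "year"), "`stomachs`")
  assert_columns(prey, c("prey_id", "stomach_id", "taxon_id", "broad_group",
                         "family", "measurement_kind"), "`prey`")
  for (col in c("month", "lat", "lon", "fl_cm", "ol_cm", "mass_kg")) {
    if (!col %in% names(stomachs)) stomachs[[col]] <- NA_real_
  }
  for (col in c("genus", "species")) {
    if (!col %in% names(prey)) prey[[col]] <- NA_character_
  }
  if (!"measured_value_mm" %in% names(prey)) prey$measured_value_mm <- NA_real_
  if (!"is_bait" %in% names(prey)) prey$is_bait <- FALSE
  prey$is_bait <- as.logical(prey$is_bait)
  prey$is_bait[is.na(prey$is_bait)] <- FALSE

  stomachs$stomach_id <- as.character(stomachs$stomach_id)
  prey$stomach_id <- as.character(prey$stomach_id)
  prey$prey_id <- as.character(prey$prey_id)

  if (anyNA(stomachs$year))
    abort("every stomach record needs a collection `year`",
          class = "tunadiet_schema_error")
  dup <- stomachs$stomach_id[duplicated(stomachs$stomach_id)]
  if (length(dup) > 0)
    abort(sprintf("duplicate stomach_id: %s",
                  paste(unique(dup), collapse = ", ")),
          class = "tunadiet_integrity_error")
  dup <- prey$prey_id[duplicated(prey$prey_id)]
  if (length(dup) > 0)
    abort(sprintf("duplicate prey_id: %s", paste(unique(dup), collapse = ", ")),
          class = "tunadiet_integrity_error")
  orphan <- setdiff(prey$stomach_id, stomachs$stomach_id)
  if (length(orphan) > 0)
    abort(sprintf("prey rows reference absent stomach_id: %s",
                  paste(orphan, collapse = ", ")),
          class = "tunadiet_integrity_error")

  bad <- which(!prey$broad_group %in% c("fish", "cephalopod", "crustacean"))
  if (length(bad) > 0)
    abort(sprintf("invalid broad_group in prey row(s) %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "tunadiet_schema_error")
  bad <- which(!prey$measurement_kind %in%
                 c("whole_length", "hard_part", "unmeasured"))
  if (length(bad) > 0)
    abort(sprintf("invalid measurement_kind in prey row(s) %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "tunadiet_schema_error")
  bad <- which(prey$measurement_kind != "unmeasured" &
                 !is.finite(prey$measured_value_mm))
  if (length(bad) > 0)
    abort(sprintf("measured prey without measured_value_mm in row(s) %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "tunadiet_schema_error")
  prey$measured_value_mm[prey$measurement_kind == "unmeasured"] <- NA_real_

  bait <- dplyr::filter(prey, .data$is_bait)
  prey <- dplyr::filter(prey, !.data$is_bait)
  if (!"length_mm" %in% names(prey)) prey$length_mm <- NA_real_
  if (!"length_source" %in% names(prey)) prey$length_source <- NA_character_
  if (!"mass_g" %in% names(prey)) prey$mass_g <- NA_real_
  if (!"energy_kJ" %in% names(prey)) prey$energy_kJ <- NA_real_

  stomachs$is_empty <- !stomachs$stomach_id %in% prey$stomach_id

  structure(list(stomachs = stomachs, prey = prey, bait = bait,
                 regressions = regressions, energy = energy, truth = truth),
            class = "diet_study")
}

#' @export
print.diet_study <- function(x, ...) {
  cat("<diet_study>\n")
  cat(sprintf("  stomachs: %d (%d non-empty, %d empty)\n",
              nrow(x$stomachs), sum(!x$stomachs$is_empty),
              sum(x$stomachs$is_empty)))
  cat(sprintf("  prey items: %d across %d taxa (%d bait rows excluded)\n",
              nrow(x$prey), length(unique(x$prey$taxon_id)),
              nrow(x$bait %||% tibble::tibble())))
  cat(sprintf("  years: %s\n",
              paste(range(x$stomachs$year), collapse = "-")))
  if (!is.null(x$regressions))
    cat(sprintf("  regressions: %d specs\n", nrow(x$regressions)))
  if (!is.null(x$energy))
    cat(sprintf("  energy densities: %d entries\n", nrow(x$energy)))
  if (!is.null(x$truth)) cat("  hidden ground truth attached\n")
  invisible(x)
}

#' Non-empty stomachs of a study
#'
#' @param study A [diet_study()].
#' @return Tibble of stomach records that contain at least one non-bait prey.
#' @export
nonempty_stomachs <- function(study) {
  dplyr::filter(study$stomachs, !.data$is_empty)
}

#' Read a diet study from delimited text files
#'
#' Files are UTF-8 comma-delimited with a header row and dot decimal marks.
#' Malformed rows are reported with their line numbers via readr's parsing
#' problems.
#'
#' @param dir Directory holding `stomachs.csv` and `prey.csv`, and optionally
#'   `regressions.csv`, `energy.csv`, `truth.csv`.
#' @param quiet Suppress the exclusion-count message.
#' @return A [diet_study()].
#' @export
read_diet_study <- function(dir, quiet = FALSE) {
  pth <- function(f) file.path(dir, f)
  rd <- function(f) {
    x <- readr::read_csv(pth(f), show_col_types = FALSE, progress = FALSE)
    probs <- readr::problems(x)
    if (nrow(probs) > 0)
      abort(sprintf("malformed rows in %s at line(s): %s", f,
                    paste(unique(probs$row), collapse = ", ")),
            class = "tunadiet_schema_error")
    x
  }
  stomachs <- rd("stomachs.csv")
  prey <- rd("prey.csv")
  regressions <- if (file.exists(pth("regressions.csv")))
    read_regressions(pth("regressions.csv"))
  energy <- if (file.exists(pth("energy.csv")))
    read_energy_densities(pth("energy.csv"))
  truth <- if (file.exists(pth("truth.csv"))) rd("truth.csv")
  study <- diet_study(stomachs, prey, regressions, energy, truth)
  if (!quiet)
    inform(sprintf(
      "read %d stomachs (%d empty excluded from analyses), %d prey (%d bait rows excluded)",
      nrow(study$stomachs), sum(study$stomachs$is_empty),
      nrow(study$prey), nrow(study$bait)))
  study
}

#' Write a diet study to delimited text files
#'
#' Inverse of [read_diet_study()]: a written study reads back with identical
#' logical content.
#'
#' @param study A [diet_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_diet_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  st <- study$stomachs
  st$is_empty <- NULL
  prey <- dplyr::bind_rows(study$prey, study$bait)
  prey <- prey[, c("prey_id", "stomach_id", "taxon_id", "broad_group",
                   "family", "genus", "species", "measurement_kind",
                   "measured_value_mm", "is_bait")]
  readr::write_csv(st, file.path(dir, "stomachs.csv"), na = "")
  readr::write_csv(prey, file.path(dir, "prey.csv"), na = "")
  if (!is.null(study$regressions))
    readr::write_csv(study$regressions, file.path(dir, "regressions.csv"), na = "")
  if (!is.null(study$energy))
    readr::write_csv(study$energy, file.path(dir, "energy.csv"), na = "")
  if (!is.null(study$truth))
    readr::write_csv(study$truth, file.path(dir, "truth.csv"), na = "")
  invisible(dir)
}
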