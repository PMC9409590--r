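# Reconstruction of prey length, mass and energy from partial remains.
#
# Pipeline: whole lengths are taken as measured; hard parts (vertebrae,
# beaks, carapaces) are converted to whole lengths with the resolved
# regressions; remaining unmeasured prey receive mean lengths of measured
# conspecifics hierarchically (same stomach, then same sampling year, then
# same diet-tree group); lengths convert to mass (cephalopods with measured
# beaks go straight from beak to mass) and mass to energy via taxon-scoped
# energy densities, with year/group-level mean densities for prey not
# identified to family.

id_class <- function(prey) {
  ifelse(is_unidentified_group(prey$family), "unidentified",
         ifelse(is.na(prey$genus) & is.na(prey$species), "family", "species"))
}

# Specs of a given kind resolvable for the identified cephalopod families in
# the study; used for the "mean over all cephalopod regressions" rule for
# unidentified squids with measured beaks.
ceph_specs <- function(study, kind) {
  fams <- unique(study$prey$family[study$prey$broad_group == "cephalopod" &
                                     !is_unidentified_group(study$prey$family)])
  specs <- list()
  for (f in fams) {
    s <- resolve_regression(study$regressions, kind, family = f,
                            broad_group = "cephalopod")
    if (!is.null(s)) specs[[length(specs) + 1L]] <- s
  }
  unique(dplyr::bind_rows(specs))
}

#' Reconstruct whole lengths from hard parts
#'
#' Prey measured only as hard parts get a whole length through the resolved
#' hard-part regression (`length_source = "hardpart_regression"`);
#' whole-length measurements are passed through (`"measured"`). Unidentified
#' squids with measured beaks receive the mean prediction of every
#' beak-to-length regression used for the study's identified cephalopods.
#' Hard parts with no resolvable regression stay unmeasured and are
#' reported.
#'
#' @param study A [diet_study()] with a regression table.
#' @param quiet Suppress the unresolvable-count message.
#' @return The study with `length_mm` and `length_source` filled where
#'   possible.
#' @export
hardpart_lengths <- function(study, quiet = FALSE) {
  prey <- study$prey
  whole <- prey$measurement_kind == "whole_length"
  prey$length_mm[whole] <- prey$measured_value_mm[whole]
  prey$length_source[whole] <- "measured"

  hard <- which(prey$measurement_kind == "hard_part")
  unresolved <- 0L
  if (length(hard) > 0) {
    cspecs <- ceph_specs(study, "hardpart_to_length")
    for (tx in unique(prey$taxon_id[hard])) {
      rows <- hard[prey$taxon_id[hard] == tx]
      r1 <- rows[1]
      if (prey$broad_group[r1] == "cephalopod" &&
          is_unidentified_group(prey$family[r1])) {
        if (nrow(cspecs) == 0) { unresolved <- unresolved + length(rows); next }
        # mean prediction per prey over all cephalopod regressions
        preds <- vapply(seq_len(nrow(cspecs)), function(i)
          apply_regression_internal(cspecs[i, ],
                                    prey$measured_value_mm[rows], "mm", "mm"),
          numeric(length(rows)))
        prey$length_mm[rows] <- rowMeans(matrix(preds, nrow = length(rows)))
        prey$length_source[rows] <- "hardpart_regression"
        next
      }
      spec <- resolve_regression(study$regressions, "hardpart_to_length",
                                 species = prey$species[r1],
                                 genus = prey$genus[r1],
                                 family = prey$family[r1],
                                 broad_group = prey$broad_group[r1])
      if (is.null(spec)) { unresolved <- unresolved + length(rows); next }
      prey$length_mm[rows] <- apply_regression_internal(
        spec, prey$measured_value_mm[rows], "mm", "mm")
      prey$length_source[rows] <- "hardpart_regression"
    }
  }
  if (unresolved > 0 && !quiet)
    inform(sprintf(
      "%d hard-part prey had no resolvable length regression and remain unmeasured",
      unresolved))
  study$prey <- prey
  study
}

# First non-NA across parallel vectors plus which one supplied it.
coalesce_with_source <- function(values, sources) {
  out <- rep(NA_real_, length(values[[1]]))
  src <- rep(NA_character_, length(values[[1]]))
  for (i in seq_along(values)) {
    take <- is.na(out) & !is.na(values[[i]])
    out[take] <- values[[i]][take]
    src[take] <- sources[i]
  }
  list(value = out, source = src)
}

#' Impute lengths of unmeasured prey hierarchically
#'
#' Mean lengths of measured prey (directly measured or reconstructed from
#' hard parts) are applied to unmeasured prey of the same taxon from, in
#' order of preference: the same stomach, the same sampling year, or the
#' same diet-tree group. Prey identified only to family use family-level
#' means through the same hierarchy. Unmeasured prey not identified to
#' family receive the year-level (else group-level) mean over their broad
#' taxonomic group (`length_source = "imputed_fallback"`). Prey whose taxon
#' has no measured representative anywhere stay length-unresolved and are
#' reported; they are excluded from mass and energy totals.
#'
#' @param study A [diet_study()] after [hardpart_lengths()].
#' @param grouping Stomach grouping (diet-tree terminal nodes), as accepted
#'   by [percent_N()].
#' @param quiet Suppress the unresolvable-count message.
#' @return The study with imputed `length_mm`/`length_source`.
#' @export
impute_lengths <- function(study, grouping, quiet = FALSE) {
  g <- stomach_grouping(study, grouping)
  prey <- study$prey
  meta <- dplyr::left_join(
    dplyr::left_join(prey, study$stomachs[, c("stomach_id", "year")],
                     by = "stomach_id"),
    g, by = "stomach_id")
  meta$idc <- id_class(meta)

  donors <- meta[!is.na(meta$length_mm) &
                   meta$length_source %in% c("measured",
                                             "hardpart_regression"), ]
  mean_by <- function(df, keys) {
    out <- dplyr::summarise(dplyr::group_by(
      df, dplyr::across(dplyr::all_of(keys))),
      .mean_len = mean(.data$length_mm), .groups = "drop")
    out
  }
  need <- which(is.na(meta$length_mm))
  if (length(need) > 0) {
    rec <- meta[need, ]
    # key column per identification class: species/genus-level prey match on
    # taxon_id, family-level prey on family, unidentified on broad group
    rec$key <- ifelse(rec$idc == "species", rec$taxon_id,
                      ifelse(rec$idc == "family", rec$family,
                             rec$broad_group))
    don_sp <- donors
    don_sp$key <- don_sp$taxon_id
    don_fam <- donors[!is_unidentified_group(donors$family), ]
    don_fam$key <- don_fam$family
    don_bg <- donors
    don_bg$key <- don_bg$broad_group

    lookup <- function(don, rec, level_key) {
      tb <- mean_by(don, c("key", level_key))
      dplyr::left_join(rec[, c("key", level_key)], tb,
                       by = c("key", level_key))$.mean_len
    }
    fill_for <- function(don, rec_idx, levels, sources) {
      rc <- rec[rec_idx, ]
      vals <- lapply(levels, function(lv) lookup(don, rc, lv))
      coalesce_with_source(vals, sources)
    }
    idx_sp <- which(rec$idc == "species")
    idx_fam <- which(rec$idc == "family")
    idx_un <- which(rec$idc == "unidentified")
    res <- list(value = rep(NA_real_, nrow(rec)),
                source = rep(NA_character_, nrow(rec)))
    if (length(idx_sp) > 0) {
      r <- fill_for(don_sp, idx_sp, c("stomach_id", "year", "group"),
                    c("imputed_stomach", "imputed_year", "imputed_group"))
      res$value[idx_sp] <- r$value
      res$source[idx_sp] <- r$source
    }
    if (length(idx_fam) > 0) {
      r <- fill_for(don_fam, idx_fam, c("stomach_id", "year", "group"),
                    c("imputed_stomach", "imputed_year", "imputed_group"))
      res$value[idx_fam] <- r$value
      res$source[idx_fam] <- r$source
    }
    if (length(idx_un) > 0) {
      r <- fill_for(don_bg, idx_un, c("year", "group"),
                    c("imputed_fallback", "imputed_fallback"))
      res$value[idx_un] <- r$value
      res$source[idx_un] <- r$source
    }
    prey$length_mm[need] <- res$value
    prey$length_source[need] <- res$source
  }
  n_bad <- sum(is.na(prey$length_mm))
  if (n_bad > 0 && !quiet)
    inform(sprintf(
      "%d prey have no measured representative at any level; excluded from mass/energy totals",
      n_bad))
  study$prey <- prey
  study
}

#' Convert prey lengths (or beaks) to body mass
#'
#' Cephalopods with measured beaks are converted straight from beak to mass
#' with the resolved `beak_to_mass` regression (unidentified squids use the
#' mean over all cephalopod beak-to-mass regressions); everything else goes
#' through `length_to_mass` on the reconstructed length.
#'
#' @param study A [diet_study()] after length reconstruction/imputation.
#' @param quiet Suppress the unresolvable-count message.
#' @return The study with `mass_g` filled where possible.
#' @export
prey_mass <- function(study, quiet = FALSE) {
  prey <- study$prey
  unresolved <- 0L
  beak_rows <- which(prey$broad_group == "cephalopod" &
                       prey$measurement_kind == "hard_part" &
                       !is.na(prey$measured_value_mm))
  cspecs <- ceph_specs(study, "beak_to_mass")
  for (tx in unique(prey$taxon_id[beak_rows])) {
    rows <- beak_rows[prey$taxon_id[beak_rows] == tx]
    r1 <- rows[1]
    if (is_unidentified_group(prey$family[r1])) {
      if (nrow(cspecs) == 0) { unresolved <- unresolved + length(rows); next }
      preds <- vapply(seq_len(nrow(cspecs)), function(i)
        apply_regression_internal(cspecs[i, ], prey$measured_value_mm[rows],
                                  "mm", "g"),
        numeric(length(rows)))
      prey$mass_g[rows] <- rowMeans(matrix(preds, nrow = length(rows)))
      next
    }
    spec <- resolve_regression(study$regressions, "beak_to_mass",
                               species = prey$species[r1],
                               genus = prey$genus[r1],
                               family = prey$family[r1],
                               broad_group = prey$broad_group[r1])
    if (is.null(spec)) next  # fall through to the length route below
    prey$mass_g[rows] <- apply_regression_internal(
      spec, prey$measured_value_mm[rows], "mm", "g")
  }
  need <- which(is.na(prey$mass_g) & !is.na(prey$length_mm))
  if (length(need) > 0) {
    bad_len <- need[prey$length_mm[need] <= 0]
    if (length(bad_len) > 0)
      abort("prey lengths must be positive for mass conversion",
            class = "tunadiet_domain_error")
    for (tx in unique(prey$taxon_id[need])) {
      rows <- need[prey$taxon_id[need] == tx]
      r1 <- rows[1]
      spec <- resolve_regression(study$regressions, "length_to_mass",
                                 species = prey$species[r1],
                                 genus = prey$genus[r1],
                                 family = prey$family[r1],
                                 broad_group = prey$broad_group[r1])
      if (is.null(spec)) { unresolved <- unresolved + length(rows); next }
      prey$mass_g[rows] <- apply_regression_internal(
        spec, prey$length_mm[rows], "mm", "g")
    }
  }
  if (unresolved > 0 && !quiet)
    inform(sprintf("%d prey had no resolvable mass regression", unresolved))
  study$prey <- prey
  study
}

#' Convert prey mass to energy content
#'
#' Energy is mass times the resolved energy density (kJ per g wet mass),
#' falling back species to genus to family to broad group. Prey not
#' identified to family use the unweighted mean density over identified
#' prey items of the same broad group in the same sampling year, else in
#' the same diet-tree group.
#'
#' @param study A [diet_study()] after [prey_mass()].
#' @param grouping Stomach grouping (diet-tree terminal nodes).
#' @param quiet Suppress the unresolvable-count message.
#' @return The study with `energy_kJ` filled where possible.
#' @export
prey_energy <- function(study, grouping, quiet = FALSE) {
  g <- stomach_grouping(study, grouping)
  prey <- study$prey
  dens <- rep(NA_real_, nrow(prey))
  idc <- id_class(prey)
  ident <- which(idc != "unidentified")
  for (tx in unique(prey$taxon_id[ident])) {
    rows <- ident[prey$taxon_id[ident] == tx]
    r1 <- rows[1]
    d <- resolve_energy_density(study$energy, species = prey$species[r1],
                                genus = prey$genus[r1],
                                family = prey$family[r1],
                                broad_group = prey$broad_group[r1])
    if (!is.null(d)) dens[rows] <- d
  }
  unid <- which(idc == "unidentified")
  if (length(unid) > 0) {
    meta <- dplyr::left_join(
      dplyr::left_join(prey[, c("prey_id", "stomach_id", "broad_group")],
                       study$stomachs[, c("stomach_id", "year")],
                       by = "stomach_id"),
      g, by = "stomach_id")
    meta$dens <- dens
    sel <- rep(FALSE, nrow(meta))
    sel[ident] <- TRUE
    id_meta <- meta[sel & !is.na(dens), ]
    by_year <- dplyr::summarise(
      dplyr::group_by(id_meta, .data$broad_group, .data$year),
      d = mean(.data$dens), .groups = "drop")
    by_group <- dplyr::summarise(
      dplyr::group_by(id_meta, .data$broad_group, .data$group),
      d = mean(.data$dens), .groups = "drop")
    mu <- meta[unid, ]
    v1 <- dplyr::left_join(mu, by_year, by = c("broad_group", "year"))$d
    v2 <- dplyr::left_join(mu, by_group, by = c("broad_group", "group"))$d
    dens[unid] <- dplyr::coalesce(v1, v2)
  }
  prey$energy_kJ <- prey$mass_g * dens
  n_bad <- sum(!is.na(prey$mass_g) & is.na(prey$energy_kJ))
  if (n_bad > 0 && !quiet)
    inform(sprintf("%d prey had no resolvable energy density", n_bad))
  study$prey <- prey
  study
}

#' Full prey reconstruction
#'
#' Runs [hardpart_lengths()], [impute_lengths()], [prey_mass()] and
#' [prey_energy()] in order.
#'
#' @inheritParams prey_energy
#' @return The reconstructed study.
#' @export
reconstruct_prey <- function(study, grouping, quiet = FALSE) {
  study <- hardpart_lengths(study, quiet = quiet)
  study <- impute_lengths(study, grouping, quiet = quiet)
  study <- prey_mass(study, quiet = quiet)
  prey_energy(study, grouping, quiet = quiet)
}

#' Per-stomach totals and the body-mass exclusion
#'
#' Sums reconstructed mass and energy per stomach, expresses contents as a
#' percentage of predator body mass (%BM) and flags stomachs whose contents
#' exceed the exclusion threshold (default 3% BM, strictly greater)
#' for removal from mass/energy analyses; maximum daily rations reported
#' for bluefin of the sampled sizes are about 2-3% BM, so heavier contents
#' indicate overestimated prey mass or multi-day accumulation. Stomachs
#' with no predator size estimate are flagged separately
#' (`no_predator_size`) and also excluded from %BM analyses.
#'
#' @param study A reconstructed [diet_study()] (after
#'   [derive_predator_size()] if predator mass must come from length).
#' @param config A [diet_config()].
#' @param quiet Suppress the exclusion-count message.
#' @return Tibble with one row per non-empty stomach: `total_mass_g`,
#'   `total_energy_kJ`, `n_prey`, `mean_prey_energy_kJ`, `pct_body_mass`,
#'   `excluded` and `exclusion_reason`.
#' @export
stomach_totals <- function(study, config = diet_config(), quiet = FALSE) {
  prey <- study$prey
  tot <- dplyr::summarise(
    dplyr::group_by(prey, .data$stomach_id),
    total_mass_g = sum(.data$mass_g, na.rm = TRUE),
    total_energy_kJ = sum(.data$energy_kJ, na.rm = TRUE),
    n_prey = dplyr::n(),
    mean_prey_energy_kJ = mean(.data$energy_kJ, na.rm = TRUE),
    .groups = "drop")
  st <- nonempty_stomachs(study)
  out <- dplyr::left_join(
    st[, c("stomach_id", "year", "mass_kg")], tot, by = "stomach_id")
  out$pct_body_mass <- 100 * out$total_mass_g / (1000 * out$mass_kg)
  no_size <- is.na(out$mass_kg)
  over <- !no_size & out$pct_body_mass > 100 * config$bm_exclusion
  out$excluded <- no_size | over
  out$exclusion_reason <- ifelse(no_size, "no_predator_size",
                                 ifelse(over, "over_bm_threshold",
                                        NA_character_))
  if (!quiet && any(out$excluded))
    inform(sprintf(
      "excluded from mass/energy analyses: %d stomach(s) > %.0f%% BM, %d without predator size",
      sum(over), 100 * config$bm_exclusion, sum(no_size)))
  out
}
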