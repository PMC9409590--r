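# Per-stomach proportional abundance, diet matrices, %N / %FO summaries and
# rare-family lumping.

# Base prey-group label: the family, except that prey not identified to
# family keep their class-level "Unidentified ..." label (never lumped).
base_group_label <- function(family) family

is_unidentified_group <- function(label) {
  grepl("^Unidentified", label)
}

#' Proportional prey abundance of a single stomach
#'
#' Divides the number of prey per group by the total number of prey across
#' all groups in the same stomach, the compositional response used by all
#' similarity analyses.
#'
#' @param counts Named numeric vector (or two-column data frame
#'   `group`, `n`) of prey counts in one stomach.
#' @return Tibble with columns `group` and `p`; `p` sums to 1.
#' @export
#' @examples
#' proportional_abundance(c(A = 2, B = 6))
proportional_abundance <- function(counts) {
  if (is.data.frame(counts)) {
    counts <- setNames(counts$n, counts$group)
  }
  counts <- counts[counts > 0]
  if (length(counts) == 0 || sum(counts) <= 0)
    abort("cannot compute a composition for an empty stomach",
          class = "tunadiet_domain_error")
  tibble::tibble(group = names(counts), p = as.numeric(counts) / sum(counts))
}

#' Mean proportional abundance across stomachs
#'
#' Unweighted mean of the per-stomach compositions; each stomach counts the
#' same regardless of how many prey it held.
#'
#' @param dmat A [diet_matrix()].
#' @param stomach_ids Optional subset of stomachs.
#' @return Tibble with columns `group` and `p_bar` (sums to 1).
#' @export
mean_proportional_abundance <- function(dmat, stomach_ids = NULL) {
  m <- as_composition_matrix(dmat)
  if (!is.null(stomach_ids)) {
    keep <- rownames(m) %in% stomach_ids
    if (!any(keep)) abort("subset contains no stomachs of the matrix")
    m <- m[keep, , drop = FALSE]
  }
  tibble::tibble(group = colnames(m), p_bar = unname(colMeans(m)))
}

#' Lump rare families into "Other" prey groups
#'
#' Families whose mean proportional abundance across all stomachs is not
#' strictly above `threshold` are pooled into an "Other" group per broad
#' taxonomic grouping ("Other fishes", "Other cephalopods", "Other
#' crustaceans"). Class-level unidentified categories are never lumped.
#'
#' @param p_bar Tibble with columns `group` (family label), `broad_group`
#'   and `p_bar`, computed over **all** stomachs of the dataset.
#' @param threshold Lumping threshold (default 0.01; strictly-greater
#'   survives).
#' @return Named character vector mapping each family label to its analysis
#'   prey group.
#' @export
lump_rare_families <- function(p_bar, threshold = 0.01) {
  other_label <- c(fish = "Other fishes", cephalopod = "Other cephalopods",
                   crustacean = "Other crustaceans")
  keep <- p_bar$p_bar > threshold | is_unidentified_group(p_bar$group)
  out <- ifelse(keep, p_bar$group, other_label[p_bar$broad_group])
  setNames(unname(out), p_bar$group)
}

# n x G composition matrix (rownames stomach ids) from a diet_matrix tibble.
as_composition_matrix <- function(dmat) {
  if (is.matrix(dmat)) return(dmat)
  m <- as.matrix(dmat[, setdiff(names(dmat), "stomach_id"), drop = FALSE])
  rownames(m) <- dmat$stomach_id
  m
}

#' Build the stomachs-by-prey-groups diet matrix
#'
#' Counts prey per family per stomach, lumps rare families
#' ([lump_rare_families()]) using the mean proportional abundance over all
#' stomachs, and converts counts to per-stomach proportions. Empty stomachs
#' have no row.
#'
#' @param study A [diet_study()].
#' @param lump_threshold Mean-proportional-abundance threshold below which a
#'   family is pooled; `NULL` disables lumping.
#' @return A tibble (class `"diet_matrix"`) with `stomach_id` and one column
#'   per prey group; every row sums to 1. The family-to-group mapping is in
#'   `attr(, "lump_map")`.
#' @export
diet_matrix <- function(study, lump_threshold = 0.01) {
  prey <- study$prey
  if (nrow(prey) == 0) abort("study contains no prey items")
  prey$group <- base_group_label(prey$family)
  counts <- dplyr::count(prey, .data$stomach_id, .data$group)
  wide <- tidyr::pivot_wider(counts, names_from = "group",
                             values_from = "n", values_fill = 0)
  m <- as_composition_matrix(wide)
  m <- m / rowSums(m)
  lump_map <- NULL
  if (!is.null(lump_threshold)) {
    fam_info <- dplyr::distinct(prey, .data$group, .data$broad_group)
    p_bar <- tibble::tibble(group = colnames(m), p_bar = colMeans(m))
    p_bar$broad_group <- fam_info$broad_group[match(p_bar$group,
                                                    fam_info$group)]
    lump_map <- lump_rare_families(p_bar, lump_threshold)
    grp <- lump_map[colnames(m)]
    m <- t(rowsum(t(m), grp))
  }
  ord <- order(colnames(m))
  m <- m[, ord, drop = FALSE]
  out <- tibble::as_tibble(m)
  out <- tibble::add_column(out, stomach_id = rownames(m), .before = 1)
  attr(out, "lump_map") <- lump_map
  class(out) <- c("diet_matrix", class(out))
  out
}

# Normalise the many ways a stomach grouping can be given into a
# tibble(stomach_id, group). `grouping` may be: a column name of
# `study$stomachs` (e.g. "year" or "regime"), a data frame with columns
# stomach_id/group, or a named character vector.
stomach_grouping <- function(study, grouping) {
  st <- nonempty_stomachs(study)
  if (is.character(grouping) && length(grouping) == 1 &&
      grouping %in% names(study$stomachs)) {
    return(tibble::tibble(stomach_id = st$stomach_id,
                          group = as.character(st[[grouping]])))
  }
  if (inherits(grouping, "diet_cart_groups")) grouping <- grouping$assignments
  if (is.data.frame(grouping)) {
    assert_columns(grouping, c("stomach_id", "group"), "`grouping`")
    return(tibble::tibble(stomach_id = as.character(grouping$stomach_id),
                          group = as.character(grouping$group)))
  }
  if (!is.null(names(grouping))) {
    return(tibble::tibble(stomach_id = names(grouping),
                          group = as.character(grouping)))
  }
  abort("cannot interpret `grouping`")
}

#' Percent numerical abundance (%N)
#'
#' For each predator group and prey unit, the share of all prey individuals
#' in that predator group: `%N = 100 * n_prey_i / n_prey_total`.
#'
#' @param study A [diet_study()].
#' @param grouping Stomach grouping: a column name of `stomachs` (e.g.
#'   `"year"`), a data frame `stomach_id`/`group`, or a tree assignment from
#'   [assign_groups()].
#' @param unit `"taxon"` (default; one row per taxon), `"family"` or
#'   `"group"` (lumped analysis prey groups).
#' @return Tibble with `group`, unit columns, `n` and `pct_N`.
#' @export
percent_N <- function(study, grouping, unit = c("taxon", "family")) {
  unit <- match.arg(unit)
  g <- stomach_grouping(study, grouping)
  prey <- dplyr::inner_join(study$prey, g, by = "stomach_id")
  key <- if (unit == "taxon") c("family", "taxon_id") else "family"
  out <- dplyr::count(prey, dplyr::across(dplyr::all_of(c("group", key))))
  out <- dplyr::mutate(dplyr::group_by(out, .data$group),
                       pct_N = 100 * .data$n / sum(.data$n))
  dplyr::ungroup(out)
}

#' Percent frequency of occurrence (%FO)
#'
#' For each predator group and prey unit, the share of non-empty stomachs in
#' that group containing the prey:
#' `%FO = 100 * n_stomachs_with_prey_i / n_stomachs`.
#'
#' @inheritParams percent_N
#' @return Tibble with `group`, unit columns, `occ`, `n_stomachs` and
#'   `pct_FO`.
#' @export
percent_FO <- function(study, grouping, unit = c("taxon", "family")) {
  unit <- match.arg(unit)
  g <- stomach_grouping(study, grouping)
  denom <- dplyr::count(g, .data$group, name = "n_stomachs")
  prey <- dplyr::inner_join(study$prey, g, by = "stomach_id")
  key <- if (unit == "taxon") c("family", "taxon_id") else "family"
  occ <- dplyr::distinct(prey, dplyr::across(dplyr::all_of(
    c("group", key, "stomach_id"))))
  occ <- dplyr::count(occ, dplyr::across(dplyr::all_of(c("group", key))),
                      name = "occ")
  out <- dplyr::left_join(occ, denom, by = "group")
  out$pct_FO <- 100 * out$occ / out$n_stomachs
  out
}

#' Diet-composition summary (%N and %FO)
#'
#' Joins [percent_N()] and [percent_FO()] into one table per predator group
#' and prey unit, the layout diet studies conventionally print.
#'
#' @inheritParams percent_N
#' @return Tibble with counts, occurrences and both percentages.
#' @export
diet_summary <- function(study, grouping, unit = c("taxon", "family")) {
  unit <- match.arg(unit)
  key <- if (unit == "taxon") c("family", "taxon_id") else "family"
  dplyr::full_join(percent_N(study, grouping, unit),
                   percent_FO(study, grouping, unit),
                   by = c("group", key))
}
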