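#' Regression-parameter tables
#'
#' Allometric conversions (hard part to whole length, length to mass, beak to
#' mass, operculum length to fork length, fork length to predator mass) are
#' user-supplied data, never hard-coded. Each row gives one regression with a
#' taxonomic scope; queries resolve by falling back from species to genus to
#' family to broad group, so the most specific applicable regression always
#' wins.
#'
#' Supported functional forms (`x` input, `y` output):
#' * `linear`: `y = a + b * x`
#' * `power`: `y = a * x^b`
#' * `log_linear`: `log(y) = a + b * log(x)` (natural log)
#'
#' Units: each row declares `input_unit` and `output_unit` (`mm`, `cm`, `g`
#' or `kg`); values are converted to the package's internal units (lengths in
#' mm, prey mass in g, predator lengths in cm and mass in kg) when the
#' regression is applied.
#'
#' @param path CSV file with columns `scope_level`
#'   (`species|genus|family|broad_group`), `scope_value`, `kind`
#'   (`hardpart_to_length|length_to_mass|beak_to_mass|ol_to_fl|fl_to_mass`),
#'   `form`, `a`, `b`, `input_unit`, `output_unit`.
#' @return A validated regression tibble (class `"diet_regressions"`).
#' @export
read_regressions <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_regressions(x)
}

#' @rdname read_regressions
#' @param x A data frame shaped like the regression CSV.
#' @export
validate_regressions <- function(x) {
  x <- tibble::as_tibble(x)
  assert_columns(x, c("scope_level", "scope_value", "kind", "form", "a", "b"),
                 "regression table")
  if (!"input_unit" %in% names(x)) x$input_unit <- "mm"
  if (!"output_unit" %in% names(x)) x$output_unit <- "mm"
  bad <- which(!x$form %in% c("linear", "power", "log_linear"))
  if (length(bad) > 0)
    abort(sprintf("unknown regression form %s in row(s) %s",
                  paste(unique(x$form[bad]), collapse = ", "),
                  paste(bad, collapse = ", ")),
          class = "tunadiet_parse_error")
  bad <- which(!x$kind %in% c("hardpart_to_length", "length_to_mass",
                              "beak_to_mass", "ol_to_fl", "fl_to_mass"))
  if (length(bad) > 0)
    abort(sprintf("unknown regression kind in row(s) %s",
                  paste(bad, collapse = ", ")),
          class = "tunadiet_parse_error")
  bad <- which(!x$scope_level %in% c("species", "genus", "family",
                                     "broad_group", "predator"))
  if (length(bad) > 0)
    abort(sprintf("unknown scope_level in row(s) %s",
                  paste(bad, collapse = ", ")),
          class = "tunadiet_parse_error")
  if (any(!is.finite(x$a)) || any(!is.finite(x$b)))
    abort("regression coefficients must be finite",
          class = "tunadiet_parse_error")
  class(x) <- c("diet_regressions", class(x))
  x
}

#' Read an energy-density table
#'
#' @param path CSV with columns `scope_level`, `scope_value`, `kj_per_g`
#'   (kJ per g wet mass).
#' @return A validated tibble (class `"diet_energy"`).
#' @export
read_energy_densities <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_energy_densities(x)
}

#' @rdname read_energy_densities
#' @param x A data frame shaped like the energy CSV.
#' @export
validate_energy_densities <- function(x) {
  x <- tibble::as_tibble(x)
  assert_columns(x, c("scope_level", "scope_value", "kj_per_g"),
                 "energy-density table")
  if (any(!is.finite(x$kj_per_g)) || any(x$kj_per_g <= 0))
    abort("kj_per_g must be positive and finite",
          class = "tunadiet_parse_error")
  class(x) <- c("diet_energy", class(x))
  x
}

# Taxonomic fallback order used by every resolver.
scope_chain <- function(species = NA, genus = NA, family = NA,
                        broad_group = NA) {
  tibble::tibble(
    scope_level = c("species", "genus", "family", "broad_group"),
    scope_value = as.character(c(species, genus, family, broad_group)))
}

#' Resolve a regression for a taxon
#'
#' Walks the species, genus, family, broad-group fallback chain and returns
#' the single most specific regression of the requested kind, or `NULL` when
#' nothing matches (a no-match is therefore distinguishable from a match).
#'
#' @param regressions A `"diet_regressions"` table.
#' @param kind Regression kind, e.g. `"length_to_mass"`.
#' @param species,genus,family,broad_group Taxon fields of the query; any may
#'   be `NA`.
#' @return A one-row tibble, or `NULL`.
#' @export
resolve_regression <- function(regressions, kind, species = NA, genus = NA,
                               family = NA, broad_group = NA) {
  cand <- regressions[regressions$kind == kind, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  chain <- scope_chain(species, genus, family, broad_group)
  for (i in seq_len(nrow(chain))) {
    if (is.na(chain$scope_value[i])) next
    hit <- cand[cand$scope_level == chain$scope_level[i] &
                  cand$scope_value == chain$scope_value[i], , drop = FALSE]
    if (nrow(hit) > 1)
      abort(sprintf("multiple %s regressions resolve for %s '%s'",
                    kind, chain$scope_level[i], chain$scope_value[i]),
            class = "tunadiet_integrity_error")
    if (nrow(hit) == 1) return(hit)
  }
  NULL
}

#' Resolve an energy density for a taxon
#'
#' @inheritParams resolve_regression
#' @param energy A `"diet_energy"` table.
#' @return Scalar kJ/g, or `NULL` when no entry resolves.
#' @export
resolve_energy_density <- function(energy, species = NA, genus = NA,
                                   family = NA, broad_group = NA) {
  if (is.null(energy)) return(NULL)
  chain <- scope_chain(species, genus, family, broad_group)
  for (i in seq_len(nrow(chain))) {
    if (is.na(chain$scope_value[i])) next
    hit <- energy[energy$scope_level == chain$scope_level[i] &
                    energy$scope_value == chain$scope_value[i], , drop = FALSE]
    if (nrow(hit) >= 1) return(hit$kj_per_g[1])
  }
  NULL
}

unit_factor <- function(unit) {
  switch(unit,
         mm = 1, cm = 10,        # lengths in mm internally
         g = 1, kg = 1000,       # masses in g internally
         abort(sprintf("unknown unit '%s'", unit),
               class = "tunadiet_parse_error"))
}

#' Evaluate or invert a regression
#'
#' `apply_regression()` maps an input in internal units (mm or g; predator
#' lengths cm, predator mass kg) through the regression, honouring the
#' declared units. `invert_regression()` is its exact inverse and is used by
#' the synthetic generator to fabricate hard-part measurements that
#' reconstruct to known true lengths.
#'
#' @param spec One-row regression tibble from [resolve_regression()].
#' @param x Input value(s) in the spec's `input_unit`.
#' @return Output value(s) in the spec's `output_unit`.
#' @export
apply_regression <- function(spec, x) {
  if (any(x <= 0, na.rm = TRUE) && spec$form[1] != "linear")
    abort("regression input must be positive", class = "tunadiet_domain_error")
  switch(spec$form[1],
         linear = spec$a[1] + spec$b[1] * x,
         power = spec$a[1] * x^spec$b[1],
         log_linear = exp(spec$a[1] + spec$b[1] * log(x)))
}

#' @rdname apply_regression
#' @param y Output value(s) in the spec's `output_unit`.
#' @export
invert_regression <- function(spec, y) {
  switch(spec$form[1],
         linear = (y - spec$a[1]) / spec$b[1],
         power = (y / spec$a[1])^(1 / spec$b[1]),
         log_linear = exp((log(y) - spec$a[1]) / spec$b[1]))
}

# Apply a regression taking internal units in and out.
# `in_internal`/`out_internal`: "mm", "cm", "g" or "kg".
apply_regression_internal <- function(spec, x, in_internal, out_internal) {
  xi <- x * unit_factor(in_internal) / unit_factor(spec$input_unit[1])
  y <- apply_regression(spec, xi)
  y * unit_factor(spec$output_unit[1]) / unit_factor(out_internal)
}

invert_regression_internal <- function(spec, y, in_internal, out_internal) {
  yi <- y * unit_factor(out_internal) / unit_factor(spec$output_unit[1])
  x <- invert_regression(spec, yi)
  x * unit_factor(spec$input_unit[1]) / unit_factor(in_internal)
}

#' Derive predator size fields
#'
#' Fills fork length from operculum length where fork length is missing
#' (using the `ol_to_fl` regression) and predator mass from fork length
#' (`fl_to_mass`). Stomachs with neither measurement are flagged, not
#' dropped: they stay in compositional analyses but are unusable for
#' body-mass-relative (energetic) analyses.
#'
#' @param study A [diet_study()] whose `regressions` hold `ol_to_fl` and
#'   `fl_to_mass` specs (scope level `"predator"`).
#' @param quiet Suppress the provenance message.
#' @return The study with `fl_cm`, `mass_kg` and a logical
#'   `size_known` column filled in `stomachs`.
#' @export
derive_predator_size <- function(study, quiet = FALSE) {
  reg <- study$regressions
  if (is.null(reg))
    abort("study carries no regression table", class = "tunadiet_schema_error")
  ol_fl <- reg[reg$kind == "ol_to_fl", , drop = FALSE]
  fl_mass <- reg[reg$kind == "fl_to_mass", , drop = FALSE]
  st <- study$stomachs
  from_ol <- is.na(st$fl_cm) & !is.na(st$ol_cm)
  if (any(from_ol)) {
    if (nrow(ol_fl) == 0)
      abort("no ol_to_fl regression available", class = "tunadiet_schema_error")
    st$fl_cm[from_ol] <-
      apply_regression_internal(ol_fl[1, ], st$ol_cm[from_ol], "cm", "cm")
  }
  need_mass <- is.na(st$mass_kg) & !is.na(st$fl_cm)
  if (any(need_mass)) {
    if (nrow(fl_mass) == 0)
      abort("no fl_to_mass regression available", class = "tunadiet_schema_error")
    st$mass_kg[need_mass] <-
      apply_regression_internal(fl_mass[1, ], st$fl_cm[need_mass], "cm", "kg")
  }
  st$size_known <- !is.na(st$mass_kg)
  if (!quiet && any(!st$size_known))
    inform(sprintf(
      "%d stomach(s) lack both fork and operculum length; excluded from %%BM analyses",
      sum(!st$size_known)))
  study$stomachs <- st
  study
}
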