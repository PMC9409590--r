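#' Analysis configuration
#'
#' Bundles the tunable thresholds of the diet pipeline. The defaults are the
#' settings of the Southern California Bight bluefin workflow: rare families
#' are lumped when their mean proportional abundance is at most 1%, stomachs
#' with reconstructed contents above 3% of predator body mass are excluded
#' from energetic analyses, prey-specific metrics are reported for prey found
#' in at least 20% of a group's stomachs, and a mean prey-specific proportion
#' above 0.5 flags specialist feeding.
#'
#' @param lump_threshold Proportion; families with mean proportional abundance
#'   strictly above this are kept as their own prey group.
#' @param bm_exclusion Proportion of predator body mass; stomachs with
#'   reconstructed contents strictly above `100 * bm_exclusion` %BM are
#'   excluded from mass/energy analyses.
#' @param fo_threshold Proportion; minimum frequency of occurrence for a prey
#'   group to enter the prey-specific (feeding-strategy) table.
#' @param specialist_threshold Mean prey-specific proportion strictly above
#'   this is classed as specialist feeding.
#' @param permutations Number of permutations for PERMANOVA/PERMDISP.
#' @param cv_folds Cross-validation folds for the diet tree.
#' @param seed Integer seed used by seed-consuming steps when none is given.
#' @return A list with class `"diet_config"`.
#' @export
#' @examples
#' diet_config()
diet_config <- function(lump_threshold = 0.01,
                        bm_exclusion = 0.03,
                        fo_threshold = 0.20,
                        specialist_threshold = 0.5,
                        permutations = 999L,
                        cv_folds = 10L,
                        seed = 1L) {
  props <- c(lump_threshold = lump_threshold, bm_exclusion = bm_exclusion,
             fo_threshold = fo_threshold,
             specialist_threshold = specialist_threshold)
  for (nm in names(props)) {
    if (!is_scalar_number(props[[nm]]) || props[[nm]] <= 0 || props[[nm]] >= 1)
      abort(sprintf("`%s` must be a proportion in (0, 1)", nm))
  }
  structure(list(lump_threshold = lump_threshold,
                 bm_exclusion = bm_exclusion,
                 fo_threshold = fo_threshold,
                 specialist_threshold = specialist_threshold,
                 permutations = as.integer(permutations),
                 cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)),
            class = "diet_config")
}

#' Read an analysis configuration from YAML
#'
#' Unknown keys are rejected so typos do not silently fall back to defaults.
#'
#' @param path Path to a YAML file whose keys are arguments of
#'   [diet_config()].
#' @return A `"diet_config"` list.
#' @export
read_diet_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(diet_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    abort(sprintf("Unknown configuration key(s): %s", paste(bad, collapse = ", ")))
  do.call(diet_config, vals)
}

#' @export
print.diet_config <- function(x, ...) {
  cat("<diet_config>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
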