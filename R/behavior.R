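# Prey-specific abundance metrics and the specialist/generalist
# classification (Amundsen-style feeding-strategy analysis).

#' Classify feeding strategy from mean prey-specific proportion
#'
#' Specialist feeding requires a mean prey-specific proportion strictly
#' above the threshold (default 0.5); a mean of exactly 0.5 is generalist.
#'
#' @param mean_p Mean prey-specific proportion(s).
#' @param threshold Specialisation threshold.
#' @return Character vector, `"specialist"` or `"generalist"`.
#' @export
classify_strategy <- function(mean_p, threshold = 0.5) {
  ifelse(mean_p > threshold, "specialist", "generalist")
}

#' Prey-specific proportion and number per stomach group
#'
#' For each prey group found in at least `fo_threshold` (default 20%) of a
#' stomach group's stomachs, computes the mean and standard deviation of
#' its proportional abundance and its count over only those stomachs that
#' contain it, plus its frequency of occurrence. Conditioning on presence
#' means the prey-specific proportion is never smaller than the prey's mean
#' proportional abundance over all stomachs; a mean above 0.5 indicates
#' specialisation on that prey.
#'
#' @param study A [diet_study()].
#' @param grouping Stomach grouping (see [percent_N()]).
#' @param dmat Optional precomputed [diet_matrix()]; its lumping defines
#'   the prey groups.
#' @param fo_threshold Minimum frequency of occurrence (proportion).
#' @return Tibble of class `"prey_specific"`: `group`, `prey_group`, `FO`,
#'   `occ`, `n_stomachs`, `mean_p`, `sd_p`, `mean_n`, `sd_n`, `strategy`.
#'   Single-occurrence prey have `NA` standard deviations.
#' @export
prey_specific_table <- function(study, grouping, dmat = NULL,
                                fo_threshold = 0.2) {
  dmat <- dmat %||% diet_matrix(study)
  lump_map <- attr(dmat, "lump_map")
  g <- stomach_grouping(study, grouping)
  prey <- study$prey
  base <- base_group_label(prey$family)
  prey$prey_group <- if (is.null(lump_map)) base else
    unname(lump_map[base])
  counts <- dplyr::count(prey, .data$stomach_id, .data$prey_group)
  counts <- dplyr::mutate(dplyr::group_by(counts, .data$stomach_id),
                          p = .data$n / sum(.data$n))
  counts <- dplyr::ungroup(counts)
  counts <- dplyr::inner_join(counts, g, by = "stomach_id")
  denom <- dplyr::count(g, .data$group, name = "n_stomachs")
  out <- dplyr::summarise(
    dplyr::group_by(counts, .data$group, .data$prey_group),
    occ = dplyr::n(),
    mean_p = mean(.data$p), sd_p = sd(.data$p),
    mean_n = mean(.data$n), sd_n = sd(.data$n),
    .groups = "drop")
  out <- dplyr::left_join(out, denom, by = "group")
  out$FO <- out$occ / out$n_stomachs
  out <- out[out$FO >= fo_threshold, ]
  out$strategy <- classify_strategy(out$mean_p)
  out <- out[, c("group", "prey_group", "FO", "occ", "n_stomachs",
                 "mean_p", "sd_p", "mean_n", "sd_n", "strategy")]
  class(out) <- c("prey_specific", class(out))
  out
}

#' Plot the feeding-strategy diagram
#'
#' Prey-specific proportion against frequency of occurrence per prey group
#' (one panel per stomach group): points in the upper half indicate
#' specialisation, points to the right indicate frequently consumed prey.
#'
#' @param object A [prey_specific_table()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prey_specific <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$FO, y = .data$mean_p,
                               label = .data$prey_group)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = .data$mean_n), alpha = 0.7) +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::facet_wrap(~group) +
    ggplot2::lims(x = c(0, 1), y = c(0, 1)) +
    ggplot2::labs(x = "frequency of occurrence",
                  y = "mean prey-specific proportion",
                  size = "mean prey-specific number") +
    ggplot2::theme_minimal()
}
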