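# Coverage-based diet-diversity accumulation over stomachs.
#
# Stomachs are the sampling units (incidence framework): Y_j counts the
# stomachs containing prey group j out of T units, U = sum(Y_j). Diversity
# is the Hill number of order 1 (exponential Shannon). Interpolation uses
# the exact expected incidence frequency counts of a hypergeometric
# subsample of t units, with entropy terms scaled by the expected incidence
# total u_t = t U / T; at t = T this is exactly the observed incidence
# entropy, exponentiated. Extrapolation blends the observed entropy with a
# coverage-adjusted asymptotic entropy estimate in proportion T/t.

#' Incidence frequencies of prey groups over stomachs
#'
#' @param dmat A [diet_matrix()] (or any stomach-by-group matrix/tibble of
#'   nonnegative values).
#' @param stomach_ids Optional subset of stomachs.
#' @return An object of class `"incidence_freq"`: list with `T` (number of
#'   sampling units), `Y` (named incidence frequencies, zero-frequency
#'   groups dropped) and `U = sum(Y)`.
#' @export
incidence_freq <- function(dmat, stomach_ids = NULL) {
  m <- as_composition_matrix(dmat)
  if (!is.null(stomach_ids)) m <- m[rownames(m) %in% stomach_ids, ,
                                    drop = FALSE]
  Y <- colSums(m > 0)
  Y <- Y[Y > 0]
  structure(list(T = nrow(m), Y = Y, U = sum(Y)), class = "incidence_freq")
}

#' @export
print.incidence_freq <- function(x, ...) {
  cat(sprintf("<incidence_freq> %d units, %d groups, U = %d\n",
              x$T, length(x$Y), as.integer(x$U)))
  invisible(x)
}

# E[Q_k(t)], k = 1..t: expected number of groups with incidence k in a
# random subsample of t of the T units (multivariate hypergeometric).
expected_Qk <- function(inc, t) {
  Tn <- inc$T
  out <- numeric(t)
  for (y in inc$Y) {
    k <- seq_len(min(t, y))
    lp <- lchoose(y, k) + lchoose(Tn - y, t - k) - lchoose(Tn, t)
    out[k] <- out[k] + exp(lp)
  }
  out
}

# Coverage-adjusted asymptotic Shannon entropy (Chao-Shen style estimator
# on incidence relative frequencies with a Horvitz-Thompson correction).
asymptotic_entropy <- function(inc) {
  Q1 <- sum(inc$Y == 1)
  C_hat <- 1 - Q1 / inc$U
  if (C_hat <= 0) {
    p <- inc$Y / inc$U
    return(-sum(p * log(p)))
  }
  p_adj <- C_hat * inc$Y / inc$U
  -sum(p_adj * log(p_adj) / (1 - (1 - p_adj)^inc$T))
}

observed_entropy <- function(inc) {
  p <- inc$Y / inc$U
  -sum(p * log(p))
}

#' Hill-Shannon diversity at sample size t
#'
#' The effective number of equally common prey groups (Hill number of order
#' 1) that a sample of `t` stomachs is expected to show. For `t <= T` this
#' is the exact expectation over hypergeometric subsamples (entropy terms
#' scaled by the expected incidence total); beyond `T` the observed and
#' asymptotic entropies are blended in proportion `T/t`. Extrapolating past
#' twice the observed sample size triggers a warning.
#'
#' @param inc An [incidence_freq()].
#' @param t Integer sample size(s), `>= 1`.
#' @return Numeric vector of diversity estimates (`>= 1`).
#' @export
hill_shannon <- function(inc, t) {
  if (any(t < 1)) abort("t must be >= 1")
  if (any(t > 2 * inc$T))
    warn(sprintf(
      "extrapolating diversity beyond twice the sample size (T = %d) is unreliable",
      inc$T))
  H_obs <- observed_entropy(inc)
  vapply(t, function(ti) {
    if (ti <= inc$T) {
      u_t <- ti * inc$U / inc$T
      EQ <- expected_Qk(inc, ti)
      k <- seq_len(ti)
      x <- k / u_t
      exp(-sum(x * log(x) * EQ))
    } else {
      H_inf <- max(asymptotic_entropy(inc), H_obs)
      exp(inc$T / ti * H_obs + (1 - inc$T / ti) * H_inf)
    }
  }, numeric(1))
}

#' Hill richness (order 0) at sample size t
#'
#' Expected number of prey groups detected in `t` stomachs (classic
#' incidence rarefaction), with Chao2-style extrapolation beyond `T`.
#'
#' @inheritParams hill_shannon
#' @return Numeric vector.
#' @export
hill_richness <- function(inc, t) {
  Tn <- inc$T
  Q1 <- sum(inc$Y == 1)
  Q2 <- sum(inc$Y == 2)
  Q0 <- if (Q2 > 0) (Tn - 1) / Tn * Q1^2 / (2 * Q2) else
    (Tn - 1) / Tn * Q1 * (Q1 - 1) / 2
  vapply(t, function(ti) {
    if (ti <= Tn) {
      sum(1 - exp(lchoose(Tn - inc$Y, ti) - lchoose(Tn, ti)))
    } else {
      A <- if (Q1 > 0) Tn * Q0 / (Tn * Q0 + Q1) else 1
      length(inc$Y) + Q0 * (1 - A^(ti - Tn))
    }
  }, numeric(1))
}

#' Sample coverage at sample size t
#'
#' Estimated fraction of the incidence distribution represented by a sample
#' of `t` stomachs: the incidence-based (singleton/doubleton) coverage
#' estimator at `t = T`, its rarefied form for smaller `t`, and the
#' geometric extension beyond `T`.
#'
#' @inheritParams hill_shannon
#' @return Coverage values in `[0, 1]`.
#' @export
sample_coverage <- function(inc, t) {
  if (any(t < 1)) abort("t must be >= 1")
  Tn <- inc$T
  U <- inc$U
  Y <- inc$Y
  Q1 <- sum(Y == 1)
  Q2 <- sum(Y == 2)
  Q0 <- if (Q2 > 0) (Tn - 1) / Tn * Q1^2 / (2 * Q2) else
    (Tn - 1) / Tn * Q1 * (Q1 - 1) / 2
  A <- if (Q1 > 0) Tn * Q0 / (Tn * Q0 + Q1) else 1
  vapply(t, function(ti) {
    if (ti < Tn) {
      yy <- Y[(Tn - Y) >= ti]
      1 - sum(yy / U * exp(lchoose(Tn - yy, ti) - lchoose(Tn - 1, ti)))
    } else {
      1 - Q1 / U * A^(ti - Tn + 1)
    }
  }, numeric(1))
}

#' Smallest sample size reaching a target coverage
#'
#' Scans the coverage curve up to twice the observed number of stomachs.
#'
#' @param inc An [incidence_freq()].
#' @param target Coverage target in (0, 1), e.g. 0.99.
#' @return Integer `t`, or `NA` (with a warning) when the target is not
#'   reached by `2T`.
#' @export
size_at_coverage <- function(inc, target) {
  if (target <= 0 || target >= 1) abort("target must be in (0, 1)")
  for (ti in seq_len(2 * inc$T)) {
    if (sample_coverage(inc, ti) >= target) return(ti)
  }
  warn(sprintf("coverage %.3f not reached by t = 2T = %d", target,
               2 * inc$T))
  NA_integer_
}

#' Diversity accumulation curves per stomach group
#'
#' Interpolated and extrapolated Hill-Shannon diversity and sample coverage
#' for each group of stomachs, up to double each group's sample size.
#'
#' @param dmat A [diet_matrix()].
#' @param grouping Tibble `stomach_id`/`group` (e.g. from
#'   [assign_groups()]`$assignments`) or a named vector.
#' @param step Evaluate every `step`-th sample size (default chooses about
#'   40 points per group).
#' @return Tibble (class `"diversity_curve"`) with `group`, `t`, `method`
#'   (`"interpolated"`/`"extrapolated"`), `qD` and `coverage`.
#' @export
diversity_curve <- function(dmat, grouping, step = NULL) {
  if (inherits(grouping, "diet_cart_groups")) grouping <- grouping$assignments
  if (!is.data.frame(grouping))
    grouping <- tibble::tibble(stomach_id = names(grouping),
                               group = as.character(grouping))
  out <- purrr::map_dfr(split(grouping$stomach_id, grouping$group),
                        .id = "group", function(ids) {
    inc <- incidence_freq(dmat, ids)
    st <- step %||% max(1L, floor(2 * inc$T / 40))
    ts <- sort(unique(c(seq(1L, 2L * inc$T, by = st), inc$T, 2L * inc$T)))
    tibble::tibble(
      t = ts,
      method = ifelse(ts <= inc$T, "interpolated", "extrapolated"),
      qD = hill_shannon(inc, ts),
      coverage = sample_coverage(inc, ts))
  })
  class(out) <- c("diversity_curve", class(out))
  out
}

#' @export
autoplot.diversity_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$t, y = .data$qD,
                               colour = .data$group,
                               linetype = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(
      values = c(interpolated = "solid", extrapolated = "dashed")) +
    ggplot2::labs(x = "stomachs sampled",
                  y = "diet diversity (Hill-Shannon)") +
    ggplot2::theme_minimal()
}
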