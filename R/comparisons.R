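# Rank-based group comparisons for prey length, number and energetic value.
#
# Distributions of per-stomach prey metrics are skewed and often
# heteroscedastic, so parametric mean comparisons are avoided: the
# homoscedastic path is Kruskal-Wallis plus pairwise Wilcoxon rank-sum
# tests with Bonferroni adjustment; the heteroscedastic path is Welch's
# heteroscedastic ANOVA computed on global average ranks followed by
# Games-Howell post hoc contrasts on the same ranks.

check_groups <- function(values, labels, min_size = 1L) {
  f <- factor(labels)
  if (nlevels(f) < 2) abort("need at least two groups")
  sizes <- table(f)
  if (any(sizes < min_size))
    abort(sprintf("group(s) %s have fewer than %d observations",
                  paste(names(sizes)[sizes < min_size], collapse = ", "),
                  min_size))
  keep <- !is.na(values) & !is.na(labels)
  list(values = values[keep], f = droplevels(f[keep]))
}

#' Kruskal-Wallis rank-sum test
#'
#' Thin tidy wrapper over [stats::kruskal.test()] (H statistic with the
#' standard ties correction, chi-square reference on g - 1 df).
#'
#' @param values Numeric response.
#' @param labels Group labels.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `method`.
#' @export
kruskal_wallis <- function(values, labels) {
  d <- check_groups(values, labels)
  if (length(unique(d$values)) == 1) {
    return(tibble::tibble(statistic = 0, df = nlevels(d$f) - 1L,
                          p_value = 1, method = "Kruskal-Wallis"))
  }
  kt <- kruskal.test(d$values, d$f)
  tibble::tibble(statistic = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p_value = kt$p.value, method = "Kruskal-Wallis")
}

#' Pairwise Wilcoxon rank-sum tests with Bonferroni adjustment
#'
#' Raw two-sided p-values are multiplied by the number of pairs and capped
#' at 1. Exact enumeration is used for small tie-free pairs and the normal
#' approximation with ties correction otherwise ([stats::wilcox.test()]
#' semantics, exact below 10 per group).
#'
#' @inheritParams kruskal_wallis
#' @return Tibble `group1`, `group2`, `statistic` (rank-sum W), `p_raw`,
#'   `p_value` (Bonferroni).
#' @export
pairwise_wilcoxon_bonferroni <- function(values, labels) {
  d <- check_groups(values, labels)
  levs <- levels(d$f)
  prs <- utils::combn(levs, 2, simplify = FALSE)
  m <- length(prs)
  purrr::map_dfr(prs, function(pr) {
    x <- d$values[d$f == pr[1]]
    y <- d$values[d$f == pr[2]]
    exact <- length(x) < 10 && length(y) < 10 &&
      !any(duplicated(c(x, y)))
    wt <- suppressWarnings(wilcox.test(x, y, exact = exact,
                                       correct = !exact))
    tibble::tibble(group1 = pr[1], group2 = pr[2],
                   statistic = unname(wt$statistic),
                   p_raw = wt$p.value,
                   p_value = min(1, wt$p.value * m))
  })
}

#' Welch's heteroscedastic ANOVA on ranks
#'
#' Replaces the response by its global average ranks and applies Welch's
#' unequal-variance F test ([stats::oneway.test()], Satterthwaite-type
#' denominator df). Appropriate when distributions are non-normal *and*
#' group variances differ.
#'
#' @inheritParams kruskal_wallis
#' @return One-row tibble: `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
welch_anova_ranks <- function(values, labels) {
  d <- check_groups(values, labels, min_size = 2L)
  r <- rank(d$values)
  v <- tapply(r, d$f, var)
  if (any(v == 0))
    abort(sprintf("group(s) %s have zero within-group rank variance",
                  paste(names(v)[v == 0], collapse = ", ")))
  ow <- oneway.test(r ~ d$f, var.equal = FALSE)
  tibble::tibble(statistic = unname(ow$statistic),
                 df1 = unname(ow$parameter[1]),
                 df2 = unname(ow$parameter[2]),
                 p_value = ow$p.value, method = "Welch ANOVA on ranks")
}

#' Games-Howell post hoc contrasts
#'
#' Pairwise comparisons for heteroscedastic designs: per pair, the Welch
#' t statistic from group means and variances with Satterthwaite df, with
#' the p-value from the studentized-range distribution
#' (`q = t * sqrt(2)`) over the full number of groups. Applied to ranks
#' when following [welch_anova_ranks()].
#'
#' @inheritParams kruskal_wallis
#' @param on_ranks Replace values by global average ranks first.
#' @return Tibble `group1`, `group2`, `estimate` (mean difference), `t`,
#'   `df`, `p_value`.
#' @export
games_howell <- function(values, labels, on_ranks = FALSE) {
  d <- check_groups(values, labels, min_size = 2L)
  x <- if (on_ranks) rank(d$values) else d$values
  levs <- levels(d$f)
  k <- length(levs)
  stats_tbl <- purrr::map_dfr(levs, function(l) {
    xi <- x[d$f == l]
    tibble::tibble(group = l, n = length(xi), mean = mean(xi),
                   var = var(xi))
  })
  purrr::map_dfr(utils::combn(levs, 2, simplify = FALSE), function(pr) {
    a <- stats_tbl[stats_tbl$group == pr[1], ]
    b <- stats_tbl[stats_tbl$group == pr[2], ]
    se2 <- a$var / a$n + b$var / b$n
    tstat <- abs(a$mean - b$mean) / sqrt(se2)
    df <- se2^2 / ((a$var / a$n)^2 / (a$n - 1) +
                     (b$var / b$n)^2 / (b$n - 1))
    p <- ptukey(tstat * sqrt(2), nmeans = k, df = df, lower.tail = FALSE)
    tibble::tibble(group1 = pr[1], group2 = pr[2],
                   estimate = a$mean - b$mean, t = tstat, df = df,
                   p_value = p)
  })
}

# Brown-Forsythe (Levene on medians) homogeneity-of-variance screen:
# classical ANOVA on absolute deviations from group medians.
brown_forsythe <- function(values, labels) {
  d <- check_groups(values, labels, min_size = 2L)
  dev <- abs(d$values - ave(d$values, d$f, FUN = median))
  ow <- oneway.test(dev ~ d$f, var.equal = TRUE)
  tibble::tibble(statistic = unname(ow$statistic),
                 df1 = unname(ow$parameter[1]),
                 df2 = unname(ow$parameter[2]),
                 p_value = ow$p.value, method = "Brown-Forsythe")
}

#' Choose and run the rank-based comparison workflow
#'
#' Screens homogeneity of variance with a Brown-Forsythe (Levene on
#' medians) test: when variances are homogeneous the Kruskal-Wallis global
#' test with Bonferroni-adjusted pairwise Wilcoxon contrasts is used; when
#' heteroscedastic, Welch's ANOVA on ranks with Games-Howell contrasts.
#'
#' @inheritParams kruskal_wallis
#' @param alpha Significance level of the variance screen.
#' @return List with `screen`, `choice` (`"kruskal"` or `"welch"`),
#'   `global` and `pairwise` tibbles.
#' @export
choose_rank_test <- function(values, labels, alpha = 0.05) {
  screen <- brown_forsythe(values, labels)
  if (screen$p_value < alpha) {
    list(screen = screen, choice = "welch",
         global = welch_anova_ranks(values, labels),
         pairwise = games_howell(values, labels, on_ranks = TRUE))
  } else {
    list(screen = screen, choice = "kruskal",
         global = kruskal_wallis(values, labels),
         pairwise = pairwise_wilcoxon_bonferroni(values, labels))
  }
}

#' Pairwise Pearson correlations among covariates
#'
#' Pairwise-complete Pearson coefficients, the collinearity screen applied
#' to candidate tree covariates (year, month, latitude, longitude, fork
#' length).
#'
#' @param data Data frame; non-numeric columns are dropped.
#' @param vars Optional column subset.
#' @return Symmetric correlation matrix.
#' @export
covariate_correlations <- function(data, vars = NULL) {
  if (!is.null(vars)) data <- data[, vars, drop = FALSE]
  num <- data[, vapply(data, is.numeric, logical(1)), drop = FALSE]
  cor(as.matrix(num), use = "pairwise.complete.obs")
}
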