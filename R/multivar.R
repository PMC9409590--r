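# Dissimilarity-based comparisons of diet composition among stomach groups:
# Bray-Curtis dissimilarity, distance-based PERMANOVA (Anderson's pseudo-F
# with unrestricted permutation of raw labels), PERMDISP (homogeneity of
# multivariate dispersion, delegated to vegan's betadisper/permutest) and
# principal coordinate analysis.

#' Bray-Curtis dissimilarity of diet compositions
#'
#' `D_ik = sum_j |p_ij - p_kj| / sum_j (p_ij + p_kj)`; for rows that each
#' sum to one this is half the L1 distance, bounded in `[0, 1]` with 1 for
#' disjoint prey supports.
#'
#' @param dmat A [diet_matrix()] (or plain matrix of nonnegative rows).
#' @return A `dist` object labelled by stomach id.
#' @export
bray_curtis <- function(dmat) {
  m <- as_composition_matrix(dmat)
  vegan::vegdist(m, method = "bray")
}

# Pseudo-F from a squared-dissimilarity matrix and integer group codes.
permanova_F <- function(D2, g, n_g) {
  N <- nrow(D2)
  a <- length(n_g)
  ss_t <- sum(D2) / (2 * N)
  ss_w <- 0
  for (k in seq_len(a)) {
    idx <- which(g == k)
    ss_w <- ss_w + sum(D2[idx, idx]) / (2 * n_g[k])
  }
  ss_a <- ss_t - ss_w
  list(F = (ss_a / (a - 1)) / (ss_w / (N - a)), ss_a = ss_a, ss_w = ss_w,
       ss_t = ss_t)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 0L
  for (i in seq_len(n)) {
    block <- cbind(i, ifelse(sub >= i, sub + 1L, sub))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

permanova_one <- function(D, labels, n_perm, exact) {
  Dm <- as.matrix(D)
  D2 <- Dm^2
  f <- factor(labels)
  g <- as.integer(f)
  n_g <- tabulate(g)
  if (any(n_g < 2)) abort("every group needs at least 2 members")
  N <- nrow(D2)
  a <- nlevels(f)
  obs <- permanova_F(D2, g, n_g)
  if (exact) {
    perms <- all_permutations(N)
    Fs <- vapply(seq_len(nrow(perms)), function(i) {
      permanova_F(D2, g[perms[i, ]], n_g)$F
    }, numeric(1))
    p <- mean(Fs >= obs$F - 1e-12)
    n_used <- nrow(perms)
  } else {
    count <- 0L
    for (i in seq_len(n_perm)) {
      gp <- sample(g)
      if (permanova_F(D2, gp, n_g)$F >= obs$F - 1e-12) count <- count + 1L
    }
    p <- (count + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  tibble::tibble(df1 = a - 1L, df2 = N - a, SS_among = obs$ss_a,
                 SS_within = obs$ss_w, SS_total = obs$ss_t,
                 pseudo_F = obs$F, p_value = p, n_perm = n_used)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-way distance-based PERMANOVA: the pseudo-F statistic compares
#' among-group to within-group sums of squared dissimilarities and its
#' significance comes from unrestricted permutation of the raw group
#' labels, with the add-one correction `p = (count + 1) / (n_perm + 1)`.
#' Pairwise contrasts report `t = sqrt(F)` per group pair with raw
#' (unadjusted) permutation p-values, together with mean within- and
#' among-group percent similarity (`100 * (1 - mean dissimilarity)`).
#'
#' @param D A `dist` (e.g. [bray_curtis()]).
#' @param labels Group label per object of `D`.
#' @param n_perm Number of permutations.
#' @param seed Integer seed for the permutation stream.
#' @param pairwise Also run all pairwise contrasts.
#' @param exact Enumerate all label permutations instead of sampling
#'   (feasible only for small n); p is then the exact tail proportion.
#' @return Object of class `"diet_permanova"` with `global`, `pairwise` and
#'   `similarity` tibbles.
#' @export
permanova <- function(D, labels, n_perm = 999, seed = 1L, pairwise = TRUE,
                      exact = FALSE) {
  stopifnot(inherits(D, "dist"))
  labels <- as.character(labels)
  if (length(labels) != attr(D, "Size"))
    abort("labels length must match the dissimilarity matrix")
  Dm <- as.matrix(D)
  res <- with_seed(seed, {
    global <- permanova_one(D, labels, n_perm, exact)
    levs <- sort(unique(labels))
    pw <- NULL
    if (pairwise && length(levs) > 2) {
      pw <- purrr::map_dfr(utils::combn(levs, 2, simplify = FALSE),
                           function(pr) {
        idx <- which(labels %in% pr)
        sub <- stats::as.dist(Dm[idx, idx])
        r <- permanova_one(sub, labels[idx], n_perm, exact)
        tibble::tibble(group1 = pr[1], group2 = pr[2],
                       t = sqrt(r$pseudo_F), pseudo_F = r$pseudo_F,
                       p_value = r$p_value)
      })
    } else if (pairwise) {
      pw <- tibble::tibble(group1 = levs[1], group2 = levs[2],
                           t = sqrt(global$pseudo_F),
                           pseudo_F = global$pseudo_F,
                           p_value = global$p_value)
    }
    list(global = global, pairwise = pw)
  })
  levs <- sort(unique(labels))
  within <- purrr::map_dfr(levs, function(l) {
    idx <- which(labels == l)
    d <- Dm[idx, idx][lower.tri(diag(length(idx)))]
    tibble::tibble(group1 = l, group2 = l,
                   mean_similarity_pct = 100 * (1 - mean(d)))
  })
  among <- purrr::map_dfr(utils::combn(levs, 2, simplify = FALSE),
                          function(pr) {
    d <- Dm[labels == pr[1], labels == pr[2]]
    tibble::tibble(group1 = pr[1], group2 = pr[2],
                   mean_similarity_pct = 100 * (1 - mean(d)))
  })
  structure(list(global = res$global, pairwise = res$pairwise,
                 similarity = dplyr::bind_rows(within, among),
                 n_perm = n_perm, seed = seed),
            class = "diet_permanova")
}

#' @export
print.diet_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f (df %d, %d), p = %.4g\n",
              x$global$pseudo_F, x$global$df1, x$global$df2,
              x$global$p_value))
  if (!is.null(x$pairwise)) {
    cat("pairwise t:\n")
    print(as.data.frame(x$pairwise), row.names = FALSE)
  }
  invisible(x)
}

#' @export
tidy.diet_permanova <- function(x, ...) x$pairwise %||% x$global

#' @export
glance.diet_permanova <- function(x, ...) x$global

#' Homogeneity of multivariate dispersion (PERMDISP)
#'
#' A multivariate analogue of Levene's test: distances from each stomach to
#' its group centroid in the principal-coordinate embedding (with the
#' negative-eigenvalue correction of Anderson's method) are compared among
#' groups by ANOVA, with permutation of least-squares residuals for the
#' p-value. Delegates to [vegan::betadisper()] and [vegan::permutest()]
#' with centroid dispersion.
#'
#' @inheritParams permanova
#' @return Object of class `"diet_permdisp"`: `global` (F, p) and
#'   `pairwise` (observed t with permuted p per pair), plus the underlying
#'   `betadisper` object in `$model`.
#' @export
permdisp <- function(D, labels, n_perm = 999, seed = 1L) {
  labels <- as.character(labels)
  if (any(table(labels) < 2)) abort("every group needs at least 2 members")
  mod <- vegan::betadisper(D, group = factor(labels), type = "centroid")
  pt <- with_seed(seed,
                  vegan::permutest(mod, pairwise = TRUE,
                                   permutations = n_perm))
  tab <- pt$tab
  levs <- levels(factor(labels))
  pw <- NULL
  if (length(levs) > 1 && !is.null(pt$pairwise)) {
    prs <- utils::combn(levs, 2, simplify = FALSE)
    pw <- purrr::map_dfr(seq_along(prs), function(i) {
      key <- paste(prs[[i]], collapse = "-")
      tibble::tibble(group1 = prs[[i]][1], group2 = prs[[i]][2],
                     t = abs(unname(pt$statistic[paste0(key, " (t)")])),
                     p_value = unname(pt$pairwise$permuted[key]))
    })
  }
  structure(list(
    global = tibble::tibble(df1 = tab$Df[1], df2 = tab$Df[2],
                            F = tab$F[1], p_value = tab[1, "Pr(>F)"],
                            n_perm = n_perm),
    pairwise = pw, model = mod, seed = seed),
    class = "diet_permdisp")
}

#' @export
print.diet_permdisp <- function(x, ...) {
  cat(sprintf("PERMDISP: F = %.3f (df %d, %d), p = %.4g\n",
              x$global$F, x$global$df1, x$global$df2, x$global$p_value))
  if (!is.null(x$pairwise)) print(as.data.frame(x$pairwise),
                                  row.names = FALSE)
  invisible(x)
}

#' @export
tidy.diet_permdisp <- function(x, ...) x$pairwise %||% x$global

#' @export
glance.diet_permdisp <- function(x, ...) x$global

#' Principal coordinate analysis
#'
#' Classical (metric) multidimensional scaling by eigendecomposition of the
#' double-centred `-0.5 * D^2` matrix. Coordinates are returned for the
#' positive-eigenvalue axes only; the full eigenvalue spectrum (including
#' any negative eigenvalues produced by semi-metric dissimilarities such as
#' Bray-Curtis) is reported.
#'
#' @param D A symmetric `dist` or matrix with zero diagonal.
#' @return Object of class `"diet_pcoa"`: `points` tibble (`stomach_id`,
#'   `Axis1`, ...), `eigenvalues`, and `rel_eig` (share of the positive
#'   eigenvalue sum).
#' @export
pcoa <- function(D) {
  Dm <- as.matrix(D)
  if (!isSymmetric(unname(Dm), tol = 1e-8))
    abort("dissimilarity matrix must be symmetric",
          class = "tunadiet_domain_error")
  n <- nrow(Dm)
  A <- -0.5 * Dm^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), nrow = length(pos))
  colnames(coords) <- paste0("Axis", seq_along(pos))
  ids <- rownames(Dm) %||% as.character(seq_len(n))
  pts <- tibble::as_tibble(coords)
  pts <- tibble::add_column(pts, stomach_id = ids, .before = 1)
  structure(list(points = pts, eigenvalues = e$values,
                 rel_eig = pmax(e$values, 0) / sum(pmax(e$values, 0))),
            class = "diet_pcoa")
}

#' @export
print.diet_pcoa <- function(x, ...) {
  k <- sum(x$eigenvalues > 0)
  cat(sprintf("<diet_pcoa> %d objects, %d positive axes (first two: %.1f%%, %.1f%% of positive inertia)\n",
              nrow(x$points), k, 100 * x$rel_eig[1], 100 * x$rel_eig[2]))
  invisible(x)
}

#' Plot a PCoA ordination
#'
#' @param object A `"diet_pcoa"`.
#' @param grouping Optional stomach grouping (tibble `stomach_id`/`group`)
#'   used to colour points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.diet_pcoa <- function(object, grouping = NULL, ...) {
  pts <- object$points
  if (!is.null(grouping)) {
    if (inherits(grouping, "diet_cart_groups")) grouping <- grouping$assignments
    pts <- dplyr::left_join(pts, grouping, by = "stomach_id")
  } else {
    pts$group <- "all"
  }
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$Axis1, y = .data$Axis2,
                                    colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = sprintf("PCoA 1 (%.1f%%)", 100 * object$rel_eig[1]),
      y = sprintf("PCoA 2 (%.1f%%)", 100 * object$rel_eig[2])) +
    ggplot2::theme_minimal()
}
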