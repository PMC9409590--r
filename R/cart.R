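# Regression tree with a multivariate compositional response.
#
# The response is the stomachs-by-prey-groups proportion matrix; node
# impurity is the within-node sum of squared Euclidean deviations of the
# compositions about the node mean, and splits maximise the impurity
# decrease by exhaustive search over covariate thresholds (numeric) or
# binary level partitions (categorical). Surrogate splits route stomachs
# with missing covariates and contribute to variable importance. The
# affirmative branch of a split goes left.

#' Tree-growing control parameters
#'
#' @param min_split Minimum stomachs in a node for a split attempt.
#' @param min_bucket Minimum stomachs in a child node.
#' @param cp Complexity parameter: a split must decrease impurity by at
#'   least `cp` times the root impurity.
#' @param max_depth Maximum tree depth.
#' @param max_surrogates Surrogate splits retained per node.
#' @param max_cat_levels Categorical covariates with more levels are skipped
#'   (binary partitions are enumerated exhaustively).
#' @return A list of class `"cart_control"`.
#' @export
cart_control <- function(min_split = 20L, min_bucket = 7L, cp = 0.01,
                         max_depth = 30L, max_surrogates = 4L,
                         max_cat_levels = 12L) {
  structure(list(min_split = as.integer(min_split),
                 min_bucket = as.integer(min_bucket), cp = cp,
                 max_depth = as.integer(max_depth),
                 max_surrogates = as.integer(max_surrogates),
                 max_cat_levels = as.integer(max_cat_levels)),
            class = "cart_control")
}

#' Within-node impurity of a set of compositions
#'
#' Sum over rows of the squared Euclidean distance to the mean composition:
#' `sum_i ||p_i - p_bar||^2`.
#'
#' @param compositions Numeric matrix (rows are compositions) or data frame.
#' @return Non-negative scalar.
#' @export
node_impurity <- function(compositions) {
  m <- as.matrix(compositions)
  n <- nrow(m)
  if (n == 0) return(0)
  s <- colSums(m)
  sum(m^2) - sum(s^2) / n
}

# Best threshold split of one numeric covariate. Returns NULL when no
# admissible split exists. Ties go to the smaller threshold.
best_numeric_split <- function(Y, x, min_bucket) {
  ord <- order(x)
  xs <- x[ord]
  Ys <- Y[ord, , drop = FALSE]
  n <- length(xs)
  if (n < 2 * min_bucket) return(NULL)
  cs <- apply(Ys, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = n)
  S <- cs[n, ]
  k <- seq_len(n - 1)
  valid <- (xs[k] < xs[k + 1]) & (k >= min_bucket) & ((n - k) >= min_bucket)
  if (!any(valid)) return(NULL)
  csk <- cs[k, , drop = FALSE]
  normL <- rowSums(csk^2)
  normR <- rowSums((matrix(S, nrow = length(k), ncol = length(S),
                           byrow = TRUE) - csk)^2)
  dec <- normL / k + normR / (n - k) - sum(S^2) / n
  dec[!valid] <- -Inf
  kk <- which.max(dec)
  list(type = "num", threshold = (xs[kk] + xs[kk + 1]) / 2,
       decrease = dec[kk])
}

# Best binary level-partition split of one categorical covariate.
best_categorical_split <- function(Y, x, min_bucket, max_cat_levels) {
  x <- factor(x)
  levs <- levels(droplevels(x))
  L <- length(levs)
  if (L < 2 || L > max_cat_levels) return(NULL)
  x <- factor(x, levels = levs)
  M <- rowsum(Y, x)                     # level sums, L x G
  nl <- as.integer(table(x))
  n <- length(x)
  S <- colSums(M)
  base <- sum(S^2) / n
  best <- NULL
  # level 1 fixed to the right side to avoid complements
  for (mask in seq_len(2^(L - 1) - 1)) {
    inL <- c(FALSE, as.logical(bitwAnd(mask, 2^(seq_len(L - 1) - 1))))
    nL <- sum(nl[inL])
    if (nL < min_bucket || (n - nL) < min_bucket) next
    SL <- colSums(M[inL, , drop = FALSE])
    dec <- sum(SL^2) / nL + sum((S - SL)^2) / (n - nL) - base
    if (is.null(best) || dec > best$decrease + 1e-12) {
      best <- list(type = "cat", subset = levs[inL], decrease = dec)
    }
  }
  best
}

#' Best split of a node
#'
#' Exhaustive search over all midpoint thresholds of numeric covariates and
#' all binary partitions of categorical covariates, maximising the decrease
#' in compositional impurity. Ties break by covariate order, then by the
#' smaller threshold. Rows with a missing value in a covariate are ignored
#' while scoring that covariate.
#'
#' @param Y Composition matrix (rows sum to 1).
#' @param X Data frame of covariates, same row count.
#' @param min_bucket Minimum child size.
#' @param max_cat_levels See [cart_control()].
#' @return A list (`var`, `type`, `threshold` or `subset`, `decrease`), or
#'   `NULL` when no admissible split exists.
#' @export
best_split <- function(Y, X, min_bucket = 7L, max_cat_levels = 12L) {
  Y <- as.matrix(Y)
  best <- NULL
  for (j in seq_along(X)) {
    x <- X[[j]]
    obs <- !is.na(x)
    if (sum(obs) < 2 * min_bucket) next
    Yo <- Y[obs, , drop = FALSE]
    xo <- x[obs]
    res <- if (is.numeric(xo)) {
      best_numeric_split(Yo, xo, min_bucket)
    } else {
      best_categorical_split(Yo, xo, min_bucket, max_cat_levels)
    }
    if (!is.null(res) &&
        (is.null(best) || res$decrease > best$decrease + 1e-12)) {
      best <- c(list(var = names(X)[j]), res)
    }
  }
  if (!is.null(best) && best$decrease <= 1e-12) return(NULL)
  best
}

# Evaluate a split rule on raw covariate values: TRUE = left (affirmative),
# NA where the covariate is missing.
rule_goes_left <- function(rule, x) {
  if (rule$type == "num") x < rule$threshold else {
    out <- as.character(x) %in% rule$subset
    out[is.na(x)] <- NA
    out
  }
}

#' Surrogate splits for a primary split
#'
#' For every covariate other than the primary, finds the rule that best
#' reproduces the primary split's left/right assignment. Agreement is
#' scaled against the majority-direction baseline,
#' `(matches - majority) / (n - majority)`, and only surrogates with
#' positive adjusted agreement are kept, ranked by agreement.
#'
#' @param X Covariate data frame for the node's rows.
#' @param primary_var Name of the primary covariate.
#' @param go_left Logical vector: primary assignment (NA where the primary
#'   covariate is missing).
#' @param max_surrogates Maximum surrogates kept.
#' @param max_cat_levels See [cart_control()].
#' @return A list of surrogate rules (`var`, `type`, `threshold`/`subset`,
#'   `left_if_yes`, `agreement`), best first.
#' @export
surrogate_splits <- function(X, primary_var, go_left, max_surrogates = 4L,
                             max_cat_levels = 12L) {
  use <- !is.na(go_left)
  out <- list()
  for (j in seq_along(X)) {
    if (names(X)[j] == primary_var) next
    x <- X[[j]]
    ok <- use & !is.na(x)
    n_ok <- sum(ok)
    if (n_ok < 2) next
    gl <- go_left[ok]
    xo <- x[ok]
    majority <- max(sum(gl), sum(!gl))
    if (n_ok == majority) next
    cand <- NULL
    if (is.numeric(xo)) {
      ord <- order(xo)
      xs <- xo[ord]
      gs <- gl[ord]
      k <- seq_len(n_ok - 1)
      valid <- xs[k] < xs[k + 1]
      if (!any(valid)) next
      cum_left <- cumsum(gs)
      total_left <- sum(gs)
      # orientation A: x < t -> left
      matches_a <- cum_left[k] + ((n_ok - k) - (total_left - cum_left[k]))
      # orientation B: x < t -> right
      matches_b <- n_ok - matches_a
      matches_a[!valid] <- -Inf
      matches_b[!valid] <- -Inf
      ka <- which.max(matches_a)
      kb <- which.max(matches_b)
      if (matches_a[ka] >= matches_b[kb]) {
        cand <- list(type = "num", threshold = (xs[ka] + xs[ka + 1]) / 2,
                     left_if_yes = TRUE, matches = matches_a[ka])
      } else {
        cand <- list(type = "num", threshold = (xs[kb] + xs[kb + 1]) / 2,
                     left_if_yes = FALSE, matches = matches_b[kb])
      }
    } else {
      xf <- factor(xo)
      if (nlevels(droplevels(xf)) > max_cat_levels) next
      tab <- table(xf, gl)
      if (ncol(tab) < 2) next
      left_levels <- rownames(tab)[tab[, "TRUE"] >= tab[, "FALSE"]]
      matches <- sum(pmax(tab[, "TRUE"], tab[, "FALSE"]))
      cand <- list(type = "cat", subset = left_levels, left_if_yes = TRUE,
                   matches = matches)
    }
    agreement <- (cand$matches - majority) / (n_ok - majority)
    if (agreement <= 0) next
    out[[length(out) + 1L]] <- list(var = names(X)[j], type = cand$type,
                                    threshold = cand$threshold %||% NA_real_,
                                    subset = cand$subset %||% NULL,
                                    left_if_yes = cand$left_if_yes,
                                    agreement = agreement)
  }
  if (length(out) == 0) return(out)
  ord <- order(vapply(out, function(s) -s$agreement, numeric(1)))
  out[ord][seq_len(min(length(out), max_surrogates))]
}

# Route node rows: primary rule first, then surrogates in order, then the
# majority direction.
route_left <- function(node, X, idx) {
  goleft <- rule_goes_left(node$split, X[[node$split$var]][idx])
  for (s in node$surrogates) {
    nas <- which(is.na(goleft))
    if (length(nas) == 0) break
    sl <- rule_goes_left(s, X[[s$var]][idx[nas]])
    if (!s$left_if_yes) sl <- !sl
    goleft[nas] <- sl
  }
  goleft[is.na(goleft)] <- node$majority_left
  goleft
}

# Grow the full tree. Y: composition matrix; X: covariate data frame.
grow_tree <- function(Y, X, control = cart_control()) {
  n <- nrow(Y)
  root_ss <- node_impurity(Y)
  min_gain <- control$cp * root_ss
  nodes <- list()
  make_node <- function(rows, depth, parent) {
    id <- length(nodes) + 1L
    m <- colSums(Y[rows, , drop = FALSE]) / length(rows)
    nodes[[id]] <<- list(id = id, parent = parent, rows = rows,
                         n = length(rows), mean = m,
                         ss = node_impurity(Y[rows, , drop = FALSE]),
                         depth = depth, terminal = TRUE, split = NULL,
                         surrogates = list(), majority_left = TRUE,
                         children = c(NA_integer_, NA_integer_))
    id
  }
  try_split <- function(id) {
    nd <- nodes[[id]]
    if (nd$n < control$min_split || nd$depth >= control$max_depth) return()
    if (nd$ss <= 1e-12) return()
    sp <- best_split(Y[nd$rows, , drop = FALSE],
                     X[nd$rows, , drop = FALSE],
                     min_bucket = control$min_bucket,
                     max_cat_levels = control$max_cat_levels)
    if (is.null(sp) || sp$decrease < min_gain) return()
    goleft_primary <- rule_goes_left(sp, X[[sp$var]][nd$rows])
    surr <- surrogate_splits(X[nd$rows, , drop = FALSE], sp$var,
                             goleft_primary,
                             max_surrogates = control$max_surrogates,
                             max_cat_levels = control$max_cat_levels)
    nodes[[id]]$split <<- sp
    nodes[[id]]$surrogates <<- surr
    nodes[[id]]$majority_left <<-
      sum(goleft_primary, na.rm = TRUE) >= sum(!goleft_primary, na.rm = TRUE)
    goleft <- route_left(nodes[[id]], X, nd$rows)
    l_rows <- nd$rows[goleft]
    r_rows <- nd$rows[!goleft]
    if (length(l_rows) == 0 || length(r_rows) == 0) {
      nodes[[id]]$split <<- NULL
      nodes[[id]]$surrogates <<- list()
      return()
    }
    nodes[[id]]$terminal <<- FALSE
    lid <- make_node(l_rows, nd$depth + 1L, id)
    rid <- make_node(r_rows, nd$depth + 1L, id)
    nodes[[id]]$children <<- c(lid, rid)
    try_split(lid)
    try_split(rid)
  }
  root <- make_node(seq_len(n), 0L, NA_integer_)
  try_split(root)
  structure(list(nodes = nodes, root = root, root_ss = root_ss, n = n,
                 covariates = names(X), control = control),
            class = "cart_tree")
}
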