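# Cost-complexity pruning, ten-fold cross-validation with the 1-SE rule,
# variable importance and group assignment for the compositional tree.

# Nodes reachable from the root given the collapsed state.
active_nodes <- function(tree, collapsed) {
  act <- rep(FALSE, length(tree$nodes))
  stack <- tree$root
  while (length(stack) > 0) {
    id <- stack[1]
    stack <- stack[-1]
    act[id] <- TRUE
    nd <- tree$nodes[[id]]
    if (!nd$terminal && !collapsed[id]) stack <- c(stack, nd$children)
  }
  act
}

# Subtree resubstitution error and leaf count per node (children have
# larger ids than their parent, so reverse id order is a postorder).
subtree_measures <- function(tree, collapsed) {
  nn <- length(tree$nodes)
  R_sub <- numeric(nn)
  leaves <- integer(nn)
  for (id in rev(seq_len(nn))) {
    nd <- tree$nodes[[id]]
    if (nd$terminal || collapsed[id]) {
      R_sub[id] <- nd$ss
      leaves[id] <- 1L
    } else {
      ch <- nd$children
      R_sub[id] <- R_sub[ch[1]] + R_sub[ch[2]]
      leaves[id] <- leaves[ch[1]] + leaves[ch[2]]
    }
  }
  list(R_sub = R_sub, leaves = leaves)
}

# Weakest-link cost-complexity sequence: list of snapshots
# (alpha, collapsed, leaves, resub), alpha nondecreasing, ending at the
# root-only tree.
prune_sequence <- function(tree) {
  nn <- length(tree$nodes)
  collapsed <- rep(FALSE, nn)
  is_internal <- !vapply(tree$nodes, `[[`, logical(1), "terminal")
  snap <- function(alpha, collapsed) {
    sm <- subtree_measures(tree, collapsed)
    list(alpha = alpha, collapsed = collapsed,
         leaves = sm$leaves[tree$root], resub = sm$R_sub[tree$root])
  }
  snaps <- list(snap(0, collapsed))
  repeat {
    act <- active_nodes(tree, collapsed)
    cand <- which(act & is_internal & !collapsed)
    if (length(cand) == 0) break
    sm <- subtree_measures(tree, collapsed)
    ss_node <- vapply(tree$nodes[cand], `[[`, numeric(1), "ss")
    g <- (ss_node - sm$R_sub[cand]) / pmax(sm$leaves[cand] - 1L, 1L)
    a <- min(g)
    collapsed[cand[g <= a + 1e-12]] <- TRUE
    snaps[[length(snaps) + 1L]] <- snap(max(a, 0), collapsed)
  }
  snaps
}

# Last snapshot whose alpha does not exceed `alpha`.
snapshot_for_alpha <- function(snaps, alpha) {
  alphas <- vapply(snaps, `[[`, numeric(1), "alpha")
  snaps[[max(which(alphas <= alpha + 1e-12))]]
}

# Terminal node id reached by each row of X.
assign_terminal <- function(tree, collapsed, X) {
  out <- integer(nrow(X))
  rec <- function(id, idx) {
    nd <- tree$nodes[[id]]
    if (nd$terminal || collapsed[id]) {
      out[idx] <<- id
      return()
    }
    gl <- route_left(nd, X, idx)
    if (any(gl)) rec(nd$children[1], idx[gl])
    if (any(!gl)) rec(nd$children[2], idx[!gl])
  }
  if (nrow(X) > 0) rec(tree$root, seq_len(nrow(X)))
  out
}

node_mean_matrix <- function(tree, ids) {
  t(vapply(ids, function(id) tree$nodes[[id]]$mean,
           numeric(length(tree$nodes[[tree$root]]$mean))))
}

#' Variable importance of a (pruned) compositional tree
#'
#' Each primary split credits its impurity decrease to its covariate; each
#' surrogate credits `agreement * decrease` to the surrogate covariate.
#' Importances are normalised so the maximum is exactly 1 (all zero for a
#' root-only tree).
#'
#' @param tree A grown `cart_tree` (internal) or a fitted [diet_cart()].
#' @param collapsed Optional collapsed state (defaults to the selected
#'   subtree for fitted models).
#' @return Named numeric vector over covariates, in `[0, 1]`.
#' @export
variable_importance <- function(tree, collapsed = NULL) {
  if (inherits(tree, "diet_cart")) {
    collapsed <- collapsed %||% tree$selected$collapsed
    tree <- tree$tree
  }
  collapsed <- collapsed %||% rep(FALSE, length(tree$nodes))
  imp <- setNames(numeric(length(tree$covariates)), tree$covariates)
  act <- active_nodes(tree, collapsed)
  for (id in which(act)) {
    nd <- tree$nodes[[id]]
    if (nd$terminal || collapsed[id] || is.null(nd$split)) next
    imp[nd$split$var] <- imp[nd$split$var] + nd$split$decrease
    for (s in nd$surrogates) {
      imp[s$var] <- imp[s$var] + s$agreement * nd$split$decrease
    }
  }
  if (max(imp) > 0) imp <- imp / max(imp)
  imp
}

#' Fit a compositional diet tree
#'
#' Grows a binary regression tree on the stomach-by-prey-group proportion
#' matrix, computes the cost-complexity pruning sequence, estimates the
#' relative error of every subtree by k-fold cross-validation (pooled
#' held-out sum of squares over the root sum of squares) and selects the
#' smallest subtree within one standard error of the minimum (the 1-SE
#' rule). Missing covariate values are routed by surrogate splits.
#'
#' @param dmat A [diet_matrix()].
#' @param covariates Data frame with `stomach_id` plus covariate columns
#'   (numeric or factor), one row per stomach of `dmat`.
#' @param control A [cart_control()].
#' @param folds Cross-validation folds (default 10).
#' @param seed Seed for fold assignment.
#' @return An object of class `"diet_cart"`: the full tree, the cp table
#'   (`size`, `alpha`, `rel_error`, `cv_error`, `cv_se`), the selected
#'   subtree, normalised variable importances, terminal assignments of the
#'   training stomachs and per-terminal cross-validated proportion of the
#'   most abundant prey group.
#' @export
fit_diet_cart <- function(dmat, covariates, control = cart_control(),
                          folds = 10L, seed = 1L) {
  assert_columns(covariates, "stomach_id", "`covariates`")
  ids <- dmat$stomach_id
  ix <- match(ids, covariates$stomach_id)
  if (anyNA(ix))
    abort("`covariates` lacks rows for some stomachs of the diet matrix")
  X <- as.data.frame(covariates[ix, setdiff(names(covariates), "stomach_id"),
                                drop = FALSE])
  Y <- as_composition_matrix(dmat)
  n <- nrow(Y)
  G <- ncol(Y)
  tree <- grow_tree(Y, X, control)
  snaps <- prune_sequence(tree)
  m <- length(snaps)
  alphas <- vapply(snaps, `[[`, numeric(1), "alpha")
  sizes <- vapply(snaps, `[[`, integer(1), "leaves")
  resub <- vapply(snaps, `[[`, numeric(1), "resub") / tree$root_ss

  cv_error <- rep(NA_real_, m)
  cv_se <- rep(NA_real_, m)
  cv_pred <- NULL
  k <- min(as.integer(folds), n)
  if (k >= 2 && tree$root_ss > 0) {
    beta <- if (m == 1) 0 else c(sqrt(alphas[-m] * alphas[-1]), Inf)
    fold_of <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
    err <- matrix(0, k, m)
    cv_pred <- lapply(seq_len(m), function(j) matrix(NA_real_, n, G))
    for (f in seq_len(k)) {
      tr <- which(fold_of != f)
      te <- which(fold_of == f)
      t_f <- grow_tree(Y[tr, , drop = FALSE], X[tr, , drop = FALSE], control)
      s_f <- prune_sequence(t_f)
      Xte <- X[te, , drop = FALSE]
      for (j in seq_len(m)) {
        snap <- snapshot_for_alpha(s_f, beta[j])
        term <- assign_terminal(t_f, snap$collapsed, Xte)
        P <- node_mean_matrix(t_f, term)
        err[f, j] <- sum((Y[te, , drop = FALSE] - P)^2)
        cv_pred[[j]][te, ] <- P
      }
    }
    cv_error <- colSums(err) / tree$root_ss
    # per-fold relative errors, size-normalised so their mean tracks the
    # pooled estimate
    n_f <- as.numeric(table(factor(fold_of, levels = seq_len(k))))
    fold_rel <- err / (tree$root_ss * n_f / n)
    cv_se <- apply(fold_rel, 2, sd) / sqrt(k)
  }

  if (all(is.na(cv_error))) {
    sel_j <- m  # no CV possible: keep the fully pruned (root) tree honest
  } else {
    i_min <- which.min(cv_error)
    thr <- cv_error[i_min] + cv_se[i_min]
    sel_j <- max(which(cv_error <= thr + 1e-12))
  }
  sel_collapsed <- snaps[[sel_j]]$collapsed
  term_full <- assign_terminal(tree, sel_collapsed, X)
  terminals <- sort(unique(term_full))
  labels <- setNames(sprintf("node_%d", terminals), terminals)

  cv_dominant <- NULL
  if (!is.null(cv_pred)) {
    Pj <- cv_pred[[sel_j]]
    cv_dominant <- purrr::map_dfr(terminals, function(id) {
      rows <- which(term_full == id)
      dom <- which.max(tree$nodes[[id]]$mean)
      tibble::tibble(node_id = id, label = labels[as.character(id)],
                     n = length(rows),
                     dominant_group = colnames(Y)[dom],
                     cv_mean_dominant_p = mean(Pj[rows, dom]))
    })
  }

  structure(list(
    tree = tree, snaps = snaps,
    cptable = tibble::tibble(size = sizes, alpha = alphas,
                             rel_error = resub, cv_error = cv_error,
                             cv_se = cv_se),
    selected = list(j = sel_j, collapsed = sel_collapsed,
                    size = sizes[sel_j], cv_error = cv_error[sel_j],
                    cv_se = cv_se[sel_j], rel_error = resub[sel_j]),
    r_squared = if (is.na(cv_error[sel_j])) NA_real_ else 1 - cv_error[sel_j],
    importance = variable_importance(tree, sel_collapsed),
    groups = tibble::tibble(stomach_id = ids,
                            node_id = term_full,
                            group = unname(labels[as.character(term_full)])),
    cv_dominant = cv_dominant,
    prey_groups = colnames(Y), folds = k, seed = seed),
    class = "diet_cart")
}

#' Fit the diet tree directly from a study
#'
#' Builds the diet matrix ([diet_matrix()]) and covariate table from the
#' study and calls [fit_diet_cart()].
#'
#' @param study A [diet_study()].
#' @param covariates Covariate column names from `study$stomachs`.
#' @param lump_threshold Passed to [diet_matrix()].
#' @param ... Passed to [fit_diet_cart()].
#' @return A `"diet_cart"` fit.
#' @export
diet_cart <- function(study,
                      covariates = c("year", "month", "lat", "lon", "fl_cm"),
                      lump_threshold = 0.01, ...) {
  dmat <- diet_matrix(study, lump_threshold = lump_threshold)
  covariates <- intersect(covariates, names(study$stomachs))
  cov <- study$stomachs[, c("stomach_id", covariates)]
  fit_diet_cart(dmat, cov, ...)
}

#' Assign stomachs to terminal diet groups
#'
#' Routes each (non-empty) stomach down the selected subtree; stomachs with
#' missing covariates follow surrogate splits and, failing those, the
#' majority direction, so no stomach is dropped.
#'
#' @param fit A [fit_diet_cart()] object.
#' @param covariates Data frame with `stomach_id` and the tree's covariates;
#'   defaults to the training assignment.
#' @return An object of class `"diet_cart_groups"` whose `assignments`
#'   tibble has `stomach_id`, `node_id`, `group`.
#' @export
assign_groups <- function(fit, covariates = NULL) {
  if (is.null(covariates)) {
    asg <- fit$groups
  } else {
    assert_columns(covariates, "stomach_id", "`covariates`")
    X <- as.data.frame(covariates[, fit$tree$covariates, drop = FALSE])
    term <- assign_terminal(fit$tree, fit$selected$collapsed, X)
    asg <- tibble::tibble(stomach_id = as.character(covariates$stomach_id),
                          node_id = term,
                          group = sprintf("node_%d", term))
  }
  structure(list(assignments = asg), class = "diet_cart_groups")
}

#' Predicted diet composition for new stomachs
#'
#' @param object A fitted `"diet_cart"`.
#' @param newdata Data frame of covariates (defaults to training data
#'   terminal means).
#' @param ... Unused.
#' @return Tibble of predicted prey-group proportions.
#' @export
predict.diet_cart <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    ids <- object$groups$node_id
  } else {
    X <- as.data.frame(newdata[, object$tree$covariates, drop = FALSE])
    ids <- assign_terminal(object$tree, object$selected$collapsed, X)
  }
  out <- tibble::as_tibble(node_mean_matrix(object$tree, ids))
  names(out) <- object$prey_groups
  out
}
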