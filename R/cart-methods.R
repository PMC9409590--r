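# Display, tidier and plotting methods for fitted diet trees.

rule_text <- function(rule) {
  if (is.null(rule)) return("")
  if (rule$type == "num") {
    sprintf("%s < %g", rule$var, rule$threshold)
  } else {
    sprintf("%s in {%s}", rule$var, paste(rule$subset, collapse = ", "))
  }
}

#' @export
print.diet_cart <- function(x, ...) {
  cat(sprintf(
    "Compositional diet tree: %d stomachs, %d prey groups, %d terminal nodes\n",
    x$tree$n, length(x$prey_groups), x$selected$size))
  if (!is.na(x$selected$cv_error))
    cat(sprintf("cv relative error %.3f (SE %.3f), R-squared %.2f\n",
                x$selected$cv_error, x$selected$cv_se, x$r_squared))
  imp <- sort(x$importance[x$importance > 0], decreasing = TRUE)
  if (length(imp) > 0)
    cat("variable importance:",
        paste(sprintf("%s=%.2f", names(imp), imp), collapse = ", "), "\n")
  cat("\n")
  collapsed <- x$selected$collapsed
  rec <- function(id, indent) {
    nd <- x$tree$nodes[[id]]
    leaf <- nd$terminal || collapsed[id]
    dom <- which.max(nd$mean)
    cat(sprintf("%s%s n=%d  top: %s (%.2f)%s\n",
                strrep("  ", indent),
                if (leaf) sprintf("[node_%d]", id) else
                  sprintf("%s?", rule_text(nd$split)),
                nd$n, names(nd$mean)[dom], nd$mean[dom],
                if (leaf) "" else "  (yes -> left)"))
    if (!leaf) {
      rec(nd$children[1], indent + 1)
      rec(nd$children[2], indent + 1)
    }
  }
  rec(x$tree$root, 0)
  invisible(x)
}

#' Tidy a fitted diet tree
#'
#' One row per node of the selected subtree, with split rules, surrogate
#' counts, node sizes and impurities.
#'
#' @param x A `"diet_cart"` fit.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.diet_cart <- function(x, ...) {
  collapsed <- x$selected$collapsed
  act <- active_nodes(x$tree, collapsed)
  purrr::map_dfr(which(act), function(id) {
    nd <- x$tree$nodes[[id]]
    leaf <- nd$terminal || collapsed[id]
    dom <- which.max(nd$mean)
    tibble::tibble(
      node_id = id, parent = nd$parent, depth = nd$depth, n = nd$n,
      terminal = leaf,
      split = if (leaf) NA_character_ else rule_text(nd$split),
      impurity_decrease = if (leaf) NA_real_ else nd$split$decrease,
      n_surrogates = if (leaf) NA_integer_ else length(nd$surrogates),
      surrogates = if (leaf) NA_character_ else
        paste(vapply(nd$surrogates, function(s)
          sprintf("%s (%.2f)", rule_text(s), s$agreement), character(1)),
          collapse = "; "),
      impurity = nd$ss,
      dominant_group = names(nd$mean)[dom],
      dominant_p = unname(nd$mean[dom]))
  })
}

#' One-row summary of a fitted diet tree
#'
#' @param x A `"diet_cart"` fit.
#' @param ... Unused.
#' @return A tibble with `n`, `n_groups`, `n_leaves`, `rel_error`,
#'   `cv_error`, `cv_se` and `r_squared` (1 minus the selected subtree's
#'   cross-validated relative error).
#' @export
glance.diet_cart <- function(x, ...) {
  tibble::tibble(n = x$tree$n, n_groups = length(x$prey_groups),
                 n_leaves = x$selected$size,
                 rel_error = x$selected$rel_error,
                 cv_error = x$selected$cv_error,
                 cv_se = x$selected$cv_se,
                 r_squared = x$r_squared)
}

#' Plot a fitted diet tree
#'
#' Dendrogram-style layout with the split condition at each internal node
#' (affirmative branch to the left) and terminal nodes annotated with their
#' size and dominant prey group.
#'
#' @param object A `"diet_cart"` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.diet_cart <- function(object, ...) {
  collapsed <- object$selected$collapsed
  leaves_x <- new.env()
  counter <- new.env()
  assign("i", 0, envir = counter)
  layout <- function(id) {
    nd <- object$tree$nodes[[id]]
    leaf <- nd$terminal || collapsed[id]
    if (leaf) {
      i <- get("i", envir = counter) + 1
      assign("i", i, envir = counter)
      return(tibble::tibble(node_id = id, x = i, depth = nd$depth,
                            leaf = TRUE))
    }
    l <- layout(nd$children[1])
    r <- layout(nd$children[2])
    me <- tibble::tibble(node_id = id,
                         x = mean(c(l$x[l$node_id == nd$children[1]],
                                    r$x[r$node_id == nd$children[2]])),
                         depth = nd$depth, leaf = FALSE)
    dplyr::bind_rows(me, l, r)
  }
  nodes <- layout(object$tree$root)
  nodes$y <- -nodes$depth
  lab <- vapply(seq_len(nrow(nodes)), function(i) {
    nd <- object$tree$nodes[[nodes$node_id[i]]]
    if (nodes$leaf[i]) {
      dom <- which.max(nd$mean)
      sprintf("node_%d\nn=%d\n%s %.2f", nd$id, nd$n, names(nd$mean)[dom],
              nd$mean[dom])
    } else rule_text(nd$split)
  }, character(1))
  nodes$label <- lab
  edges <- purrr::map_dfr(which(!nodes$leaf), function(i) {
    nd <- object$tree$nodes[[nodes$node_id[i]]]
    ch <- nodes[match(nd$children, nodes$node_id), ]
    tibble::tibble(x = nodes$x[i], y = nodes$y[i], xend = ch$x, yend = ch$y)
  })
  p <- ggplot2::ggplot()
  if (nrow(edges) > 0)
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "grey50")
  p + ggplot2::geom_label(
    data = nodes,
    ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
    size = 3) +
    ggplot2::theme_void()
}
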