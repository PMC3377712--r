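#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a ZINB fit
#'
#' @param x a [fit_zinb()] result.
#' @param ... unused.
#' @return tibble with one row per count-model coefficient (`term`,
#'   `estimate`) plus the `zero_inflation_pi` and `dispersion_theta` rows.
#' @method tidy zinb_fit
#' @export
tidy.zinb_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = names(x$coefficients),
                   estimate = unname(x$coefficients),
                   component = "count"),
    tibble::tibble(term = c("zero_inflation_pi", "dispersion_theta"),
                   estimate = c(x$pi, x$theta),
                   component = "mixture")
  )
}

#' @rdname tidy.zinb_fit
#' @method glance zinb_fit
#' @export
glance.zinb_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$logLik, df = x$df, n = x$n,
    pi = x$pi, theta = x$theta, converged = x$converged
  )
}

#' Tidy an edge PCA
#'
#' @param x an [edge_pca()] result.
#' @param ... unused.
#' @return loadings in long form: `edge_id`, `component`, `loading`.
#' @method tidy edge_pca
#' @export
tidy.edge_pca <- function(x, ...) {
  tidyr::pivot_longer(x$vectors, -"edge_id", names_to = "component",
                      values_to = "loading")
}

#' @rdname tidy.edge_pca
#' @method glance edge_pca
#' @export
glance.edge_pca <- function(x, ...) {
  tibble::tibble(
    n_components = length(x$values),
    total_variance = x$total_variance,
    var_explained_1 = x$var_explained[1],
    var_explained_2 = if (length(x$var_explained) > 1) x$var_explained[2] else NA_real_
  )
}

#' Tidy an elastic-net sign model
#'
#' @param x an [elasticnet_fit()] result.
#' @param ... unused.
#' @return the nonzero coefficients (`taxon`, `estimate`, `criterion`).
#' @method tidy sign_model
#' @export
tidy.sign_model <- function(x, ...) {
  dplyr::mutate(x$coefficients, criterion = x$criterion)
}

#' @rdname tidy.sign_model
#' @method glance sign_model
#' @export
glance.sign_model <- function(x, ...) {
  tibble::tibble(
    criterion = x$criterion, alpha = x$alpha, lambda = x$lambda,
    rule = x$rule, n_selected = nrow(x$coefficients), n = x$n,
    cv_error = x$cv$mean_error[match(x$lambda, x$cv$lambda)]
  )
}

#' Tidy an interaction LRT table
#'
#' @param x an [interaction_lrt()] result.
#' @param ... unused.
#' @return the table as a plain tibble.
#' @method tidy interaction_lrt
#' @export
tidy.interaction_lrt <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Scores plot for an edge PCA
#'
#' @param object an [edge_pca()] result.
#' @param meta optional sample metadata joined by `sample`; `colour` names
#'   one of its columns.
#' @param colour metadata column mapped to point colour.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot edge_pca
#' @export
autoplot.edge_pca <- function(object, meta = NULL, colour = NULL, ...) {
  d <- object$scores
  if (!is.null(meta)) d <- dplyr::left_join(d, meta, by = "sample")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if (!is.null(colour) && !is.null(meta)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]), size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::labs(
    x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
    y = if (length(object$var_explained) > 1) {
      sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])
    } else "PC2"
  ) + ggplot2::theme_minimal()
}

#' Heatmap of a co-occurrence analysis
#'
#' @param object a [cooccurrence()] result.
#' @param ... unused.
#' @return a ggplot tile heatmap with taxa in clustering order.
#' @method autoplot cooccurrence
#' @export
autoplot.cooccurrence <- function(object, ...) {
  ord <- object$clustering$labels[object$clustering$order]
  d <- tibble::as_tibble(as.data.frame.table(object$correlation,
                                             stringsAsFactors = FALSE))
  names(d) <- c("taxon_a", "taxon_b", "correlation")
  d$taxon_a <- factor(d$taxon_a, levels = ord)
  d$taxon_b <- factor(d$taxon_b, levels = ord)
  ggplot2::ggplot(d, ggplot2::aes(.data$taxon_a, .data$taxon_b,
                                  fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Discard-reason bar chart for a QC report
#'
#' @param object a `qc_report` (from [demultiplex_and_filter()]).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot qc_report
#' @export
autoplot.qc_report <- function(object, ...) {
  d <- dplyr::bind_rows(
    object$discards,
    tibble::tibble(criterion = "retained", n = object$n_retained)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$criterion, .data$n),
                                  y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "reads") +
    ggplot2::theme_minimal()
}

#' Dendrogram-style plot of a squash clustering
#'
#' Draws the (generally non-ultrametric) merge tree with branch lengths in
#' KR units and bootstrap supports (when present) at internal nodes.
#'
#' @param object a `squash_tree`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot squash_tree
#' @export
autoplot.squash_tree <- function(object, ...) {
  phy <- object$tree
  n_tip <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)
  ord <- phy$tip.label[order(depth[seq_len(n_tip)])]
  ypos <- numeric(n_tip + phy$Nnode)
  ypos[seq_len(n_tip)] <- match(phy$tip.label, rev(ord))
  for (nd in internal_nodes_postorder(phy)) {
    kids <- phy$edge[phy$edge[, 1] == nd, 2]
    ypos[nd] <- mean(ypos[kids])
  }
  seg <- tibble::tibble(
    x = depth[phy$edge[, 1]], xend = depth[phy$edge[, 2]],
    y = ypos[phy$edge[, 2]], yend = ypos[phy$edge[, 2]]
  )
  seg_v <- tibble::tibble(
    x = depth[phy$edge[, 1]], xend = depth[phy$edge[, 1]],
    y = ypos[phy$edge[, 1]], yend = ypos[phy$edge[, 2]]
  )
  tips <- tibble::tibble(x = depth[seq_len(n_tip)], y = ypos[seq_len(n_tip)],
                         label = phy$tip.label)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = dplyr::bind_rows(seg, seg_v),
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = tips,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
                       hjust = -0.05, size = 3) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0.02, 0.25))) +
    ggplot2::labs(x = "KR distance", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank(),
                   panel.grid.minor.y = ggplot2::element_blank())
}

#' Loadings-on-tree plot for an edge PCA component
#'
#' Positive loadings draw in one colour and negative in another, with line
#' width proportional to magnitude — the standard way of reading an edge
#' PCA eigenvector on the reference tree.
#'
#' @param object an `edge_projection` (from
#'   [project_component_on_tree()]).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot edge_projection
#' @export
autoplot.edge_projection <- function(object, ...) {
  phy <- object$tree
  n_tip <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)
  ypos <- numeric(n_tip + phy$Nnode)
  ypos[seq_len(n_tip)] <- seq_len(n_tip)
  for (nd in internal_nodes_postorder(phy)) {
    kids <- phy$edge[phy$edge[, 1] == nd, 2]
    ypos[nd] <- mean(ypos[kids])
  }
  w <- object$weights$scaled_weight
  seg <- tibble::tibble(
    x = depth[phy$edge[, 1]], xend = depth[phy$edge[, 2]],
    y = ypos[phy$edge[, 2]], yend = ypos[phy$edge[, 2]],
    weight = w
  )
  seg_v <- tibble::tibble(
    x = depth[phy$edge[, 1]], xend = depth[phy$edge[, 1]],
    y = ypos[phy$edge[, 1]], yend = ypos[phy$edge[, 2]],
    weight = w
  )
  ggplot2::ggplot(dplyr::bind_rows(seg, seg_v),
                  ggplot2::aes(x = .data$x, xend = .data$xend,
                               y = .data$y, yend = .data$yend,
                               colour = .data$weight,
                               linewidth = abs(.data$weight))) +
    ggplot2::geom_segment() +
    ggplot2::scale_colour_gradient2(low = "darkgreen", high = "darkorange") +
    ggplot2::scale_linewidth(range = c(0.2, 1.6), guide = "none") +
    ggplot2::labs(x = "substitutions/site", y = NULL, colour = "loading") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

# Internal nodes ordered so every child node precedes its parent.
internal_nodes_postorder <- function(phy) {
  n_tip <- length(phy$tip.label)
  depth <- integer(n_tip + phy$Nnode)
  phy <- stats::reorder(phy, "cladewise")
  for (i in seq_len(nrow(phy$edge))) {
    depth[phy$edge[i, 2]] <- depth[phy$edge[i, 1]] + 1L
  }
  nodes <- n_tip + seq_len(phy$Nnode)
  nodes[order(depth[nodes], decreasing = TRUE)]
}
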