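#' Samples-by-edges signed mass matrix
#'
#' The edge PCA transform: entry (s, e) is the mass of sample s on the
#' distal side of edge e minus the mass on the proximal side (equal to
#' `2 * distal - 1` for unit-mass samples). Point masses sitting on an edge
#' itself count to the distal side.
#'
#' @param mass_maps a `mass_map` tibble (see
#'   [mass_map_from_placements()]).
#' @param tree the common placement tree.
#' @return numeric matrix, samples in rows, columns named by `edge_id`.
#' @export
edge_mass_matrix <- function(mass_maps, tree) {
  tree <- as_placement_tree(tree)
  et <- edge_table(tree)
  samples <- sort(unique(mass_maps$sample))
  out <- matrix(0, length(samples), nrow(et),
                dimnames = list(samples, as.character(et$edge_id)))
  for (s in samples) {
    m <- mass_maps[mass_maps$sample == s, ]
    edge_mass <- numeric(nrow(et))
    agg <- dplyr::summarise(dplyr::group_by(m, .data$edge_id),
                            mass = sum(.data$mass), .groups = "drop")
    edge_mass[match(agg$edge_id, et$edge_id)] <- agg$mass
    total <- sum(edge_mass)
    distal <- (subtree_sums(tree, edge_mass) + edge_mass) / total
    out[s, ] <- 2 * distal - 1
  }
  out
}

#' Edge principal components analysis
#'
#' Classical covariance PCA of the per-sample signed edge-mass vectors:
#' columns are centered (not scaled — the transform already puts all edges
#' on one scale in `[-1, 1]`), the covariance matrix is
#' eigendecomposed, and scores are the projections of the centered matrix
#' onto the eigenvectors. Signs follow the convention that each
#' component's largest-magnitude loading is positive. Zero-variance edges
#' are retained (they simply carry zero loadings).
#'
#' @param x samples-by-edges matrix from [edge_mass_matrix()].
#' @param n_components number of components to keep; truncated (with a
#'   warning) when it exceeds the matrix rank.
#' @return list of class `edge_pca`: `values` (variances per kept
#'   component), `vectors` (tibble: `edge_id`, `PC1`, ...), `scores`
#'   (tibble: `sample`, `PC1`, ...), `var_explained` (fractions of total
#'   variance), `total_variance`.
#' @export
edge_pca <- function(x, n_components = 2) {
  if (nrow(x) < 2) stop("need >= 2 samples", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  vals <- pc$sdev^2
  rank <- sum(vals > max(vals[1], 0) * 1e-12)
  if (n_components > rank) {
    warning("requested ", n_components, " components but rank is ", rank,
            "; truncating", call. = FALSE)
    n_components <- max(rank, 1L)
  }
  keep <- seq_len(n_components)
  rot <- pc$rotation[, keep, drop = FALSE]
  scores <- pc$x[, keep, drop = FALSE]
  for (k in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, k]))
    if (rot[i, k] < 0) {
      rot[, k] <- -rot[, k]
      scores[, k] <- -scores[, k]
    }
  }
  total_var <- sum(apply(x, 2, stats::var))
  structure(
    list(
      values = vals[keep],
      vectors = dplyr::bind_cols(
        tibble::tibble(edge_id = as.integer(colnames(x))),
        tibble::as_tibble(rot)
      ),
      scores = dplyr::bind_cols(
        tibble::tibble(sample = rownames(x)),
        tibble::as_tibble(scores)
      ),
      var_explained = vals[keep] / total_var,
      total_variance = total_var,
      all_values = vals
    ),
    class = "edge_pca"
  )
}

#' Project an edge PCA component onto the tree
#'
#' Attaches a component's per-edge loadings to the tree for drawing or
#' export: positive and negative loadings are the two "directions" of the
#' component on the tree, and magnitudes are reported both raw and scaled
#' to a maximum of 1.
#'
#' @param fit an [edge_pca()] result.
#' @param tree the placement tree the mass matrix was computed on.
#' @param component component number (default 1).
#' @return list of class `edge_projection`: `tree`, `weights` (tibble:
#'   `edge_id`, `weight`, `scaled_weight`, `sign`), `newick` (the tree with
#'   `{edge_id}` annotations; weights are joined by `edge_id`).
#' @export
project_component_on_tree <- function(fit, tree, component = 1) {
  tree <- as_placement_tree(tree)
  et <- edge_table(tree)
  col <- paste0("PC", component)
  if (!col %in% names(fit$vectors)) stop("component not present in fit", call. = FALSE)
  w <- fit$vectors[[col]][match(et$edge_id, fit$vectors$edge_id)]
  w[is.na(w)] <- 0
  mx <- max(abs(w))
  weights <- tibble::tibble(
    edge_id = et$edge_id,
    weight = w,
    scaled_weight = if (mx > 0) w / mx else w,
    sign = sign(w)
  )
  structure(
    list(tree = tree, weights = weights, newick = write_edge_newick(tree)),
    class = "edge_projection"
  )
}
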