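#' Normalise a phylogenetic tree for placement arithmetic
#'
#' All placement, mass and classification functions in this package index
#' edges by an integer `edge_id` running 0, 1, ... in preorder (cladewise)
#' traversal order. `as_placement_tree()` validates a tree and puts it into
#' that canonical edge order so that `edge_id` is simply the edge row minus
#' one.
#'
#' @param tree an [ape::phylo] object; must be rooted and carry branch
#'   lengths.
#' @return the same tree, reordered cladewise, with class
#'   `c("placement_tree", "phylo")`.
#' @export
as_placement_tree <- function(tree) {
  if (!inherits(tree, "phylo")) {
    stop("`tree` must be an ape 'phylo' object", call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("`tree` must have branch lengths", call. = FALSE)
  }
  if (!ape::is.rooted(tree)) {
    stop("`tree` must be rooted", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("`tree` has negative branch lengths", call. = FALSE)
  }
  env <- attr(tree, "pm_env")
  tree <- stats::reorder(tree, "cladewise")
  class(tree) <- unique(c("placement_tree", class(tree)))
  # shared-by-reference scratch space so repeated distance computations on
  # one tree reuse the edge table and traversal orders
  attr(tree, "pm_env") <- if (is.null(env)) new.env(parent = emptyenv()) else env
  tree
}

# Cached per-tree traversal context (edge table, postorder order, child
# subtree sums helper data). The cache lives in an environment attribute,
# so all copies of one placement tree share it.
tree_context <- function(tree) {
  env <- attr(tree, "pm_env")
  if (is.null(env)) {
    env <- new.env(parent = emptyenv())
  }
  if (is.null(env$ctx)) {
    et <- edge_table(tree)
    env$ctx <- list(
      edge_id = et$edge_id,
      parent = et$parent,
      child = et$child,
      length = et$length,
      postorder = postorder_edge_index(tree),
      n_node = max(et$child, et$parent)
    )
  }
  env$ctx
}

#' Edge table of a placement tree
#'
#' @param tree a tree accepted by [as_placement_tree()].
#' @return a tibble with one row per edge: `edge_id` (0-based, preorder),
#'   `parent` and `child` node numbers (ape convention), `length`,
#'   `is_terminal`, and `tip_label` (the tip name for terminal edges, `NA`
#'   otherwise).
#' @export
edge_table <- function(tree) {
  tree <- as_placement_tree(tree)
  n_tip <- length(tree$tip.label)
  child <- tree$edge[, 2]
  tibble::tibble(
    edge_id = seq_len(nrow(tree$edge)) - 1L,
    parent = tree$edge[, 1],
    child = child,
    length = tree$edge.length,
    is_terminal = child <= n_tip,
    tip_label = ifelse(child <= n_tip, tree$tip.label[pmin(child, n_tip)], NA_character_)
  )
}

# Edge indices (1-based rows of tree$edge) sorted so that every edge whose
# child is deeper comes first; processing in this order visits all of a
# node's descendant edges before the edge above it.
postorder_edge_index <- function(tree) {
  et <- edge_table(tree)
  depth <- integer(max(et$child, et$parent))
  root <- setdiff(et$parent, et$child)[1]
  depth[root] <- 0L
  # cladewise order guarantees a parent's edge precedes its children's edges
  for (i in seq_len(nrow(et))) {
    depth[et$child[i]] <- depth[et$parent[i]] + 1L
  }
  order(depth[et$child], decreasing = TRUE)
}

# For each edge (by edge_id + 1), the tip indices on its distal side.
tips_below_edges <- function(tree) {
  et <- edge_table(tree)
  n_tip <- length(tree$tip.label)
  below_node <- vector("list", max(et$child, et$parent))
  for (i in postorder_edge_index(tree)) {
    ch <- et$child[i]
    if (ch <= n_tip) below_node[[ch]] <- ch
  }
  for (i in postorder_edge_index(tree)) {
    ch <- et$child[i]
    pa <- et$parent[i]
    below_node[[pa]] <- c(below_node[[pa]], below_node[[ch]])
  }
  lapply(seq_len(nrow(et)), function(i) sort(below_node[[et$child[i]]]))
}

# Sum an arbitrary per-edge quantity over the subtree strictly below each
# edge's child node (excluding the edge itself). `edge_values` is indexed by
# edge_id + 1.
subtree_sums <- function(tree, edge_values) {
  et <- edge_table(tree)
  node_sum <- numeric(max(et$child, et$parent))
  for (i in postorder_edge_index(tree)) {
    node_sum[et$parent[i]] <- node_sum[et$parent[i]] +
      node_sum[et$child[i]] + edge_values[i]
  }
  node_sum[et$child]
}

# Serialise a placement tree as newick with "{edge_id}" annotations after
# each branch length (the jplace convention). `annot` maps edge_id to the
# integer printed in braces; defaults to the edge_id itself.
write_edge_newick <- function(tree, annot = NULL) {
  tree <- as_placement_tree(tree)
  et <- edge_table(tree)
  if (is.null(annot)) annot <- et$edge_id
  n_tip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(et)), et$parent)
  root <- setdiff(et$parent, et$child)[1]
  fmt_len <- function(x) format(x, digits = 10, scientific = FALSE, trim = TRUE)
  node_str <- function(node) {
    idx <- kids[[as.character(node)]]
    if (is.null(idx)) {
      return(tree$tip.label[node])
    }
    inner <- vapply(idx, function(i) {
      paste0(node_str(et$child[i]), ":", fmt_len(et$length[i]), "{", annot[i], "}")
    }, character(1))
    paste0("(", paste(inner, collapse = ","), ")")
  }
  paste0(node_str(root), ";")
}

# Parse a jplace-style newick string with {n} edge annotations. Returns a
# list with the tree (canonical placement order) and a tibble mapping the
# embedded edge numbers to this package's edge_ids.
read_edge_newick <- function(text) {
  if (!grepl("\\{\\d+\\}", text)) {
    stop("newick string carries no {n} edge annotations", call. = FALSE)
  }
  # move each {n} into the node label of the edge's child so ape can parse it
  tagged <- gsub("(:[0-9eE.+-]+)\\{(\\d+)\\}", "@@\\2\\1", text)
  tree <- ape::read.tree(text = tagged)
  if (is.null(tree)) stop("malformed newick string", call. = FALSE)
  n_tip <- length(tree$tip.label)
  labels <- character(n_tip + tree$Nnode)
  labels[seq_len(n_tip)] <- tree$tip.label
  if (!is.null(tree$node.label)) {
    labels[n_tip + seq_len(tree$Nnode)] <- tree$node.label
  }
  tag <- suppressWarnings(as.integer(sub(".*@@(\\d+)$", "\\1", labels)))
  has_tag <- grepl("@@\\d+$", labels)
  clean <- sub("@@\\d+$", "", labels)
  tree$tip.label <- clean[seq_len(n_tip)]
  if (!is.null(tree$node.label)) tree$node.label <- clean[n_tip + seq_len(tree$Nnode)]
  tree <- as_placement_tree(tree)
  et <- edge_table(tree)
  # node numbering is preserved by reorder(); map child node -> embedded tag
  edge_num <- tag[et$child]
  if (anyNA(edge_num[has_tag[et$child]])) {
    stop("could not recover edge numbers from newick annotations", call. = FALSE)
  }
  list(tree = tree, edge_map = tibble::tibble(edge_num = edge_num, edge_id = et$edge_id))
}

# Pairwise path distance between attachment points on a tree. `points` is a
# tibble with columns edge_id, distal_length (distance from the child node).
# Returns a dense symmetric matrix.
attachment_point_distances <- function(points, tree) {
  tree <- as_placement_tree(tree)
  et <- edge_table(tree)
  idx <- match(points$edge_id, et$edge_id)
  if (anyNA(idx)) stop("unknown edge_id in attachment points", call. = FALSE)
  len <- et$length[idx]
  d_child <- pmin(points$distal_length, len)
  d_parent <- len - d_child
  childs <- et$child[idx]
  parents <- et$parent[idx]
  nd <- ape::dist.nodes(tree)
  n <- nrow(points)
  via <- function(enda, endb, da, db) {
    outer(da, db, "+") + nd[enda, endb, drop = FALSE]
  }
  dmat <- pmin(
    via(childs, childs, d_child, d_child),
    via(childs, parents, d_child, d_parent),
    via(parents, childs, d_parent, d_child),
    via(parents, parents, d_parent, d_parent)
  )
  same_edge <- outer(idx, idx, "==")
  dmat[same_edge] <- abs(outer(d_child, d_child, "-"))[same_edge]
  diag(dmat) <- 0
  dmat
}
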