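#' Build per-sample mass maps from placements
#'
#' Each sample becomes a distribution of one unit of mass over the tree.
#' In `"spread"` mode every attachment deposits its posterior-weighted
#' share of the read's mass at its attachment point; in `"best"` mode each
#' read's full mass goes to its highest-posterior attachment. Coincident
#' points are aggregated; each sample's masses are normalised to total 1.
#'
#' @param placements attachment tibble (`sample`, `read_id`, `edge_id`,
#'   `distal_length`, `posterior`).
#' @param tree the placement tree.
#' @param mode `"spread"` (default) or `"best"`.
#' @return a mass-map tibble (`sample`, `edge_id`, `position`, `mass`)
#'   where `position` is measured from the proximal (rootward) end of the
#'   edge. Class `mass_map`.
#' @export
mass_map_from_placements <- function(placements, tree, mode = c("spread", "best")) {
  mode <- match.arg(mode)
  if (nrow(placements) == 0) stop("empty placement set", call. = FALSE)
  tree <- as_placement_tree(tree)
  et <- edge_table(tree)
  idx <- match(placements$edge_id, et$edge_id)
  if (anyNA(idx)) stop("placements reference edges absent from the tree", call. = FALSE)
  d <- placements
  if (mode == "best") {
    d <- dplyr::slice_max(dplyr::group_by(d, .data$sample, .data$read_id),
                          .data$posterior, n = 1, with_ties = FALSE)
    d <- dplyr::ungroup(d)
    d$posterior <- 1
  }
  len <- et$length[match(d$edge_id, et$edge_id)]
  d$position <- pmax(0, len - pmin(d$distal_length, len))
  d <- dplyr::summarise(
    dplyr::group_by(d, .data$sample, .data$edge_id, .data$position),
    mass = sum(.data$posterior), .groups = "drop"
  )
  d <- dplyr::group_by(d, .data$sample)
  d <- dplyr::mutate(d, mass = .data$mass / sum(.data$mass))
  d <- dplyr::ungroup(d)
  structure(dplyr::arrange(d, .data$sample, .data$edge_id, .data$position),
            class = c("mass_map", class(d)))
}

#' Kantorovich-Rubinstein (earth-mover) distance between two mass maps
#'
#' The KR distance between two unit-mass distributions on a tree, the
#' generalization of weighted UniFrac that admits mass on internal edges
#' and split (probabilistic) mass. Computed exactly as
#' `sum over edges of the integral of |F(y)| dy`, where `F(y)` is the net
#' signed mass of `p - q` in the subtree below point `y`; the integrand is
#' piecewise constant with breakpoints at the point masses, so a single
#' post-order traversal suffices.
#'
#' @param p,q mass-map tibbles for one sample each (columns `edge_id`,
#'   `position`, `mass`; a `sample` column is ignored but must be
#'   constant).
#' @param tree the common placement tree.
#' @return nonnegative distance (branch-length units).
#' @export
kr_distance <- function(p, q, tree) {
  tree <- as_placement_tree(tree)
  ctx <- tree_context(tree)
  one <- function(m) {
    if ("sample" %in% names(m) && length(unique(m$sample)) > 1) {
      stop("mass map contains more than one sample", call. = FALSE)
    }
    m
  }
  p <- one(p); q <- one(q)
  eidx <- match(c(p$edge_id, q$edge_id), ctx$edge_id)
  if (anyNA(eidx)) stop("mass map references edges absent from the tree", call. = FALSE)
  pos <- c(p$position, q$position)
  net <- c(p$mass, -q$mass)
  n_edge <- length(ctx$edge_id)

  # net mass per edge, then net mass strictly below each edge's child node
  edge_net <- numeric(n_edge)
  agg <- rowsum(net, eidx)
  edge_net[as.integer(rownames(agg))] <- agg[, 1]
  below <- numeric(ctx$n_node)
  for (i in ctx$postorder) {
    below[ctx$parent[i]] <- below[ctx$parent[i]] + below[ctx$child[i]] + edge_net[i]
  }
  base <- below[ctx$child]

  # edges without point masses contribute L * |base|
  has_pts <- unique(eidx)
  total <- sum(ctx$length[-has_pts] * abs(base[-has_pts]))
  if (length(has_pts) == 0) return(total + sum(ctx$length * abs(base)))

  # per-edge piecewise-constant integral, vectorised over all points:
  # F on (p_{k-1}, p_k) is base + suffix-sum of net at positions >= p_k
  L <- ctx$length[eidx]
  pos <- pmin(pmax(pos, 0), L)
  o <- order(eidx, pos)
  e <- eidx[o]; ps <- pos[o]; nt <- net[o]
  first <- !duplicated(e)
  last <- !duplicated(e, fromLast = TRUE)
  # suffix sums within each edge group
  grp_tot <- rowsum(nt, e)
  cum <- cumsum(nt)
  cum_before <- cum - nt # prefix sum excluding self
  grp_start_cum <- cum_before[first][match(e, e[first])]
  prefix_within <- cum_before - grp_start_cum
  suffix <- grp_tot[match(e, as.integer(rownames(grp_tot))), 1] - prefix_within
  width_low <- ps - ifelse(first, 0, c(0, ps[-length(ps)]))
  fval_low <- base[e] + suffix
  total <- total + sum(width_low * abs(fval_low))
  total + sum((ctx$length[e[last]] - ps[last]) * abs(base[e[last]]))
}

#' Weighted average of mass maps
#'
#' Pointwise weighted union of the input distributions ("squashing"),
#' renormalised to unit total mass.
#'
#' @param maps list of mass-map tibbles (single sample each).
#' @param weights positive weights, one per map (default equal).
#' @param sample_id sample id given to the averaged map.
#' @return a single-sample mass-map tibble.
#' @export
average_mass <- function(maps, weights = rep(1, length(maps)), sample_id = "average") {
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  w <- weights / sum(weights)
  pts <- dplyr::bind_rows(lapply(seq_along(maps), function(i) {
    m <- maps[[i]]
    tot <- sum(m$mass)
    tibble::tibble(edge_id = m$edge_id, position = m$position,
                   mass = w[i] * m$mass / tot)
  }))
  out <- dplyr::summarise(dplyr::group_by(pts, .data$edge_id, .data$position),
                          mass = sum(.data$mass), .groups = "drop")
  out$sample <- sample_id
  dplyr::arrange(out[, c("sample", "edge_id", "position", "mass")],
                 .data$edge_id, .data$position)
}

#' Squash clustering of samples by KR distance
#'
#' Agglomerative clustering in which the distance between two clusters is
#' the KR distance between the averages ("squashes") of their member mass
#' distributions. At each step the closest pair of clusters merges; the
#' merged average weights each child by its member count, and each child's
#' branch length is the KR distance between the child's average and the
#' merged average — so the result is generally not ultrametric. Merge ties
#' are broken by the smallest sorted pair of cluster ids.
#'
#' @param mass_maps a `mass_map` tibble covering >= 2 samples.
#' @param tree the common placement tree.
#' @return list of class `squash_tree`: `tree` (ape phylo over sample ids,
#'   internal nodes labeled `cl1`, `cl2`, ... in merge order), `merges`
#'   (tibble: `step`, `a`, `b`, `distance`).
#' @export
squash_cluster <- function(mass_maps, tree) {
  tree <- as_placement_tree(tree)
  samples <- sort(unique(mass_maps$sample))
  if (length(samples) < 2) stop("need at least 2 samples", call. = FALSE)
  maps <- lapply(samples, function(s) mass_maps[mass_maps$sample == s, ])
  names(maps) <- samples
  active <- stats::setNames(as.list(samples), samples) # id -> newick fragment
  sizes <- stats::setNames(rep(1, length(samples)), samples)
  nwk <- stats::setNames(samples, samples)

  dists <- list()
  dkey <- function(a, b) paste(sort(c(a, b)), collapse = "\r")
  for (i in seq_along(samples)) {
    for (j in seq_len(i - 1L)) {
      a <- samples[j]; b <- samples[i]
      dists[[dkey(a, b)]] <- kr_distance(maps[[a]], maps[[b]], tree)
    }
  }
  merges <- list()
  step <- 0L
  while (length(active) > 1L) {
    ids <- sort(names(active))
    best <- NULL
    for (i in seq_along(ids)) {
      for (j in seq_len(i - 1L)) {
        a <- ids[j]; b <- ids[i]
        d <- dists[[dkey(a, b)]]
        if (is.null(best) || d < best$d - 1e-15 ||
            (abs(d - best$d) <= 1e-15 &&
             paste(a, b) < paste(best$a, best$b))) {
          best <- list(a = a, b = b, d = d)
        }
      }
    }
    step <- step + 1L
    new_id <- sprintf("cl%d", step)
    wa <- sizes[[best$a]]; wb <- sizes[[best$b]]
    merged <- average_mass(list(maps[[best$a]], maps[[best$b]]),
                           weights = c(wa, wb), sample_id = new_id)
    la <- kr_distance(maps[[best$a]], merged, tree)
    lb <- kr_distance(maps[[best$b]], merged, tree)
    nwk[[new_id]] <- sprintf("(%s:%.10f,%s:%.10f)%s",
                             nwk[[best$a]], la, nwk[[best$b]], lb, new_id)
    maps[[new_id]] <- merged
    sizes[[new_id]] <- wa + wb
    active[[best$a]] <- NULL
    active[[best$b]] <- NULL
    active[[new_id]] <- new_id
    merges[[step]] <- tibble::tibble(step = step, a = best$a, b = best$b,
                                     distance = best$d)
    for (other in setdiff(names(active), new_id)) {
      dists[[dkey(other, new_id)]] <- kr_distance(maps[[other]], merged, tree)
    }
  }
  out_tree <- ape::read.tree(text = paste0(nwk[[names(active)]], ";"))
  structure(
    list(tree = out_tree, merges = dplyr::bind_rows(merges)),
    class = "squash_tree"
  )
}

#' Bootstrap support for a squash clustering
#'
#' Resamples each sample's placements (reads) with replacement, rebuilds
#' mass maps, re-clusters, and reports for each internal node of the
#' reference clustering the fraction of replicates containing the same
#' leaf bipartition.
#'
#' @param placements attachment tibble (`sample`, `read_id`, ...).
#' @param tree the placement tree.
#' @param n_boot number of bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @param mode mass deposition mode, see [mass_map_from_placements()].
#' @return the `squash_tree` of the full data with an added `support`
#'   tibble (`node_label`, `members`, `support`), and supports in the ape
#'   tree's `node.label`.
#' @export
squash_bootstrap <- function(placements, tree, n_boot = 100, seed = 1,
                             mode = "spread") {
  if (n_boot < 1) stop("`n_boot` must be >= 1", call. = FALSE)
  local_rng(seed)
  tree <- as_placement_tree(tree)
  base <- squash_cluster(mass_map_from_placements(placements, tree, mode), tree)

  clade_keys <- function(sq) {
    phy <- sq$tree
    n_tip <- length(phy$tip.label)
    keys <- character(phy$Nnode)
    for (k in seq_len(phy$Nnode)) {
      tips <- ape::extract.clade(phy, n_tip + k)$tip.label
      keys[k] <- paste(sort(tips), collapse = "|")
    }
    keys
  }
  base_keys <- clade_keys(base)
  hits <- stats::setNames(numeric(length(base_keys)), base_keys)
  by_read <- split(seq_len(nrow(placements)),
                   paste(placements$sample, placements$read_id, sep = "\r"))
  read_sample <- vapply(strsplit(names(by_read), "\r"), `[[`, character(1), 1)
  reads_of <- split(seq_along(by_read), read_sample)
  for (b in seq_len(n_boot)) {
    take <- unlist(lapply(reads_of, function(ix) {
      ix[sample.int(length(ix), length(ix), replace = TRUE)]
    }), use.names = FALSE)
    rows <- placements[unlist(by_read[take], use.names = FALSE), ]
    # resampled copies of one read must stay distinct
    rep_id <- rep(seq_along(take), lengths(by_read)[take])
    rows$read_id <- paste0(rows$read_id, "_b", rep_id)
    mm <- mass_map_from_placements(rows, tree, mode)
    keys <- clade_keys(squash_cluster(mm, tree))
    hits[base_keys %in% keys] <- hits[base_keys %in% keys] + 1
  }
  support <- tibble::tibble(
    node_label = if (!is.null(base$tree$node.label)) base$tree$node.label else
      sprintf("node%d", seq_along(base_keys)),
    members = base_keys,
    support = unname(hits) / n_boot
  )
  base$tree$node.label <- sprintf("%.3f", support$support)
  base$support <- support
  base
}

#' Cluster reads into phylogenetic islands
#'
#' Single-linkage clustering of best attachment points under tree path
#' distance with a distance threshold. Islands whose reads originate from
#' fewer than `min_subjects` distinct subjects are dropped. Each retained
#' island is labeled by the majority classification of its members and
#' represented by the read closest to the island's attachment-point medoid.
#'
#' @param placements attachment tibble (`read_id`, `subject`, `edge_id`,
#'   `distal_length`, `posterior`).
#' @param tree the placement tree.
#' @param cutoff single-linkage distance threshold (default 0.02
#'   substitutions/site).
#' @param min_subjects minimum distinct subjects per retained island
#'   (default 2).
#' @param classifications optional tibble (`read_id`, `name` or `taxid`)
#'   used for the majority label.
#' @param mode `"best"` (default) clusters each read's top attachment;
#'   `"spread"` clusters every attachment point, with reads assigned to the
#'   island of their top attachment.
#' @return tibble of class `island_table`: `island`, `read_id`, `subject`,
#'   `label`, `representative` (logical).
#' @export
island_cluster <- function(placements, tree, cutoff = 0.02, min_subjects = 2,
                           classifications = NULL, mode = c("best", "spread")) {
  mode <- match.arg(mode)
  tree <- as_placement_tree(tree)
  best <- dplyr::slice_max(dplyr::group_by(placements, .data$read_id),
                           .data$posterior, n = 1, with_ties = FALSE)
  best <- dplyr::ungroup(best)
  pts <- if (mode == "best") best else placements
  dmat <- attachment_point_distances(
    pts[, c("edge_id", "distal_length")], tree
  )
  if (nrow(pts) == 1) {
    groups <- 1L
  } else {
    hc <- stats::hclust(stats::as.dist(dmat), method = "single")
    groups <- stats::cutree(hc, h = cutoff)
  }
  if (mode == "spread") {
    # island of a read = island of its best attachment
    key <- paste(pts$read_id, pts$edge_id, pts$distal_length)
    bkey <- paste(best$read_id, best$edge_id, best$distal_length)
    groups <- groups[match(bkey, key)]
    pts <- best
    dmat <- dmat[match(bkey, key), match(bkey, key), drop = FALSE]
  }
  out <- tibble::tibble(
    read_id = pts$read_id,
    subject = pts$subject,
    group = groups
  )
  keep <- dplyr::summarise(dplyr::group_by(out, .data$group),
                           n_subjects = dplyr::n_distinct(.data$subject),
                           .groups = "drop")
  keep <- keep$group[keep$n_subjects >= min_subjects]
  out <- out[out$group %in% keep, ]
  if (nrow(out) == 0) {
    return(structure(tibble::tibble(island = character(0), read_id = character(0),
                                    subject = character(0), label = character(0),
                                    representative = logical(0)),
                     class = c("island_table", "tbl_df", "tbl", "data.frame")))
  }
  # stable island ids by size then smallest read id
  ord <- dplyr::arrange(
    dplyr::summarise(dplyr::group_by(out, .data$group),
                     n = dplyr::n(), first_read = min(.data$read_id),
                     .groups = "drop"),
    dplyr::desc(.data$n), .data$first_read
  )
  island_id <- stats::setNames(sprintf("island%02d", seq_len(nrow(ord))), ord$group)
  out$island <- island_id[as.character(out$group)]

  label_of <- function(ids) {
    if (is.null(classifications)) return(NA_character_)
    col <- if ("name" %in% names(classifications)) "name" else "taxid"
    v <- classifications[[col]][match(ids, classifications$read_id)]
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_character_)
    tab <- sort(table(v), decreasing = TRUE)
    names(tab)[1]
  }
  res <- list()
  for (isl in unique(out$island)) {
    members <- out[out$island == isl, ]
    ridx <- match(members$read_id, pts$read_id)
    sub <- dmat[ridx, ridx, drop = FALSE]
    medoid <- which.min(rowSums(sub))
    res[[isl]] <- tibble::tibble(
      island = isl,
      read_id = members$read_id,
      subject = members$subject,
      label = label_of(members$read_id),
      representative = seq_len(nrow(members)) == medoid
    )
  }
  structure(dplyr::bind_rows(res),
            class = c("island_table", "tbl_df", "tbl", "data.frame"))
}
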