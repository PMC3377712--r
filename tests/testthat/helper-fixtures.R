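# Small fixtures shared across test files. Everything is built in code at
# test time; seeds are fixed so expectations are stable.

# A tiny hand-built two-leaf tree with branch lengths 0.3 and 0.2.
two_leaf_tree <- function() {
  as_placement_tree(ape::read.tree(text = "(A:0.3,B:0.2);"))
}

# The worked three-leaf example: A and B are species X1, X2 of genus G;
# C is species Y of genus H.
three_leaf_tree <- function() {
  as_placement_tree(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
}

three_leaf_taxonomy <- function() {
  tibble::tribble(
    ~taxid, ~name, ~rank, ~parent, ~provisional,
    "root", "root", "root", NA_character_, FALSE,
    "F", "F", "family", "root", FALSE,
    "G", "G", "genus", "F", FALSE,
    "H", "H", "genus", "F", FALSE,
    "X1", "X1", "species", "G", FALSE,
    "X2", "X2", "species", "G", FALSE,
    "Y", "Y", "species", "H", FALSE
  )
}

# Cached small reference world (building one takes a moment).
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_reference_world(n_taxa = 5, seqs_per_taxon = 5,
                                         seq_length = 300, seed = 11)
    }
    cache
  }
})

# A single-sample mass map tibble.
mass_map <- function(edge_id, position, mass, sample = "s1") {
  tibble::tibble(sample = sample, edge_id = as.integer(edge_id),
                 position = position, mass = mass)
}

# Random rooted tree with unit-scale branch lengths.
random_tree <- function(n_tips, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n_tips)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.5)
    as_placement_tree(tr)
  })
}

# Random mass map on a tree: k point masses at random positions.
random_mass_map <- function(tree, k, sample = "s1", seed = 1) {
  withr::with_seed(seed, {
    et <- edge_table(tree)
    idx <- sample.int(nrow(et), k, replace = TRUE)
    m <- stats::runif(k)
    mass_map(
      edge_id = et$edge_id[idx],
      position = stats::runif(k) * et$length[idx],
      mass = m / sum(m),
      sample = sample
    )
  })
}

# Discretised-integral KR oracle: numerically integrates |F(y)| with
# `points_per_edge` midpoint samples per edge. Independent of the exact
# breakpoint traversal in kr_distance().
kr_oracle <- function(p, q, tree, points_per_edge = 1e4) {
  et <- edge_table(tree)
  pts <- rbind(
    data.frame(edge_id = p$edge_id, position = p$position, net = p$mass),
    data.frame(edge_id = q$edge_id, position = q$position, net = -q$mass)
  )
  total <- 0
  for (i in seq_len(nrow(et))) {
    L <- et$length[i]
    sub <- subtree_edge_ids(tree, i)
    base <- sum(pts$net[pts$edge_id %in% sub])
    on_edge <- pts[pts$edge_id == et$edge_id[i], ]
    # refine the uniform grid with the mass positions so the step-function
    # integrand is integrated without discretisation bias
    nodes <- sort(unique(c(seq(0, L, length.out = points_per_edge + 1),
                           pmin(pmax(on_edge$position, 0), L))))
    mids <- (nodes[-1] + nodes[-length(nodes)]) / 2
    fv <- rep(base, length(mids))
    for (k in seq_len(nrow(on_edge))) {
      fv <- fv + on_edge$net[k] * (on_edge$position[k] > mids)
    }
    total <- total + sum(abs(fv) * diff(nodes))
  }
  total
}

# Edge ids strictly below edge `row`'s child node (by parent-chasing).
subtree_edge_ids <- function(tree, row) {
  et <- edge_table(tree)
  kids <- et$child[row]
  out <- integer(0)
  repeat {
    nxt <- which(et$parent %in% kids)
    if (!length(nxt)) break
    out <- c(out, et$edge_id[nxt])
    kids <- et$child[nxt]
  }
  out
}

# Leaf-only weighted-UniFrac-style tally: sum over edges of
# length * |A_e - B_e| where A_e, B_e are the leaf-mass fractions of each
# sample below the edge. Valid when all mass sits on terminal edges at the
# leaf ends.
unifrac_tally <- function(p, q, tree) {
  et <- edge_table(tree)
  below <- tips_below_edges(tree)
  tipmass <- function(d) {
    tm <- numeric(length(tree$tip.label))
    for (i in seq_len(nrow(d))) {
      tip <- et$child[match(d$edge_id[i], et$edge_id)]
      tm[tip] <- tm[tip] + d$mass[i]
    }
    tm / sum(tm)
  }
  a <- tipmass(p)
  b <- tipmass(q)
  sum(vapply(seq_len(nrow(et)), function(i) {
    et$length[i] * abs(sum(a[below[[i]]]) - sum(b[below[[i]]]))
  }, numeric(1)))
}
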