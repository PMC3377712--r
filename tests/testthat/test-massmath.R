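test_that("mass maps deposit and normalise read mass", {
  tree <- three_leaf_tree()
  et <- edge_table(tree)
  eid <- function(tip) et$edge_id[match(tip, et$tip_label)]
  one <- tibble::tibble(sample = "s1", read_id = "r1", edge_id = eid("A"),
                        distal_length = 0.5, posterior = 1)
  mm <- mass_map_from_placements(one, tree)
  expect_equal(nrow(mm), 1)
  expect_equal(mm$mass, 1.0)

  two <- tibble::tibble(sample = "s1", read_id = c("r1", "r2"),
                        edge_id = c(eid("A"), eid("C")),
                        distal_length = 0, posterior = 1)
  mm2 <- mass_map_from_placements(two, tree)
  expect_equal(sort(mm2$mass), c(0.5, 0.5))

  # spread and best agree when every read has one attachment
  mm_best <- mass_map_from_placements(two, tree, mode = "best")
  expect_equal(mm2, mm_best)
  expect_error(mass_map_from_placements(two[0, ], tree), "empty")
})

test_that("KR distance is exact on the two-leaf tree and zero on identity", {
  tree <- two_leaf_tree() # branch lengths 0.3 and 0.2
  et <- edge_table(tree)
  p <- mass_map(et$edge_id[et$tip_label == "A"], position = 0.3, mass = 1)
  q <- mass_map(et$edge_id[et$tip_label == "B"], position = 0.2, mass = 1,
                sample = "s2")
  # all mass must cross both edges: 0.3 + 0.2
  expect_equal(kr_distance(p, q, tree), 0.5)
  expect_equal(kr_distance(p, p, tree), 0)
})

test_that("KR distance matches the discretised-integral oracle", {
  for (seed in 1:5) {
    tree <- random_tree(6, seed)
    p <- random_mass_map(tree, 5, sample = "p", seed = seed * 100 + 1)
    q <- random_mass_map(tree, 4, sample = "q", seed = seed * 100 + 2)
    expect_equal(kr_distance(p, q, tree), kr_oracle(p, q, tree),
                 tolerance = 1e-6)
  }
})

test_that("KR distance satisfies the metric axioms on random triples", {
  withr::with_seed(99, seeds <- sample.int(1e6, 20))
  for (k in seq_along(seeds)) {
    tree <- random_tree(5, seeds[k])
    a <- random_mass_map(tree, 3, "a", seeds[k] + 1)
    b <- random_mass_map(tree, 3, "b", seeds[k] + 2)
    c <- random_mass_map(tree, 3, "c", seeds[k] + 3)
    dab <- kr_distance(a, b, tree)
    dba <- kr_distance(b, a, tree)
    dac <- kr_distance(a, c, tree)
    dbc <- kr_distance(b, c, tree)
    expect_equal(dab, dba, tolerance = 1e-12)
    expect_gte(dab, 0)
    expect_lte(dac, dab + dbc + 1e-12)
    expect_equal(kr_distance(a, a, tree), 0)
  }
})

test_that("leaf-only KR equals the weighted-UniFrac subtree tally", {
  for (seed in 6:10) {
    tree <- random_tree(7, seed)
    et <- edge_table(tree)
    term <- et[et$is_terminal, ]
    mk <- function(s, sd) {
      withr::with_seed(sd, {
        idx <- sample.int(nrow(term), 4, replace = TRUE)
        m <- stats::runif(4)
        mass_map(term$edge_id[idx], position = term$length[idx],
                 mass = m / sum(m), sample = s)
      })
    }
    p <- mk("p", seed * 7 + 1)
    q <- mk("q", seed * 7 + 2)
    # aggregate duplicate points the way mass maps do
    agg <- function(d) dplyr::summarise(
      dplyr::group_by(d, .data$sample, .data$edge_id, .data$position),
      mass = sum(.data$mass), .groups = "drop"
    )
    expect_equal(kr_distance(agg(p), agg(q), tree),
                 unifrac_tally(agg(p), agg(q), tree), tolerance = 1e-9)
  }
})

test_that("averaging mass maps weights and renormalises", {
  tree <- two_leaf_tree()
  et <- edge_table(tree)
  a <- mass_map(et$edge_id[1], 0.1, 1, "a")
  b <- mass_map(et$edge_id[2], 0.1, 1, "b")
  self <- average_mass(list(a, a))
  expect_equal(self$edge_id, a$edge_id)
  expect_equal(self$mass, 1)
  even <- average_mass(list(a, b))
  expect_equal(sort(even$mass), c(0.5, 0.5))
  weighted <- average_mass(list(a, b), weights = c(2, 1))
  expect_equal(weighted$mass[weighted$edge_id == a$edge_id], 2 / 3)
  expect_equal(weighted$mass[weighted$edge_id == b$edge_id], 1 / 3)
  expect_error(average_mass(list(a, b), weights = c(1, 0)), "positive")
})

test_that("squash clustering merges duplicates first at zero length", {
  tree <- three_leaf_tree()
  et <- edge_table(tree)
  eid <- function(tip) et$edge_id[match(tip, et$tip_label)]
  mk <- function(s, tip) mass_map(eid(tip), 0.5, 1, s)
  mm <- dplyr::bind_rows(mk("s1", "A"), mk("s2", "A"), mk("s3", "C"))
  sq <- squash_cluster(mm, tree)
  expect_equal(sq$tree$Nnode, 2) # n - 1 internal nodes
  expect_identical(sort(c(sq$merges$a[1], sq$merges$b[1])), c("s1", "s2"))
  expect_equal(sq$merges$distance[1], 0)
  # zero-length cherry for the duplicated samples
  cherry <- ape::extract.clade(sq$tree, ape::getMRCA(sq$tree, c("s1", "s2")))
  expect_equal(sum(cherry$edge.length), 0)
})

test_that("squash clustering separates two distant clades last", {
  w <- small_world()
  taxa <- unique(w$sequences$taxid)
  et <- edge_table(w$tree)
  leaf_edge <- function(t) {
    tips <- w$sequences$seq_id[w$sequences$taxid == t]
    et$edge_id[match(tips[1], et$tip_label)]
  }
  mk <- function(s, t) mass_map(leaf_edge(t), 0, 1, s)
  # two samples on taxon 1's clade, two on taxon 3's clade
  mm <- dplyr::bind_rows(mk("a1", taxa[1]), mk("a2", taxa[1]),
                         mk("b1", taxa[3]), mk("b2", taxa[3]))
  # pull the duplicates slightly apart so distances are not all zero
  mm$mass <- 1
  sq <- squash_cluster(mm, w$tree)
  last <- sq$merges[nrow(sq$merges), ]
  # the final merge joins the a-group with the b-group
  groups <- list(c("a1", "a2"), c("b1", "b2"))
  tips_last <- lapply(c(last$a, last$b), function(id) {
    if (id %in% sq$tree$tip.label) return(id)
    k <- match(id, sq$tree$node.label)
    ape::extract.clade(sq$tree, length(sq$tree$tip.label) + k)$tip.label
  })
  expect_setequal(sort(unlist(tips_last)), c("a1", "a2", "b1", "b2"))
  expect_true(setequal(tips_last[[1]], groups[[1]]) ||
                setequal(tips_last[[1]], groups[[2]]))
})

test_that("sample order does not change the squash tree", {
  tree <- random_tree(6, 123)
  mm <- dplyr::bind_rows(lapply(1:5, function(i) {
    random_mass_map(tree, 3, sample = sprintf("s%d", i), seed = 300 + i)
  }))
  sq1 <- squash_cluster(mm, tree)
  withr::with_seed(1, mm2 <- mm[sample.int(nrow(mm)), ])
  sq2 <- squash_cluster(mm2, tree)
  expect_identical(ape::write.tree(sq1$tree), ape::write.tree(sq2$tree))
})

test_that("bootstrap supports are certain for single-read samples", {
  tree <- three_leaf_tree()
  et <- edge_table(tree)
  pl <- tibble::tibble(
    sample = c("s1", "s2", "s3"),
    read_id = "r1",
    edge_id = et$edge_id[match(c("A", "B", "C"), et$tip_label)],
    distal_length = 0,
    pendant_length = 0,
    posterior = 1
  )
  sq <- squash_bootstrap(pl, tree, n_boot = 5, seed = 1)
  expect_true(all(sq$support$support == 1))
  expect_true(all(sq$support$support >= 0 & sq$support$support <= 1))
})

test_that("islands split by path distance and apply the subject rule", {
  tree <- three_leaf_tree() # A-B path = 2, to C = 4-ish
  et <- edge_table(tree)
  eid <- function(tip) et$edge_id[match(tip, et$tip_label)]
  pl <- tibble::tibble(
    read_id = sprintf("r%d", 1:6),
    subject = c("u1", "u2", "u1", "u2", "u3", "u3"),
    edge_id = c(eid("A"), eid("A"), eid("A"), eid("C"), eid("C"), eid("C")),
    distal_length = c(0, 0.005, 0.01, 0, 0.004, 0.008),
    posterior = 1
  )
  isl <- island_cluster(pl, tree, cutoff = 0.02)
  expect_equal(dplyr::n_distinct(isl$island), 2)
  # reads on the same edge cluster together; the two groups never mix
  grp <- split(isl$read_id, isl$island)
  expect_true(setequal(grp[[1]], c("r1", "r2", "r3")) ||
                setequal(grp[[1]], c("r4", "r5", "r6")))
  expect_equal(sum(isl$representative), 2)

  # an island carried by one subject only is dropped
  pl_single <- pl
  pl_single$subject <- c("u1", "u1", "u1", "u2", "u3", "u2")
  isl2 <- island_cluster(pl_single, tree, cutoff = 0.02)
  expect_equal(dplyr::n_distinct(isl2$island), 1)
  expect_false(any(c("r1", "r2", "r3") %in% isl2$read_id))

  # all reads at one point form one island
  pl_one <- pl
  pl_one$edge_id <- eid("A")
  pl_one$distal_length <- 0.5
  expect_equal(dplyr::n_distinct(island_cluster(pl_one, tree)$island), 1)

  # majority labels flow through from classifications
  cls <- tibble::tibble(read_id = sprintf("r%d", 1:6),
                        name = c("X1", "X1", "X2", "Y", "Y", "Y"))
  isl3 <- island_cluster(pl, tree, classifications = cls)
  labs <- unique(isl3[, c("island", "label")])
  expect_setequal(labs$label, c("X1", "Y"))
})

test_that("attachment point distances include partial edge segments", {
  tree <- three_leaf_tree()
  et <- edge_table(tree)
  eid <- function(tip) et$edge_id[match(tip, et$tip_label)]
  pts <- tibble::tibble(
    edge_id = c(eid("A"), eid("B"), eid("C"), eid("A")),
    distal_length = c(0.25, 0.5, 1.0, 0.75)
  )
  d <- placemass:::attachment_point_distances(pts, tree)
  # distal_length is measured from the child node, so the climb to the
  # shared internal node is (edge length - distal_length)
  expect_equal(d[1, 2], (1 - 0.25) + (1 - 0.5))
  expect_equal(d[1, 4], 0.5)                    # same edge
  expect_equal(d[1, 3], (1 - 0.25) + 1 + (2 - 1)) # via the root into C's edge
  expect_true(isSymmetric(d))
})

test_that("island membership under posterior-spread mode stays per read", {
  tree <- three_leaf_tree()
  et <- edge_table(tree)
  eid <- function(tip) et$edge_id[match(tip, et$tip_label)]
  pl <- tibble::tibble(
    read_id = rep(c("r1", "r2", "r3"), each = 2),
    subject = rep(c("u1", "u2", "u3"), each = 2),
    edge_id = c(eid("A"), eid("C"), eid("A"), eid("C"), eid("C"), eid("A")),
    distal_length = 0.1,
    posterior = rep(c(0.9, 0.1), 3)
  )
  isl <- island_cluster(pl, tree, cutoff = 0.02, mode = "spread")
  # r1 and r2 share a best-attachment edge; r3's best sits alone on the
  # distant edge, so its single-subject island is dropped
  expect_equal(anyDuplicated(isl$read_id), 0)
  expect_setequal(isl$read_id, c("r1", "r2"))
  expect_equal(dplyr::n_distinct(isl$island), 1)
})
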