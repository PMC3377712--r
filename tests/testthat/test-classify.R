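three_leaf_seq_taxids <- c(A = "X1", B = "X2", C = "Y")

test_that("edge labels follow the one-side purity rule on the worked tree", {
  tree <- three_leaf_tree()
  labels <- label_edges(tree, three_leaf_taxonomy(), three_leaf_seq_taxids)
  et <- edge_table(tree)
  lab_of <- function(tip) labels$taxid[labels$edge_id ==
                                         et$edge_id[match(tip, et$tip_label)]]
  expect_identical(lab_of("A"), "X1")
  expect_identical(lab_of("B"), "X2")
  expect_identical(lab_of("C"), "Y")
  # internal edge above (A,B): distal side {X1, X2} is pure at genus G
  internal <- labels$taxid[labels$edge_id %in% et$edge_id[!et$is_terminal]]
  expect_identical(internal, "G")
  expect_true(all(labels$edge_id == et$edge_id))
})

test_that("single-species trees label every edge with that species", {
  tree <- as_placement_tree(ape::read.tree(text = "((A:1,B:1):1,C:1);"))
  tax <- three_leaf_taxonomy()
  labels <- label_edges(tree, tax, c(A = "X1", B = "X1", C = "X1"))
  expect_true(all(labels$taxid == "X1"))
  expect_true(all(labels$rank == "species"))
})

test_that("one-side and both-sides label readings agree on pure clades", {
  w <- small_world()
  seq_taxids <- stats::setNames(w$sequences$taxid, w$sequences$seq_id)
  one <- label_edges(w$tree, w$taxonomy, seq_taxids, strategy = "one_side")
  # within-clade edges are labeled with their clade's species
  et <- edge_table(w$tree)
  term <- et[et$is_terminal, ]
  expect_identical(
    one$taxid[match(term$edge_id, one$edge_id)],
    unname(seq_taxids[term$tip_label])
  )
  both <- label_edges(w$tree, w$taxonomy, seq_taxids, strategy = "both_sides")
  # the one-side labels refine the both-sides labels along each lineage
  lin <- placemass:::lineage_table(w$taxonomy)
  agree <- vapply(seq_len(nrow(one)), function(i) {
    a <- one$taxid[i]; b <- both$taxid[i]
    if (b == "root") return(TRUE)
    b %in% unlist(lin[match(a, lin$taxid), ]) || a == b
  }, logical(1))
  expect_true(all(agree))
})

test_that("posterior-sum classification applies the 0.9 cutoff by rank", {
  tree <- three_leaf_tree()
  tax <- three_leaf_taxonomy()
  labels <- label_edges(tree, tax, three_leaf_seq_taxids)
  et <- edge_table(tree)
  eid <- function(tip) et$edge_id[match(tip, et$tip_label)]

  # all mass on X1's edge -> species X1 with posterior 1
  p1 <- tibble::tibble(read_id = "r1", edge_id = eid("A"), posterior = 1)
  c1 <- classify_reads(p1, labels, tax)
  expect_identical(c1$taxid, "X1")
  expect_equal(c1$posterior, 1.0)

  # worked example: 0.6 on X1, 0.35 on X2, 0.05 on Y -> genus G with 0.95
  p2 <- tibble::tibble(
    read_id = "r2",
    edge_id = c(eid("A"), eid("B"), eid("C")),
    posterior = c(0.6, 0.35, 0.05)
  )
  c2 <- classify_reads(p2, labels, tax)
  expect_identical(c2$taxid, "G")
  expect_identical(c2$rank, "genus")
  expect_equal(c2$posterior, 0.95)
  # compound name: X1 and X2 exceed 0.05 individually
  expect_identical(c2$name, "G X1/X2")

  # cumulative posterior is monotone in rank specificity
  sums <- list(
    species = max(0.6, 0.35, 0.05),
    genus = 0.95,
    family = 1.0
  )
  expect_true(sums$species <= sums$genus && sums$genus <= sums$family)
})

test_that("compound names respect threshold and the three-name cap", {
  tax <- dplyr::bind_rows(
    three_leaf_taxonomy(),
    tibble::tibble(taxid = c("X3", "X4"), name = c("X3", "X4"),
                   rank = "species", parent = "G", provisional = FALSE)
  )
  cls <- tibble::tibble(read_id = "r", taxid = "G", rank = "genus", name = "G")
  sp <- tibble::tibble(
    read_id = "r",
    taxid = c("X1", "X2", "X3", "X4"),
    posterior = c(0.40, 0.30, 0.20, 0.08)
  )
  # four species above 0.05: only the top three are named
  expect_identical(compound_name(cls, sp, tax), "G X1/X2/X3")
  # raise the threshold: only X1, X2 qualify
  expect_identical(compound_name(cls, sp, tax, threshold = 0.25), "G X1/X2")
  # species-level classification is never renamed
  cls_sp <- tibble::tibble(read_id = "r", taxid = "X1", rank = "species", name = "X1")
  expect_identical(compound_name(cls_sp, sp, tax), "X1")
})

test_that("naive placement concentrates mass correctly", {
  w <- small_world()
  rp <- build_reference_package(w$sequences, w$taxonomy)
  et <- edge_table(rp$tree)

  # a read equal to a reference places all mass on that leaf's edge
  ref1 <- rp$sequences[1, ]
  pl <- naive_place(ref1$sequence, rp)
  expect_equal(nrow(pl), 1)
  expect_identical(et$tip_label[match(pl$edge_id, et$edge_id)], ref1$seq_id)
  expect_equal(pl$posterior, 1.0)

  # a read equidistant from two references splits mass evenly
  tiny <- tibble::tibble(
    seq_id = c("L1", "L2", "M1"),
    taxid = c("t1", "t1", "t2"),
    sequence = c(
      paste0(strrep("A", 99), "C"),
      paste0(strrep("A", 99), "G"),
      paste0(strrep("T", 50), strrep("A", 49), "C")
    )
  )
  tiny_tax <- dplyr::bind_rows(
    tibble::tibble(taxid = "root", name = "root", rank = "root",
                   parent = NA_character_, provisional = FALSE),
    tibble::tibble(taxid = "f", name = "f", rank = "family", parent = "root",
                   provisional = FALSE),
    tibble::tibble(taxid = "g", name = "g", rank = "genus", parent = "f",
                   provisional = FALSE),
    tibble::tibble(taxid = c("t1", "t2"), name = c("t1", "t2"),
                   rank = "species", parent = "g", provisional = FALSE)
  )
  rp2 <- build_reference_package(tiny, tiny_tax)
  mid <- paste0(strrep("A", 99), "T") # equidistant from L1 and L2
  pl2 <- naive_place(mid, rp2)
  et2 <- edge_table(rp2$tree)
  hit <- et2$tip_label[match(pl2$edge_id, et2$edge_id)]
  expect_setequal(hit, c("L1", "L2"))
  expect_equal(pl2$posterior, c(0.5, 0.5), tolerance = 1e-12)

  # junk with no similarity to any reference goes unplaced
  expect_equal(nrow(naive_place(strrep("T", 100), rp2, score_floor = 0.9)), 0)
})

test_that("simulated reads round-trip to their source species", {
  w <- small_world()
  co <- simulate_cohort(n_samples = 8, frac_bv = 0.5,
                        taxa = unique(w$sequences$taxid),
                        config = effect_config(depth_mean = 120), seed = 31)
  pl <- simulate_placements(co$counts, w, placement_spread = 0.05, seed = 32)
  seq_taxids <- stats::setNames(w$sequences$taxid, w$sequences$seq_id)
  labels <- label_edges(w$tree, w$taxonomy, seq_taxids)
  cls <- classify_reads(pl, labels, w$taxonomy)
  hits <- cls$taxid == cls$true_taxid & cls$rank == "species"
  expect_gte(mean(hits), 0.95)
})

test_that("jplace files round-trip and tolerate permuted field order", {
  w <- small_world()
  co <- simulate_cohort(n_samples = 2, frac_bv = 0.5,
                        taxa = unique(w$sequences$taxid),
                        config = effect_config(depth_mean = 30), seed = 41)
  pl <- simulate_placements(co$counts, w, placement_spread = 0.1, seed = 42)
  one <- pl[pl$sample == pl$sample[1], ]
  path <- withr::local_tempfile(fileext = ".jplace")
  write_jplace(one, w$tree, path)
  back <- read_jplace(path)
  expect_setequal(back$placements$read_id, one$read_id)
  merged <- dplyr::inner_join(
    back$placements, one,
    by = c("read_id", "edge_id"), suffix = c("_rt", "_orig")
  )
  expect_equal(nrow(merged), nrow(one))
  expect_equal(merged$posterior_rt, merged$posterior_orig, tolerance = 1e-9)
  expect_equal(merged$distal_length_rt, merged$distal_length_orig,
               tolerance = 1e-9)
  expect_identical(sort(back$tree$tip.label), sort(w$tree$tip.label))

  # permuted fields order is parsed by name
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  obj$fields <- list("pendant_length", "edge_num", "like_weight_ratio",
                     "distal_length")
  obj$placements <- lapply(obj$placements, function(rec) {
    rec$p <- lapply(rec$p, function(x) x[c(4, 1, 2, 3)])
    rec
  })
  path2 <- withr::local_tempfile(fileext = ".jplace")
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path2)
  back2 <- read_jplace(path2)
  expect_equal(
    dplyr::arrange(back2$placements, read_id, edge_id),
    dplyr::arrange(back$placements, read_id, edge_id),
    tolerance = 1e-9
  )

  # malformed input: no tree
  obj$tree <- NULL
  path3 <- withr::local_tempfile(fileext = ".jplace")
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path3)
  expect_error(read_jplace(path3), "tree")
})
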