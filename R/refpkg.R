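#' Pairwise distance between aligned sequences
#'
#' The fraction of non-identical nucleotides over comparable alignment
#' columns. Columns where either sequence carries a gap (`-` or `.`) or an
#' ambiguity code (anything outside `A`, `C`, `G`, `T`) are excluded from
#' both numerator and denominator.
#'
#' @param seq_a,seq_b aligned sequences of equal length (character
#'   scalars).
#' @return distance in `[0, 1]`; symmetric in its arguments.
#' @export
pairwise_distance <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b)) {
    stop("sequences must have equal aligned length", call. = FALSE)
  }
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) {
    stop("no comparable columns between sequences", call. = FALSE)
  }
  mean(a[ok] != b[ok])
}

# Full symmetric distance matrix for a sequence tibble (seq_id, sequence).
pairwise_distance_matrix <- function(sequences) {
  n <- nrow(sequences)
  chars <- lapply(toupper(sequences$sequence), function(s) strsplit(s, "")[[1]])
  valid <- lapply(chars, function(x) x %in% c("A", "C", "G", "T"))
  d <- matrix(0, n, n, dimnames = list(sequences$seq_id, sequences$seq_id))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      ok <- valid[[i]] & valid[[j]]
      if (!any(ok)) stop("no comparable columns between '", sequences$seq_id[i],
                         "' and '", sequences$seq_id[j], "'", call. = FALSE)
      d[i, j] <- d[j, i] <- mean(chars[[i]][ok] != chars[[j]][ok])
    }
  }
  d
}

#' Select the primary reference sequence "S" of a taxon
#'
#' The primary reference is the sequence with the smallest median distance
#' to all other sequences of its taxon; a singleton taxon returns its only
#' member. Ties are broken by lexicographic sequence id.
#'
#' @param sequences tibble (`seq_id`, `sequence`) of one taxon's aligned
#'   sequences.
#' @return the selected `seq_id`.
#' @export
select_primary_reference <- function(sequences) {
  if (nrow(sequences) == 0) stop("no sequences supplied", call. = FALSE)
  if (nrow(sequences) == 1) return(sequences$seq_id)
  d <- pairwise_distance_matrix(sequences)
  med <- vapply(seq_len(nrow(d)), function(i) stats::median(d[i, -i]), numeric(1))
  ids <- sequences$seq_id
  ids[order(med, ids)][1]
}

#' Screen a taxon's sequences for mislabels
#'
#' Discards sequences whose distance to the primary reference exceeds
#' `cutoff` (default 0.015, i.e. less than 98.5% identity); the primary is
#' always kept.
#'
#' @param sequences tibble (`seq_id`, `sequence`) of one taxon.
#' @param primary the primary reference `seq_id` (must be present).
#' @param cutoff maximum allowed distance to the primary.
#' @return list with `kept` and `discarded` tibbles; `discarded` carries a
#'   `distance` column.
#' @export
filter_mislabeled <- function(sequences, primary, cutoff = 0.015) {
  if (!primary %in% sequences$seq_id) {
    stop("`primary` is not among the supplied sequences", call. = FALSE)
  }
  pseq <- sequences$sequence[sequences$seq_id == primary]
  d <- unname(vapply(sequences$sequence, pairwise_distance, numeric(1), seq_b = pseq))
  drop <- d > cutoff & sequences$seq_id != primary
  list(
    kept = sequences[!drop, ],
    discarded = dplyr::mutate(sequences[drop, ], distance = d[drop])
  )
}

#' Select maximally diverse representative sequences for a taxon
#'
#' Always retains the primary reference and any type-strain sequences, then
#' fills the remaining slots greedily: each step adds the sequence that
#' maximises the sum of pairwise distances among the selected set. Ties are
#' broken by lexicographic sequence id.
#'
#' @param sequences tibble (`seq_id`, `sequence`) of one taxon's kept
#'   sequences.
#' @param primary primary reference `seq_id`.
#' @param type_strain_ids `seq_id`s that must be retained.
#' @param n target number of representatives (default 5); raised when the
#'   mandatory set is larger.
#' @return tibble of selected sequences.
#' @export
select_representatives <- function(sequences, primary, type_strain_ids = character(0),
                                   n = 5) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  ids <- sequences$seq_id
  if (nrow(sequences) <= n) return(dplyr::arrange(sequences, .data$seq_id))
  d <- pairwise_distance_matrix(sequences)
  sel <- unique(c(primary, intersect(type_strain_ids, ids)))
  n <- max(n, length(sel))
  while (length(sel) < n) {
    cand <- sort(setdiff(ids, sel))
    gain <- vapply(cand, function(x) sum(d[x, sel]), numeric(1))
    sel <- c(sel, cand[which.max(gain)])
  }
  dplyr::arrange(sequences[ids %in% sel, ], .data$seq_id)
}

#' Assemble a curated reference package
#'
#' Runs the per-taxon curation chain (primary reference selection, mislabel
#' screening, representative selection) over an aligned sequence set and
#' bundles the result with its taxonomy and a phylogenetic tree. When no
#' tree is supplied, a neighbor-joining tree is built from the pairwise
#' distance matrix as a documented stand-in for a maximum-likelihood tree:
#' midpoint-rooted, negative branch lengths clamped to zero, edges numbered
#' by preorder traversal.
#'
#' @param sequences tibble (`seq_id`, `taxid`, `sequence`), pre-aligned.
#' @param taxonomy taxonomy tibble (see [synthetic_taxonomy()]).
#' @param tree optional externally built tree (bypasses neighbor joining).
#' @param cutoff mislabel screening cutoff (default 0.015).
#' @param n_representatives representatives per taxon (default 5).
#' @param type_strain_ids `seq_id`s that must be retained.
#' @return list of class `ref_pkg`: `sequences` (retained), `taxonomy`,
#'   `tree`, and `curation_log` (tibble: `taxid`, `seq_id`, `action`,
#'   `distance`).
#' @export
build_reference_package <- function(sequences, taxonomy, tree = NULL,
                                    cutoff = 0.015, n_representatives = 5,
                                    type_strain_ids = character(0)) {
  stopifnot(all(c("seq_id", "taxid", "sequence") %in% names(sequences)))
  unresolved <- setdiff(unique(sequences$taxid), taxonomy$taxid)
  if (length(unresolved)) {
    stop("sequence taxids missing from taxonomy: ",
         paste(unresolved, collapse = ", "), call. = FALSE)
  }
  log <- list()
  kept <- list()
  for (t in sort(unique(sequences$taxid))) {
    sx <- dplyr::arrange(sequences[sequences$taxid == t, ], .data$seq_id)
    primary <- select_primary_reference(sx)
    scr <- filter_mislabeled(sx, primary, cutoff = cutoff)
    if (nrow(scr$discarded)) {
      log[[length(log) + 1L]] <- tibble::tibble(
        taxid = t, seq_id = scr$discarded$seq_id,
        action = "discarded_mislabel", distance = scr$discarded$distance
      )
    }
    if (nrow(scr$kept) == 0) {
      warning("taxon '", t, "' has no sequences after mislabel screening; dropped",
              call. = FALSE)
      next
    }
    rep_seqs <- select_representatives(scr$kept, primary,
                                       type_strain_ids = type_strain_ids,
                                       n = n_representatives)
    log[[length(log) + 1L]] <- tibble::tibble(
      taxid = t, seq_id = rep_seqs$seq_id,
      action = ifelse(rep_seqs$seq_id == primary, "primary", "representative"),
      distance = NA_real_
    )
    kept[[t]] <- rep_seqs
  }
  kept <- dplyr::bind_rows(kept)
  if (is.null(tree)) {
    tree <- nj_tree_from_sequences(kept)
  } else {
    tree <- as_placement_tree(tree)
    missing_tips <- setdiff(tree$tip.label, kept$seq_id)
    if (length(missing_tips)) {
      stop("tree tips not among retained sequences: ",
           paste(utils::head(missing_tips, 5), collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(
      sequences = kept,
      taxonomy = taxonomy,
      tree = tree,
      curation_log = dplyr::bind_rows(log)
    ),
    class = "ref_pkg"
  )
}

# Neighbor-joining stand-in tree from aligned sequences: midpoint-rooted,
# negative branch lengths clamped to zero.
nj_tree_from_sequences <- function(sequences) {
  n <- nrow(sequences)
  if (n < 2) stop("need at least 2 sequences for a tree", call. = FALSE)
  d <- pairwise_distance_matrix(sequences)
  if (n == 2) {
    tree <- ape::read.tree(text = sprintf(
      "(%s:%f,%s:%f);", sequences$seq_id[1], d[1, 2] / 2,
      sequences$seq_id[2], d[1, 2] / 2
    ))
    return(as_placement_tree(tree))
  }
  tree <- ape::nj(stats::as.dist(d))
  tree <- phangorn::midpoint(tree)
  tree$edge.length[tree$edge.length < 0] <- 0
  tree$node.label <- NULL
  as_placement_tree(tree)
}

#' Write a reference package to a directory
#'
#' Emits aligned FASTA, taxonomy CSV, newick tree, curation log CSV, and a
#' JSON manifest naming each component.
#'
#' @param refpkg a [build_reference_package()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_refpkg <- function(refpkg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(refpkg$sequences, file.path(dir, "aligned.fasta"))
  utils::write.csv(refpkg$taxonomy, file.path(dir, "taxonomy.csv"), row.names = FALSE)
  ape::write.tree(refpkg$tree, file.path(dir, "tree.nwk"))
  utils::write.csv(refpkg$curation_log, file.path(dir, "curation_log.csv"),
                   row.names = FALSE)
  manifest <- list(
    format_version = "1.0",
    alignment = "aligned.fasta",
    taxonomy = "taxonomy.csv",
    tree = "tree.nwk",
    curation_log = "curation_log.csv",
    seq_info = tibble::tibble(seq_id = refpkg$sequences$seq_id,
                              taxid = refpkg$sequences$taxid)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a reference package directory
#'
#' @param dir a directory written by [write_refpkg()].
#' @return a `ref_pkg` list.
#' @export
read_refpkg <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  seqs <- read_fasta(file.path(dir, manifest$alignment))
  seqs$taxid <- manifest$seq_info$taxid[match(seqs$seq_id, manifest$seq_info$seq_id)]
  structure(
    list(
      sequences = seqs[, c("seq_id", "taxid", "sequence")],
      taxonomy = tibble::as_tibble(
        utils::read.csv(file.path(dir, manifest$taxonomy), stringsAsFactors = FALSE)
      ),
      tree = as_placement_tree(ape::read.tree(file.path(dir, manifest$tree))),
      curation_log = tibble::as_tibble(
        utils::read.csv(file.path(dir, manifest$curation_log), stringsAsFactors = FALSE)
      )
    ),
    class = "ref_pkg"
  )
}
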