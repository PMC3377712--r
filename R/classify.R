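#' Label tree edges with taxonomic identifiers
#'
#' For each edge, ranks are scanned from most to least specific over the
#' leaves on the edge's distal side; the edge is labeled with taxid `t` at
#' the first rank `r` at which exactly one distinct rank-`r` taxid occurs
#' on that side. The distal side takes precedence throughout — this is
#' what puts species labels on terminal and within-clade edges and genus
#' labels on clade stems. Only when no rank is pure distally is the same
#' scan applied to the proximal side; edges where neither side ever
#' purifies get the root taxid.
#'
#' The alternative, stricter reading of the rule — requiring the
#' identifier to be the only one across both sides together — is available
#' as `strategy = "both_sides"`; on trees whose taxa form pure clades the
#' two readings agree.
#'
#' @param tree a placement tree whose tips are reference `seq_id`s.
#' @param taxonomy taxonomy tibble.
#' @param seq_taxids named character vector mapping tip labels to species
#'   (or provisional) taxids.
#' @param strategy `"one_side"` (default) or `"both_sides"`.
#' @return tibble (`edge_id`, `rank`, `taxid`).
#' @export
label_edges <- function(tree, taxonomy, seq_taxids,
                        strategy = c("one_side", "both_sides")) {
  strategy <- match.arg(strategy)
  tree <- as_placement_tree(tree)
  et <- edge_table(tree)
  n_tip <- length(tree$tip.label)
  tip_taxid <- seq_taxids[tree$tip.label]
  if (anyNA(tip_taxid)) {
    stop("leaves without a resolvable taxid: ",
         paste(utils::head(tree$tip.label[is.na(tip_taxid)], 5), collapse = ", "),
         call. = FALSE)
  }
  lin <- lineage_table(taxonomy)
  ranks <- setdiff(rev(taxonomy_ranks()), "root") # most to least specific
  # per-tip ancestor taxid at each rank
  tip_at_rank <- lapply(ranks, function(r) {
    v <- lin[[r]][match(tip_taxid, lin$taxid)]
    if (anyNA(v)) stop("leaf lineage does not reach rank '", r, "'", call. = FALSE)
    v
  })
  names(tip_at_rank) <- ranks

  below <- tips_below_edges(tree)
  all_tips <- seq_len(n_tip)
  out_rank <- character(nrow(et))
  out_taxid <- character(nrow(et))
  for (i in seq_len(nrow(et))) {
    distal <- below[[i]]
    proximal <- setdiff(all_tips, distal)
    assigned <- FALSE
    if (strategy == "one_side") {
      for (side in list(distal, proximal)) {
        for (r in ranks) {
          tt <- unique(tip_at_rank[[r]][side])
          if (length(tt) == 1L) {
            out_rank[i] <- r; out_taxid[i] <- tt; assigned <- TRUE; break
          }
        }
        if (assigned) break
      }
    } else {
      for (r in ranks) {
        both <- unique(c(tip_at_rank[[r]][distal], tip_at_rank[[r]][proximal]))
        if (length(both) == 1L) {
          out_rank[i] <- r; out_taxid[i] <- both; assigned <- TRUE; break
        }
      }
    }
    if (!assigned) {
      out_rank[i] <- "root"
      out_taxid[i] <- "root"
    }
  }
  tibble::tibble(edge_id = et$edge_id, rank = out_rank, taxid = out_taxid)
}

#' Classify placed reads by summed posterior probability
#'
#' For each read, candidate taxa are the labels of the edges carrying
#' posterior mass together with all their ancestors. The cumulative
#' posterior of a candidate is the sum of posteriors over attachments whose
#' edge label is that taxid or one of its descendants. Each read is
#' assigned the most specific taxid whose cumulative posterior reaches
#' `cutoff`; because every label lifts to the root, classification always
#' succeeds at some rank.
#'
#' @param placements attachment tibble (`read_id`, `edge_id`, `posterior`,
#'   plus any identifying columns such as `sample`). Posteriors are
#'   renormalised to sum to 1 per read.
#' @param edge_labels result of [label_edges()].
#' @param taxonomy taxonomy tibble.
#' @param cutoff posterior probability cutoff (default 0.9).
#' @param compound_threshold,compound_max for genus-or-higher assignments, a
#'   compound name is appended naming up to `compound_max` more-specific
#'   taxa whose individual cumulative posterior exceeds
#'   `compound_threshold` (defaults 0.05 and 3).
#' @return tibble with one row per read: `read_id` (plus `sample` if
#'   present), `taxid`, `rank`, `posterior`, `name` (compound name when
#'   applicable, otherwise the taxon name).
#' @export
classify_reads <- function(placements, edge_labels, taxonomy, cutoff = 0.9,
                           compound_threshold = 0.05, compound_max = 3) {
  stopifnot(all(c("read_id", "edge_id", "posterior") %in% names(placements)))
  missing_edges <- setdiff(placements$edge_id, edge_labels$edge_id)
  if (length(missing_edges)) {
    stop("placements reference unlabeled edges: ",
         paste(utils::head(missing_edges, 5), collapse = ", "), call. = FALSE)
  }
  lin <- lineage_table(taxonomy)
  ranks <- setdiff(rev(taxonomy_ranks()), "root")
  p <- dplyr::group_by(placements, .data$read_id)
  p <- dplyr::mutate(p, posterior = .data$posterior / sum(.data$posterior))
  p <- dplyr::ungroup(p)
  lab_idx <- match(edge_labels$taxid[match(p$edge_id, edge_labels$edge_id)], lin$taxid)

  # cumulative posterior per read and per lifted taxid, one rank at a time;
  # an edge whose label is less specific than the rank contributes nothing
  rank_sums <- lapply(ranks, function(r) {
    lifted <- lin[[r]][lab_idx]
    d <- tibble::tibble(read_id = p$read_id, taxid = lifted, posterior = p$posterior)
    d <- dplyr::filter(d, !is.na(.data$taxid))
    d <- dplyr::summarise(dplyr::group_by(d, .data$read_id, .data$taxid),
                          posterior = sum(.data$posterior), .groups = "drop")
    d$rank <- r
    d
  })
  names(rank_sums) <- ranks

  ids <- unique(p$read_id)
  assigned <- tibble::tibble(read_id = ids, taxid = "root", rank = "root",
                             posterior = 1)
  done <- rep(FALSE, length(ids))
  for (r in ranks) {
    d <- rank_sums[[r]]
    d <- dplyr::filter(d, .data$posterior >= cutoff)
    if (nrow(d) == 0) next
    # at most one taxid can reach a cutoff > 0.5; for smaller cutoffs keep
    # the largest (ties by taxid)
    d <- dplyr::slice_max(dplyr::group_by(d, .data$read_id), .data$posterior,
                          n = 1, with_ties = FALSE)
    d <- dplyr::ungroup(d)
    hit <- match(d$read_id, ids)
    new <- hit[!done[hit]]
    dn <- d[!done[hit], ]
    assigned$taxid[new] <- dn$taxid
    assigned$rank[new] <- r
    assigned$posterior[new] <- dn$posterior
    done[new] <- TRUE
  }

  name_of <- stats::setNames(taxonomy$name, taxonomy$taxid)
  name_of <- c(name_of, root = "root")
  assigned$name <- unname(name_of[assigned$taxid])
  # compound names for genus-or-higher classifications
  needs_compound <- which(assigned$rank != "species")
  if (length(needs_compound)) {
    species_sums <- rank_sums[["species"]]
    cn <- compound_name(
      assigned[needs_compound, ], species_sums, taxonomy,
      threshold = compound_threshold, max_names = compound_max
    )
    assigned$name[needs_compound] <- cn
  }
  extra <- intersect(c("sample", "subject", "true_taxid"), names(placements))
  if (length(extra)) {
    first <- dplyr::distinct(p[, c("read_id", extra)], .data$read_id, .keep_all = TRUE)
    assigned <- dplyr::left_join(assigned, first, by = "read_id")
  }
  assigned
}

#' Compound names for genus-or-higher classifications
#'
#' Appends to a non-species classification the names of up to `max_names`
#' species-rank taxa below it, each with individual cumulative posterior
#' greater than `threshold`, joined with `/` (e.g. `"Lactobacillus
#' crispatus/iners"`). Species-level classifications are returned
#' unchanged.
#'
#' @param classification tibble rows (`read_id`, `taxid`, `rank`, `name`).
#' @param species_posteriors tibble (`read_id`, `taxid`, `posterior`) of
#'   species-rank cumulative posteriors.
#' @param taxonomy taxonomy tibble.
#' @param threshold minimum individual posterior (default 0.05).
#' @param max_names maximum number of names appended (default 3).
#' @return character vector of display names, one per classification row.
#' @export
compound_name <- function(classification, species_posteriors, taxonomy,
                          threshold = 0.05, max_names = 3) {
  lin <- lineage_table(taxonomy)
  name_of <- stats::setNames(taxonomy$name, taxonomy$taxid)
  out <- classification$name
  for (k in seq_len(nrow(classification))) {
    row <- classification[k, ]
    if (row$rank == "species") next
    sp <- dplyr::filter(species_posteriors, .data$read_id == row$read_id,
                        .data$posterior > threshold)
    if (row$taxid != "root") {
      anc <- lin[[row$rank]][match(sp$taxid, lin$taxid)]
      sp <- sp[!is.na(anc) & anc == row$taxid, ]
    }
    if (nrow(sp) == 0) next
    sp <- dplyr::arrange(sp, dplyr::desc(.data$posterior), .data$taxid)
    sp <- utils::head(sp, max_names)
    out[k] <- paste0(row$name, " ", paste(name_of[sp$taxid], collapse = "/"))
  }
  out
}

#' Place a read on the reference tree by nearest-reference identity
#'
#' A deliberately simple distance-based placer used to exercise the
#' classification machinery on synthetic data: each reference leaf is
#' scored by the best ungapped-offset identity fraction against the read,
#' the top `top_k` leaves are converted to posteriors by a
#' temperature-controlled softmax, and attachments are placed at the
#' midpoint of those leaves' terminal edges with a fixed pendant length.
#' It makes no attempt at likelihood-based placement.
#'
#' @param read_seq read sequence (character scalar).
#' @param refpkg a `ref_pkg` (sequences must be degappable to plain
#'   nucleotides).
#' @param top_k number of candidate leaves retained (default 3).
#' @param temperature softmax temperature on the identity scale (default
#'   4e-4, sharp enough to resolve single-site identity differences;
#'   smaller is more concentrated).
#' @param score_floor minimum identity for any placement (default 0.6).
#' @param min_posterior attachments below this posterior are dropped and
#'   the rest renormalised (default 1e-3).
#' @return attachment tibble (`edge_id`, `distal_length`, `pendant_length`,
#'   `posterior`), or a zero-row tibble when no leaf scores above
#'   `score_floor`.
#' @export
naive_place <- function(read_seq, refpkg, top_k = 3, temperature = 4e-4,
                        score_floor = 0.6, min_posterior = 1e-3) {
  tree <- as_placement_tree(refpkg$tree)
  et <- edge_table(tree)
  read <- strsplit(toupper(read_seq), "")[[1]]
  scores <- vapply(refpkg$sequences$sequence, function(ref) {
    best_offset_identity(read, strsplit(gsub("[-.]", "", toupper(ref)), "")[[1]])
  }, numeric(1))
  names(scores) <- refpkg$sequences$seq_id
  keep <- utils::head(order(-scores, names(scores)), top_k)
  scores <- scores[keep]
  if (max(scores) < score_floor) {
    return(tibble::tibble(edge_id = integer(0), distal_length = numeric(0),
                          pendant_length = numeric(0), posterior = numeric(0)))
  }
  w <- exp((scores - max(scores)) / temperature)
  post <- w / sum(w)
  drop <- post < min_posterior
  post <- post[!drop] / sum(post[!drop])
  leaf_edges <- et[match(names(post), et$tip_label), ]
  tibble::tibble(
    edge_id = leaf_edges$edge_id,
    distal_length = leaf_edges$length / 2,
    pendant_length = 0.01,
    posterior = unname(post)
  )
}

# Best ungapped-offset identity fraction of `read` against `ref` (character
# vectors); the read is slid along the reference and scored by matches /
# read length.
best_offset_identity <- function(read, ref) {
  lr <- length(read)
  lf <- length(ref)
  if (lr > lf) {
    tmp <- read; read <- ref; ref <- tmp
    lr <- length(read); lf <- length(ref)
  }
  best <- 0
  for (off in 0:(lf - lr)) {
    m <- sum(read == ref[(off + 1):(off + lr)]) / lr
    if (m > best) best <- m
    if (best == 1) break
  }
  best
}
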