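#' Simulate a curated vaginal-niche reference world
#'
#' Generates an aligned reference sequence set, a rank-structured taxonomy
#' (family, genus, species, including provisional BVAB-style taxa), and a
#' phylogenetic tree, with the distance structure the curation and
#' classification stages assume: sequences of one species sit within 1.5%
#' pairwise distance of each other while different species are separated by
#' more than 3%.
#'
#' Divergence is engineered hierarchically with disjoint blocks of
#' alignment columns: every genus mutates its own genus block, and every
#' species additionally mutates a species block, so congeners are closer
#' to each other than to other genera and between-species divergence is
#' guaranteed by construction rather than in expectation. Within-species
#' variation is a small number of i.i.d. substitutions outside all blocks.
#' Only distances matter downstream, so no indel process is simulated and
#' the "alignment" is gap-free.
#'
#' @param n_taxa number of species-level taxa (>= 2). The first two are
#'   Lactobacillus-like (crispatus-like and iners-like); the remainder are
#'   BV-associated taxa including at least one provisional (BVAB-like) taxon.
#' @param seqs_per_taxon reference sequences per taxon (>= 1).
#' @param seq_length alignment length in columns (>= 50).
#' @param seed integer seed; all randomness is drawn from it.
#' @param genus_frac,between_frac,within_frac fraction of columns mutated
#'   per genus block, per species block, and per individual sequence.
#'   Defaults give ~7% between-genus, ~4% within-genus between-species and
#'   <1% within-species distances.
#' @return a list of class `reference_world`: `sequences` (tibble: `seq_id`,
#'   `taxid`, `sequence`), `taxonomy` (see [synthetic_taxonomy()]), and
#'   `tree` (a [as_placement_tree()] tree whose tips are `seq_id`s).
#' @export
simulate_reference_world <- function(n_taxa = 12, seqs_per_taxon = 5,
                                     seq_length = 300, seed = 1,
                                     genus_frac = 0.015,
                                     between_frac = 0.02, within_frac = 0.004) {
  if (n_taxa < 2) stop("`n_taxa` must be >= 2", call. = FALSE)
  if (seqs_per_taxon < 1) stop("`seqs_per_taxon` must be >= 1", call. = FALSE)
  if (seq_length < 50) stop("`seq_length` must be >= 50", call. = FALSE)

  taxonomy <- synthetic_taxonomy(n_taxa)
  species <- dplyr::filter(taxonomy, .data$rank == "species")
  genus_of <- species$parent
  genera <- unique(genus_of)

  s_block <- max(2L, ceiling(between_frac * seq_length))
  g_block <- max(2L, ceiling(genus_frac * seq_length))
  n_block_cols <- n_taxa * s_block + length(genera) * g_block
  if (n_block_cols > floor(seq_length * 0.6)) {
    stop("`seq_length` too small for `n_taxa` disjoint mutation blocks",
         call. = FALSE)
  }
  local_rng(seed)

  bases <- c("A", "C", "G", "T")
  root_seq <- sample(bases, seq_length, replace = TRUE)
  edges0 <- cumsum(c(0L, rep(s_block, n_taxa), rep(g_block, length(genera))))
  blocks <- lapply(seq_len(n_taxa + length(genera)), function(i) {
    (edges0[i] + 1L):edges0[i + 1L]
  })
  sp_blocks <- blocks[seq_len(n_taxa)]
  gn_blocks <- blocks[n_taxa + seq_along(genera)]
  free_cols <- setdiff(seq_len(seq_length), unlist(blocks))
  n_within <- max(1L, floor(within_frac * seq_length))

  rotate_base <- function(b, k) bases[((match(b, bases) - 1L + k) %% 4L) + 1L]
  seqs <- list()
  for (i in seq_len(n_taxa)) {
    g <- match(genus_of[i], genera)
    ancestor <- root_seq
    ancestor[gn_blocks[[g]]] <- rotate_base(ancestor[gn_blocks[[g]]], 1L + (g %% 3L))
    ancestor[sp_blocks[[i]]] <- rotate_base(ancestor[sp_blocks[[i]]], 1L + (i %% 3L))
    for (j in seq_len(seqs_per_taxon)) {
      s <- ancestor
      if (j > 1L) { # first sequence is the unmutated species ancestor
        at <- sample(free_cols, n_within)
        s[at] <- rotate_base(s[at], sample(1:3, n_within, replace = TRUE))
      }
      seq_id <- sprintf("%s_r%02d", species$taxid[i], j)
      seqs[[seq_id]] <- paste(s, collapse = "")
    }
  }
  sequences <- tibble::tibble(
    seq_id = names(seqs),
    taxid = rep(species$taxid, each = seqs_per_taxon),
    sequence = unlist(seqs, use.names = FALSE)
  )
  tree <- nj_tree_from_sequences(sequences)
  structure(
    list(sequences = sequences, taxonomy = taxonomy, tree = tree),
    class = "reference_world"
  )
}

#' Rank-structured synthetic taxonomy for the vaginal niche
#'
#' Builds a taxonomy table (root, family, genus, species) whose species are
#' named after the taxa that dominate vaginal communities: two Lactobacillus
#' species (crispatus-like, dominant in non-BV women; iners-like, found in
#' both states) and BV-associated anaerobes, including provisional
#' uncultivated taxa in the style of BVAB1/2/3.
#'
#' @param n_taxa number of species (>= 2).
#' @return tibble with columns `taxid`, `name`, `rank`, `parent`,
#'   `provisional`, ordered root first. Rank order is given by
#'   [taxonomy_ranks()].
#' @export
synthetic_taxonomy <- function(n_taxa = 12) {
  if (n_taxa < 2) stop("`n_taxa` must be >= 2", call. = FALSE)
  pool <- tibble::tribble(
    ~species, ~genus, ~family, ~provisional,
    "Lactobacillus_crispatus_like", "Lactobacillus", "Lactobacillaceae", FALSE,
    "Lactobacillus_iners_like", "Lactobacillus", "Lactobacillaceae", FALSE,
    "Gardnerella_vaginalis_like", "Gardnerella", "Bifidobacteriaceae", FALSE,
    "Atopobium_vaginae_like", "Atopobium", "Coriobacteriaceae", FALSE,
    "BVAB1", "BVAB_genogroup", "Lachnospiraceae", TRUE,
    "BVAB2", "BVAB_genogroup", "Lachnospiraceae", TRUE,
    "Prevotella_amnii_like", "Prevotella", "Prevotellaceae", FALSE,
    "Prevotella_timonensis_like", "Prevotella", "Prevotellaceae", FALSE,
    "Megasphaera_type1_like", "Megasphaera", "Veillonellaceae", FALSE,
    "Sneathia_sanguinegens_like", "Sneathia", "Leptotrichiaceae", FALSE,
    "Leptotrichia_amnionii_like", "Leptotrichia", "Leptotrichiaceae", FALSE,
    "Eggerthella_like", "Eggerthella", "Coriobacteriaceae", FALSE
  )
  if (n_taxa > nrow(pool)) {
    extra <- tibble::tibble(
      species = sprintf("BVAB%d", seq_len(n_taxa - nrow(pool)) + 2L),
      genus = "BVAB_genogroup",
      family = "Lachnospiraceae",
      provisional = TRUE
    )
    pool <- dplyr::bind_rows(pool, extra)
  }
  pool <- pool[seq_len(n_taxa), ]
  fams <- unique(pool$family)
  gens <- unique(pool[, c("genus", "family")])
  dplyr::bind_rows(
    tibble::tibble(taxid = "root", name = "root", rank = "root",
                   parent = NA_character_, provisional = FALSE),
    tibble::tibble(taxid = fams, name = fams, rank = "family",
                   parent = "root", provisional = FALSE),
    tibble::tibble(taxid = gens$genus, name = gens$genus, rank = "genus",
                   parent = gens$family, provisional = gens$genus == "BVAB_genogroup"),
    tibble::tibble(taxid = pool$species, name = pool$species, rank = "species",
                   parent = pool$genus, provisional = pool$provisional)
  )
}

#' Rank order used throughout the package
#'
#' @return character vector of ranks from least to most specific.
#' @export
taxonomy_ranks <- function() c("root", "family", "genus", "species")

# Ancestor taxid of each species-rank taxid at every rank; wide tibble with
# one row per species and one column per rank.
lineage_table <- function(taxonomy) {
  ranks <- taxonomy_ranks()
  parent_of <- stats::setNames(taxonomy$parent, taxonomy$taxid)
  rank_of <- stats::setNames(taxonomy$rank, taxonomy$taxid)
  lineage_of <- function(taxid) {
    out <- stats::setNames(rep(NA_character_, length(ranks)), ranks)
    t <- taxid
    while (!is.na(t)) {
      out[rank_of[[t]]] <- t
      t <- parent_of[[t]]
    }
    out
  }
  ids <- taxonomy$taxid
  mat <- t(vapply(ids, lineage_of, character(length(ranks))))
  out <- tibble::as_tibble(mat)
  out$taxid <- ids
  dplyr::relocate(out, "taxid")
}

# Seeded RNG scope: sets the seed for the calling function's lifetime and
# restores the caller's RNG state afterwards, so package randomness never
# leaks into or depends on global state.
local_rng <- function(seed, envir = parent.frame()) {
  if (!is.null(seed)) {
    withr::local_seed(as.integer(seed), .local_envir = envir)
  }
  invisible(NULL)
}
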