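#' Simulate phylogenetic placements for a cohort's reads
#'
#' Converts a count table into per-read placements on a reference tree,
#' with the posterior-mass structure a likelihood placer would produce:
#' each read's posterior concentrates on edges within its source taxon's
#' clade, with a configurable fraction of stray mass on other edges.
#'
#' Every read gets one "home" attachment on a terminal edge of a leaf of
#' its taxon, carrying posterior `1 - placement_spread`, and (when
#' `placement_spread > 0`) two stray attachments on edges outside the clade
#' splitting the remaining mass. The number of reads per (sample, taxon)
#' equals the count table entry.
#'
#' @param counts long count tibble (`sample`, `taxid`, `count`).
#' @param world a [simulate_reference_world()] result (tree + sequences
#'   provide the taxon-to-leaf map).
#' @param placement_spread fraction of each read's posterior mass placed
#'   outside its taxon's clade (in `[0, 1)`).
#' @param seed integer seed.
#' @return tibble of attachments with columns `sample`, `read_id`,
#'   `subject`, `true_taxid`, `edge_id`, `distal_length`, `pendant_length`,
#'   `posterior`. Posteriors sum to 1 per read.
#' @export
simulate_placements <- function(counts, world, placement_spread = 0.02, seed = 1) {
  stopifnot(placement_spread >= 0, placement_spread < 1)
  local_rng(seed)
  tree <- as_placement_tree(world$tree)
  et <- edge_table(tree)

  leaf_edges <- dplyr::filter(et, .data$is_terminal)
  leaf_taxid <- world$sequences$taxid[match(leaf_edges$tip_label, world$sequences$seq_id)]
  if (anyNA(leaf_taxid)) stop("tree tips do not match reference sequences", call. = FALSE)
  taxon_edges <- split(leaf_edges$edge_id, leaf_taxid)

  reads <- dplyr::filter(counts, .data$count > 0)
  unknown <- setdiff(unique(reads$taxid), names(taxon_edges))
  if (length(unknown)) {
    stop("taxa without leaves on the tree: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  reads <- reads[rep(seq_len(nrow(reads)), reads$count), c("sample", "taxid")]
  n <- nrow(reads)
  if (n == 0) stop("count table has no reads", call. = FALSE)
  reads$read_id <- sprintf("%s_r%06d", reads$sample, stats::ave(
    rep(1L, n), reads$sample, FUN = seq_along))

  home <- vapply(reads$taxid, function(t) {
    e <- taxon_edges[[t]]
    if (length(e) == 1L) e else sample(e, 1L)
  }, integer(1))
  len <- et$length[match(home, et$edge_id)]
  out <- tibble::tibble(
    sample = reads$sample,
    read_id = reads$read_id,
    subject = reads$sample,
    true_taxid = reads$taxid,
    edge_id = home,
    distal_length = len / 2,
    pendant_length = 0.01,
    posterior = 1 - placement_spread
  )
  if (placement_spread > 0) {
    clade_ids <- taxon_edges[reads$taxid]
    stray <- lapply(seq_len(n), function(i) {
      pool <- setdiff(et$edge_id, clade_ids[[i]])
      sample(pool, min(2L, length(pool)))
    })
    k <- lengths(stray)
    stray_edge <- unlist(stray)
    stray_len <- et$length[match(stray_edge, et$edge_id)]
    extra <- tibble::tibble(
      sample = rep(reads$sample, k),
      read_id = rep(reads$read_id, k),
      subject = rep(reads$sample, k),
      true_taxid = rep(reads$taxid, k),
      edge_id = stray_edge,
      distal_length = stray_len / 2,
      pendant_length = 0.01,
      posterior = rep(placement_spread / k, k)
    )
    out <- dplyr::bind_rows(out, extra)
  }
  dplyr::arrange(out, .data$sample, .data$read_id, dplyr::desc(.data$posterior))
}

#' Write a synthetic barcoded pyrosequencing run as FASTQ
#'
#' Turns a count table into raw multiplexed reads: each read is
#' `barcode + primer + read body`, where the body is a mutated subsequence
#' of one of its taxon's reference sequences and the per-base qualities are
#' drawn around a configurable profile. A configurable fraction of
#' deliberately failing reads (unknown barcode, short body, low quality) is
#' injected and logged so the QC stage can be tested against ground truth.
#'
#' @param counts long count tibble (`sample`, `taxid`, `count`).
#' @param world a [simulate_reference_world()] result.
#' @param barcodes tibble (`sample`, `barcode`); barcodes must be distinct
#'   and of equal length (8 bp by convention). Generated automatically when
#'   `NULL`.
#' @param primer primer sequence appearing after the barcode.
#' @param read_length body length of a clean read.
#' @param quality_mean,quality_sd per-base Phred quality profile.
#' @param fail_frac named numeric vector with entries `bad_barcode`,
#'   `short`, `low_quality`: fraction of reads injected with each defect.
#' @param mutation_rate per-base substitution rate applied to read bodies.
#' @param path output FASTQ path (Sanger Phred+33).
#' @param seed integer seed.
#' @return invisibly, a list: `path`, `barcodes`, and `injection_log`
#'   (tibble `read_id`, `sample`, `taxid`, `fail_type` with `"none"` for
#'   clean reads).
#' @export
write_fastq_run <- function(counts, world, barcodes = NULL,
                            primer = "ATTAGAWACCC", read_length = 250,
                            quality_mean = 38, quality_sd = 2,
                            fail_frac = c(bad_barcode = 0, short = 0, low_quality = 0),
                            mutation_rate = 0.005,
                            path = tempfile(fileext = ".fastq"), seed = 1) {
  local_rng(seed)
  samples <- sort(unique(counts$sample))
  if (is.null(barcodes)) {
    barcodes <- tibble::tibble(sample = samples, barcode = make_barcodes(length(samples)))
  }
  if (anyDuplicated(barcodes$barcode)) {
    stop("duplicate barcodes", call. = FALSE)
  }
  if (length(unique(nchar(barcodes$barcode))) != 1) {
    stop("barcodes must all have the same length", call. = FALSE)
  }
  fail_frac <- fail_frac[c("bad_barcode", "short", "low_quality")]
  fail_frac[is.na(fail_frac)] <- 0

  refs <- split(world$sequences$sequence, world$sequences$taxid)
  reads <- dplyr::filter(counts, .data$count > 0)
  reads <- reads[rep(seq_len(nrow(reads)), reads$count), c("sample", "taxid")]
  n <- nrow(reads)
  reads$read_id <- sprintf("%s_r%06d", reads$sample,
                           stats::ave(rep(1L, n), reads$sample, FUN = seq_along))
  fail <- sample(
    c("none", names(fail_frac)), n, replace = TRUE,
    prob = c(max(0, 1 - sum(fail_frac)), fail_frac)
  )

  bases <- c("A", "C", "G", "T")
  bc <- barcodes$barcode[match(reads$sample, barcodes$sample)]
  bodies <- character(n)
  quals <- character(n)
  bclen <- nchar(barcodes$barcode[1])
  for (i in seq_len(n)) {
    ref <- refs[[reads$taxid[i]]]
    ref <- gsub("-", "", ref[sample.int(length(ref), 1)])
    L <- if (fail[i] == "short") sample(50:150, 1) else min(read_length, nchar(ref))
    start <- sample.int(max(1L, nchar(ref) - L + 1L), 1)
    body <- strsplit(substr(ref, start, start + L - 1L), "")[[1]]
    nmut <- stats::rbinom(1, L, mutation_rate)
    if (nmut > 0) {
      at <- sample.int(L, nmut)
      body[at] <- sample(bases, nmut, replace = TRUE)
    }
    this_bc <- if (fail[i] == "bad_barcode") {
      paste(rev(strsplit(bc[i], "")[[1]]), collapse = "")
    } else {
      bc[i]
    }
    qm <- if (fail[i] == "low_quality") 20 else quality_mean
    total <- bclen + nchar(primer) + L
    q <- pmin(40L, pmax(2L, as.integer(round(stats::rnorm(total, qm, quality_sd)))))
    bodies[i] <- paste0(this_bc, primer, paste(body, collapse = ""))
    quals[i] <- intToUtf8(q + 33L)
  }
  # reversed barcodes can collide with real ones (palindromes, other samples)
  if (any(fail == "bad_barcode")) {
    known <- barcodes$barcode
    still <- substr(bodies, 1, bclen) %in% known & fail == "bad_barcode"
    if (any(still)) {
      repl <- paste0(strrep("N", 1), substr(bodies[still], 2, bclen))
      bodies[still] <- paste0(repl, substr(bodies[still], bclen + 1, nchar(bodies[still])))
    }
  }
  write_fastq(tibble::tibble(read_id = reads$read_id, sequence = bodies, quality = quals),
              path)
  invisible(list(
    path = path,
    barcodes = barcodes,
    injection_log = tibble::tibble(
      read_id = reads$read_id, sample = reads$sample,
      taxid = reads$taxid, fail_type = fail
    )
  ))
}

# Distinct fixed-length barcodes, deterministic in the current RNG state.
make_barcodes <- function(n, length = 8) {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  while (length(out) < n) {
    cand <- apply(matrix(sample(bases, 50 * length, replace = TRUE), ncol = length),
                  1, paste, collapse = "")
    out <- unique(c(out, cand))
  }
  out[seq_len(n)]
}
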