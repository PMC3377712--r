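#' Shannon diversity of a count vector
#'
#' `H = -sum p_i log p_i` over taxa with positive counts; natural log by
#' default (the ecology convention).
#'
#' @param counts nonnegative count vector with at least one positive entry.
#' @param base logarithm base (default `exp(1)`).
#' @return diversity index, >= 0.
#' @export
shannon <- function(counts, base = exp(1)) {
  if (all(counts == 0)) stop("all counts are zero", call. = FALSE)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' Chao1 richness estimate
#'
#' Bias-corrected by default:
#' `S_obs + f1 (f1 - 1) / (2 (f2 + 1))`, with `f1`/`f2` the singleton and
#' doubleton counts. The classic estimator `S_obs + f1^2 / (2 f2)` is
#' selectable (it is undefined when `f2 = 0` with singletons present, in
#' which case the bias-corrected form is used for that term, as is
#' standard).
#'
#' @param counts nonnegative count vector with at least one positive entry.
#' @param bias_corrected use the bias-corrected form (default `TRUE`).
#' @return estimated richness, >= observed richness.
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  if (all(counts == 0)) stop("all counts are zero", call. = FALSE)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected || f2 == 0) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    s_obs + f1^2 / (2 * f2)
  }
}

#' Per-sample diversity table
#'
#' @param counts long count tibble (`sample`, `taxid`, `count`).
#' @return tibble: `sample`, `richness` (observed), `shannon`, `chao1`.
#' @export
diversity_table <- function(counts) {
  dplyr::summarise(
    dplyr::group_by(counts, .data$sample),
    richness = sum(.data$count > 0),
    shannon = shannon(.data$count),
    chao1 = chao1(.data$count),
    .groups = "drop"
  )
}

#' Trim a count table to its most abundant taxa
#'
#' Taxa are ranked by total abundance across all samples and the top
#' `ceiling(top_frac * n_taxa)` retained. The attached trim report states
#' the fraction of reads the retained taxa account for.
#'
#' @param counts long count tibble (`sample`, `taxid`, `count`).
#' @param top_frac fraction of taxa to retain (default 0.30).
#' @return the trimmed count tibble, with attribute `trim_report` (list:
#'   `n_taxa_in`, `n_taxa_kept`, `retained_read_fraction`).
#' @export
trim_taxa <- function(counts, top_frac = 0.30) {
  totals <- dplyr::summarise(dplyr::group_by(counts, .data$taxid),
                             total = sum(.data$count), .groups = "drop")
  totals <- dplyr::arrange(totals, dplyr::desc(.data$total), .data$taxid)
  n_keep <- ceiling(top_frac * nrow(totals))
  keep <- totals$taxid[seq_len(n_keep)]
  out <- counts[counts$taxid %in% keep, ]
  attr(out, "trim_report") <- list(
    n_taxa_in = nrow(totals),
    n_taxa_kept = n_keep,
    retained_read_fraction = sum(totals$total[seq_len(n_keep)]) / sum(totals$total)
  )
  out
}

#' Taxon co-occurrence analysis
#'
#' Pearson correlations between `log(count + 0.5)`-transformed per-taxon
#' counts across samples (the 0.5 is a continuity correction), with the
#' correlation rows clustered by Euclidean distance and complete linkage.
#' Zero-variance taxa have undefined correlations and are dropped with a
#' warning.
#'
#' @param counts long count tibble (`sample`, `taxid`, `count`), >= 3
#'   samples.
#' @return list of class `cooccurrence`: `taxa` (retained), `correlation`
#'   (matrix), `clustering` (hclust), `dropped`.
#' @export
cooccurrence <- function(counts) {
  m <- count_matrix(counts)
  if (nrow(m) < 3) stop("need >= 3 samples", call. = FALSE)
  x <- log(m + 0.5)
  v <- apply(x, 2, stats::var)
  dropped <- colnames(x)[v == 0]
  if (length(dropped)) {
    warning("dropping zero-variance taxa: ", paste(dropped, collapse = ", "),
            call. = FALSE)
    x <- x[, v > 0, drop = FALSE]
  }
  cc <- stats::cor(x)
  hc <- stats::hclust(stats::dist(cc), method = "complete")
  structure(
    list(taxa = colnames(x), correlation = cc, clustering = hc, dropped = dropped),
    class = "cooccurrence"
  )
}

#' Community summary statistics by BV group
#'
#' Computes, per taxon and BV group, the prevalence (fraction of samples
#' with at least one read) and read share (taxon reads / group reads);
#' per sample, the dominant taxon (plurality of reads, ties broken
#' lexicographically and flagged); and, per group, the minimal set of top
#' taxa whose cumulative read share reaches `target_share`.
#'
#' @param counts long count tibble (`sample`, `taxid`, `count`).
#' @param meta sample metadata with a `sample` column and the BV columns of
#'   [simulate_cohort()].
#' @param bv_definition `"nugent"` (Gram stain, score >= 7) or `"amsel"`
#'   (clinical 3-of-4 rule).
#' @param target_share read-share target for the coverage summary (default
#'   0.95).
#' @param dominance `"plurality"` (default) or `"majority"` (> 50% of
#'   reads required, otherwise `NA`).
#' @return list of class `community_summary`: `taxon_summary` (tibble:
#'   `group`, `taxid`, `prevalence`, `read_share`), `dominance` (tibble:
#'   `sample`, `group`, `dominant_taxid`, `dominant_share`, `tie`),
#'   `coverage` (tibble: `group`, `n_taxa`, `taxa`).
#' @export
community_summaries <- function(counts, meta, bv_definition = c("nugent", "amsel"),
                                target_share = 0.95,
                                dominance = c("plurality", "majority")) {
  bv_definition <- match.arg(bv_definition)
  dominance <- match.arg(dominance)
  col <- if (bv_definition == "nugent") "bv_nugent" else "bv_amsel"
  if (!col %in% names(meta)) stop("metadata lacks column '", col, "'", call. = FALSE)
  d <- dplyr::inner_join(counts, meta[, c("sample", col)], by = "sample")
  if (nrow(d) == 0) stop("no samples after joining metadata", call. = FALSE)
  d$group <- ifelse(d[[col]], "BV", "non-BV")
  if (length(unique(d$group)) < 2) {
    stop("empty BV group under the '", bv_definition, "' definition", call. = FALSE)
  }

  n_samples <- dplyr::summarise(
    dplyr::group_by(dplyr::distinct(d, .data$sample, .data$group), .data$group),
    n = dplyr::n(), .groups = "drop"
  )
  taxon_summary <- dplyr::summarise(
    dplyr::group_by(d, .data$group, .data$taxid),
    n_present = sum(.data$count > 0),
    reads = sum(.data$count),
    .groups = "drop_last"
  )
  taxon_summary <- dplyr::mutate(
    taxon_summary,
    read_share = .data$reads / sum(.data$reads)
  )
  taxon_summary <- dplyr::ungroup(taxon_summary)
  taxon_summary <- dplyr::left_join(taxon_summary, n_samples, by = "group")
  taxon_summary <- dplyr::mutate(taxon_summary,
                                 prevalence = .data$n_present / .data$n)
  taxon_summary <- taxon_summary[, c("group", "taxid", "prevalence", "read_share")]

  dom <- dplyr::summarise(
    dplyr::group_by(d, .data$sample, .data$group),
    total = sum(.data$count),
    top = max(.data$count),
    dominant_taxid = sort(.data$taxid[.data$count == max(.data$count)])[1],
    tie = sum(.data$count == max(.data$count)) > 1,
    .groups = "drop"
  )
  dom$dominant_share <- dom$top / dom$total
  if (dominance == "majority") {
    dom$dominant_taxid[dom$dominant_share <= 0.5] <- NA_character_
  }
  dom <- dom[, c("sample", "group", "dominant_taxid", "dominant_share", "tie")]

  cov <- lapply(split(taxon_summary, taxon_summary$group), function(g) {
    g <- dplyr::arrange(g, dplyr::desc(.data$read_share), .data$taxid)
    k <- which(cumsum(g$read_share) >= target_share)[1]
    if (is.na(k)) k <- nrow(g)
    tibble::tibble(group = g$group[1], n_taxa = k,
                   taxa = paste(g$taxid[seq_len(k)], collapse = ";"))
  })
  structure(
    list(
      taxon_summary = taxon_summary,
      dominance = dom,
      coverage = dplyr::bind_rows(cov)
    ),
    class = "community_summary"
  )
}
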