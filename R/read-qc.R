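#' Demultiplex and quality-filter barcoded amplicon reads
#'
#' Applies the four inclusion criteria for raw pyrosequencing reads, in
#' order, recording each discarded read under the first criterion it fails:
#'
#' 1. the read starts with a known barcode;
#' 2. the exact primer sequence follows immediately after the barcode;
#' 3. at least `min_len` nucleotides remain after removing barcode and
#'    primer;
#' 4. the mean per-base Phred quality of the remaining nucleotides is at
#'    least `min_avg_qual`.
#'
#' Barcode and primer are trimmed from retained reads. When `clip = TRUE`
#' (the default) the retained reads are then window-clipped with
#' [quality_clip()] and criterion 3 is re-checked on the clipped length
#' (discards recorded as `"short_after_clip"`). The quality average of
#' criterion 4 is computed after trimming barcode and primer.
#'
#' @param reads tibble from [read_fastq()] (`read_id`, `sequence`,
#'   `quality`).
#' @param barcodes tibble (`sample`, `barcode`); barcodes must be distinct,
#'   of one fixed length, and none may be a prefix of another.
#' @param primer exact primer sequence (non-empty).
#' @param min_len minimum body length (default 200 nt).
#' @param min_avg_qual minimum mean Phred quality (default 35).
#' @param clip apply [quality_clip()] to retained reads.
#' @param window,q_threshold,min_frac clipping parameters, see
#'   [quality_clip()].
#' @return list of class `qc_result`: `reads` (retained reads with `sample`
#'   assignment, trimmed and clipped) and `report` (class `qc_report`:
#'   per-criterion discard counts, retained count, per-sample tallies,
#'   clipped-length histogram, and the per-read `fate` table).
#' @export
demultiplex_and_filter <- function(reads, barcodes, primer,
                                   min_len = 200, min_avg_qual = 35,
                                   clip = TRUE, window = 30,
                                   q_threshold = 15, min_frac = 0.9) {
  if (!nzchar(primer)) stop("`primer` must be non-empty", call. = FALSE)
  bc <- barcodes$barcode
  if (anyDuplicated(bc)) stop("duplicate barcodes", call. = FALSE)
  if (length(unique(nchar(bc))) != 1) {
    stop("ambiguous barcodes: lengths differ (one barcode would be a prefix of another)",
         call. = FALSE)
  }
  bclen <- nchar(bc[1])
  plen <- nchar(primer)

  fate <- rep("retained", nrow(reads))
  sample_of <- barcodes$sample[match(substr(reads$sequence, 1, bclen), bc)]
  fate[is.na(sample_of)] <- "unknown_barcode"

  ok <- fate == "retained"
  has_primer <- substr(reads$sequence, bclen + 1L, bclen + plen) == primer
  fate[ok & !has_primer] <- "primer_mismatch"

  ok <- fate == "retained"
  body_len <- nchar(reads$sequence) - bclen - plen
  fate[ok & body_len < min_len] <- "too_short"

  ok <- fate == "retained"
  body_seq <- substr(reads$sequence, bclen + plen + 1L, nchar(reads$sequence))
  body_qual <- substr(reads$quality, bclen + plen + 1L, nchar(reads$quality))
  mean_q <- rep(NA_real_, nrow(reads))
  mean_q[ok] <- vapply(body_qual[ok], function(q) mean(phred_scores(q)), numeric(1))
  fate[ok & mean_q < min_avg_qual] <- "low_quality"

  out <- tibble::tibble(
    read_id = reads$read_id,
    sample = sample_of,
    sequence = body_seq,
    quality = body_qual
  )[fate == "retained", ]

  clip_lengths <- integer(0)
  if (clip && nrow(out) > 0) {
    clipped <- purrr::map2(out$sequence, out$quality, quality_clip,
                           window = window, q_threshold = q_threshold,
                           min_frac = min_frac)
    out$sequence <- purrr::map_chr(clipped, "sequence")
    out$quality <- purrr::map_chr(clipped, "quality")
    too_short <- nchar(out$sequence) < min_len
    fate[which(fate == "retained")[too_short]] <- "short_after_clip"
    clip_lengths <- nchar(out$sequence[!too_short])
    out <- out[!too_short, ]
  } else if (nrow(out) > 0) {
    clip_lengths <- nchar(out$sequence)
  }

  criteria <- c("unknown_barcode", "primer_mismatch", "too_short",
                "low_quality", "short_after_clip")
  report <- structure(
    list(
      n_input = nrow(reads),
      n_retained = nrow(out),
      discards = tibble::tibble(
        criterion = criteria,
        n = vapply(criteria, function(cr) sum(fate == cr), integer(1))
      ),
      per_sample = dplyr::count(out, .data$sample, name = "reads"),
      clip_length_histogram = if (length(clip_lengths)) table(clip_lengths) else table(integer(0)),
      fate = tibble::tibble(read_id = reads$read_id, sample = sample_of, fate = fate)
    ),
    class = "qc_report"
  )
  structure(list(reads = out, report = report), class = "qc_result")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Read QC report\n")
  cat(sprintf("  input reads:    %d\n", x$n_input))
  cat(sprintf("  retained reads: %d (%.1f%%)\n", x$n_retained,
              100 * x$n_retained / max(1, x$n_input)))
  cat("  discards by first failing criterion:\n")
  for (i in seq_len(nrow(x$discards))) {
    cat(sprintf("    %-16s %d\n", x$discards$criterion[i], x$discards$n[i]))
  }
  invisible(x)
}

#' Clip a read to its longest high-quality span
#'
#' Returns the longest contiguous span of the read in which every
#' length-`window` sub-window contains at least `min_frac` bases with
#' Phred quality strictly greater than `q_threshold`. Spans shorter than
#' `window` are evaluated as a single window (the fraction is taken over
#' the whole span). Ties between equally long spans go to the leftmost.
#'
#' @param sequence,quality a read and its quality string (equal lengths).
#' @param window window size in bases (default 30).
#' @param q_threshold Phred threshold; bases must exceed it (default 15).
#' @param min_frac minimum fraction of above-threshold bases per window
#'   (default 0.9).
#' @return list with `sequence`, `quality` (the clipped span; empty strings
#'   when no valid span exists), `start`, `end` (1-based coordinates in the
#'   input; 0 when empty).
#' @export
quality_clip <- function(sequence, quality, window = 30, q_threshold = 15,
                         min_frac = 0.9) {
  L <- nchar(sequence)
  if (L != nchar(quality)) {
    stop("`sequence` and `quality` must have the same length", call. = FALSE)
  }
  if (L == 0) return(list(sequence = "", quality = "", start = 0L, end = 0L))
  good <- as.integer(phred_scores(quality) > q_threshold)
  cs <- c(0L, cumsum(good))
  span_ok_short <- function(i, j) (cs[j + 1L] - cs[i]) >= min_frac * (j - i + 1L)

  best <- c(0L, -1L) # start, end
  if (L >= window) {
    # a span of length >= window is valid iff every window position inside
    # it is valid; maximal runs of valid window positions give the spans
    wsum <- cs[(window + 1L):(L + 1L)] - cs[1:(L - window + 1L)]
    valid <- wsum >= min_frac * window
    r <- rle(valid)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    if (length(runs)) {
      span_len <- r$lengths[runs] + window - 1L
      k <- runs[which.max(span_len)] # which.max takes the leftmost tie
      best <- c(starts[k], ends[k] + window - 1L)
    }
  }
  if (best[2] < best[1]) {
    # no valid long span: search short spans (length < window), longest
    # first, leftmost tie
    maxlen <- min(L, window - 1L)
    for (len in rev(seq_len(maxlen))) {
      for (i in seq_len(L - len + 1L)) {
        if (span_ok_short(i, i + len - 1L)) {
          best <- c(i, i + len - 1L)
          break
        }
      }
      if (best[2] >= best[1]) break
    }
  }
  if (best[2] < best[1]) {
    return(list(sequence = "", quality = "", start = 0L, end = 0L))
  }
  list(
    sequence = substr(sequence, best[1], best[2]),
    quality = substr(quality, best[1], best[2]),
    start = as.integer(best[1]), end = as.integer(best[2])
  )
}
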