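#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ file (Sanger Phred+33 qualities).
#' @return tibble with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble::tibble(
    read_id = sub("\\s.*$", "", names(x)),
    sequence = unname(as.character(x)),
    quality = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}

#' Write a tibble of reads as FASTQ
#'
#' @param reads tibble with columns `read_id`, `sequence`, `quality`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality)
  )
  invisible(path)
}

#' Read / write aligned FASTA
#'
#' @param path FASTA file.
#' @return `read_fasta()`: tibble with `seq_id`, `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  tibble::tibble(seq_id = sub("\\s.*$", "", names(x)), sequence = as.character(x))
}

#' @rdname read_fasta
#' @param sequences tibble with `seq_id`, `sequence`.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::BStringSet(sequences$sequence)
  names(x) <- sequences$seq_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# Phred scores of a Sanger-encoded quality string (integer vector).
phred_scores <- function(quality) {
  utf8ToInt(quality) - 33L
}
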