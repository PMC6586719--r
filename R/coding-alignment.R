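#' Coding-sequence alignment container
#'
#' A `CodingAlignment` holds equal-length gapped nucleotide sequences
#' (alphabet `A C G T - N`) for two or more samples, the substrate for all
#' diversity statistics. Protein domains (e.g. the Aux/IAA Domains I-IV) may
#' be declared as named intervals in alignment coordinates, 1-based inclusive.
#'
#' @param sequences character vector of aligned sequences (equal length).
#' @param sample_ids sample labels; defaults to names of `sequences`.
#' @param frame_offset bases to skip before the first complete codon
#'   (0 unless stated).
#' @param domains optional `data.frame` with columns `name`, `start`, `end`
#'   (alignment coordinates, 1-based inclusive).
#' @return an object of class `CodingAlignment`.
#' @examples
#' aln <- coding_alignment(c(a = "ATGAAA", b = "ATGAAG"))
#' nucleotide_diversity(aln)
#' @export
coding_alignment <- function(sequences, sample_ids = names(sequences),
                             frame_offset = 0L, domains = NULL) {
  force(sample_ids) # capture names before they are stripped below
  sequences <- vapply(sequences, clean_seq, character(1), USE.NAMES = FALSE)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_along(sequences))
  if (length(sample_ids) != length(sequences))
    ck_stop("sample_ids and sequences differ in length", "bad_input")
  len <- unique(nchar(sequences))
  if (length(len) != 1L)
    ck_stop("aligned sequences must all have the same length", "length_mismatch")
  bad <- grepl("[^ACGTN-]", sequences)
  if (any(bad))
    ck_stop(sprintf("sequence %s contains characters outside {A,C,G,T,-,N}",
                    sample_ids[which(bad)[1]]), "bad_alphabet")
  if (!is.null(domains)) {
    domains <- as.data.frame(domains)
    stopifnot(all(c("name", "start", "end") %in% names(domains)))
    if (any(domains$start < 1L | domains$end > len | domains$start > domains$end))
      ck_stop("domain interval outside [1, alignment length]", "bad_domain")
  }
  structure(list(sample_ids = as.character(sample_ids),
                 sequences = sequences,
                 frame_offset = as.integer(frame_offset),
                 domains = domains),
            class = "CodingAlignment")
}

#' @export
print.CodingAlignment <- function(x, ...) {
  cat(sprintf("CodingAlignment: %d samples x %d sites", length(x$sequences),
              nchar(x$sequences[1])))
  if (!is.null(x$domains))
    cat(sprintf(", %d domains (%s)", nrow(x$domains),
                paste(x$domains$name, collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' @export
length.CodingAlignment <- function(x) length(x$sequences)

#' Read an aligned FASTA file into a CodingAlignment
#'
#' Gaps must be `-`. An optional 3-column delimited sidecar (`name`, `start`,
#' `end`; 1-based inclusive, no header required) declares domain intervals.
#'
#' @param fasta path to an aligned FASTA file.
#' @param domains_file optional path to the domain sidecar (TSV).
#' @inheritParams coding_alignment
#' @return a `CodingAlignment`.
#' @export
read_coding_alignment <- function(fasta, domains_file = NULL, frame_offset = 0L) {
  ss <- Biostrings::readBStringSet(fasta)
  domains <- if (!is.null(domains_file)) read_domains(domains_file)
  coding_alignment(as.character(ss), sample_ids = names(ss),
                   frame_offset = frame_offset, domains = domains)
}

read_domains <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("name", "start", "end"),
                         stringsAsFactors = FALSE)
  # tolerate a header row
  if (is.na(suppressWarnings(as.integer(d$start[1])))) d <- d[-1, , drop = FALSE]
  d$start <- as.integer(d$start); d$end <- as.integer(d$end)
  d
}

#' Write a CodingAlignment as aligned FASTA
#'
#' @param aln a `CodingAlignment`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_coding_alignment <- function(aln, path) {
  ss <- Biostrings::BStringSet(aln$sequences)
  names(ss) <- aln$sample_ids
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# subset alignment columns (1-based inclusive), keeping sample ids
subset_alignment <- function(aln, start, end) {
  seqs <- substr(aln$sequences, start, end)
  coding_alignment(seqs, aln$sample_ids, frame_offset = 0L)
}
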