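# Shared helpers: classed conditions, sequence utilities, coordinate
# conventions. Files are 1-based inclusive; internal interval arithmetic is
# 0-based half-open only inside the converters below.

ck_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("crisprkit_", class), "crisprkit_error")))
}

ck_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(paste0("crisprkit_", class), "crisprkit_warning")))
}

#' @keywords internal
clean_seq <- function(x, strip_gaps = FALSE) {
  x <- toupper(gsub("[[:space:]*]", "", x))
  if (strip_gaps) x <- gsub("-", "", x, fixed = TRUE)
  x
}

# character matrix (samples x sites) from a vector of equal-length strings
seq_matrix <- function(seqs) {
  if (length(unique(nchar(seqs))) != 1L)
    ck_stop("sequences have unequal lengths", "length_mismatch")
  do.call(rbind, strsplit(seqs, "", fixed = TRUE))
}

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

is_base <- function(x) x %in% c("A", "C", "G", "T")

# 1-based inclusive <-> 0-based half-open
to_internal <- function(start1, end1) cbind(start = start1 - 1L, end = end1)
to_file <- function(start0, end0) cbind(start = start0 + 1L, end = end0)

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
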