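#' Extract splice junctions from spliced alignments
#'
#' Reads SAM records and reports one junction per distinct skipped
#' reference interval (CIGAR N operation), with supporting-read counts
#' aggregated per sample. `intron_start`/`intron_end` are the first and
#' last skipped (intronic) bases, 1-based inclusive. Records without a skip
#' contribute nothing; results are invariant to read order and to
#' splitting one input file into several.
#'
#' @param sam_files character vector of SAM paths; names are sample labels
#'   (unnamed files are labelled by file name). Several files may share a
#'   label; their counts are summed.
#' @return `data.frame` with `chrom`, `intron_start`, `intron_end`,
#'   `strand`, `sample`, `count`, sorted by position then sample.
#' @export
extract_junctions <- function(sam_files) {
  labels <- names(sam_files)
  if (is.null(labels)) labels <- rep("", length(sam_files))
  labels[labels == ""] <- tools::file_path_sans_ext(basename(sam_files[labels == ""]))
  rows <- list()
  for (i in seq_along(sam_files)) {
    bam <- Rsamtools::asBam(sam_files[i],
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
    gal <- GenomicAlignments::readGAlignments(bam)
    j <- unlist(GenomicAlignments::junctions(gal))
    if (!length(j)) next
    rows[[length(rows) + 1]] <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(j)),
      intron_start = GenomicRanges::start(j),
      intron_end = GenomicRanges::end(j),
      strand = "?",
      sample = labels[i],
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(chrom = character(0), intron_start = integer(0),
                      intron_end = integer(0), strand = character(0),
                      sample = character(0), count = integer(0)))
  df <- do.call(rbind, rows)
  agg <- stats::aggregate(list(count = rep(1L, nrow(df))),
                          df[c("chrom", "intron_start", "intron_end",
                               "strand", "sample")], sum)
  agg <- agg[order(agg$chrom, agg$intron_start, agg$intron_end, agg$sample), ]
  rownames(agg) <- NULL
  agg
}

#' Read a 6-column junction BED into the junction table format
#'
#' BED is 0-based half-open; `start` is converted to the first intronic
#' base (1-based) and `end` to the last.
#'
#' @param path BED6 file (`chrom`, `start`, `end`, `name`, `count`,
#'   `strand`); `name` is used as the sample label.
#' @return junction `data.frame` as from [extract_junctions()].
#' @export
read_junction_bed <- function(path) {
  b <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "name",
                                       "count", "strand"),
                         stringsAsFactors = FALSE)
  data.frame(chrom = b$chrom, intron_start = b$start + 1L, intron_end = b$end,
             strand = b$strand, sample = b$name, count = b$count,
             stringsAsFactors = FALSE)
}

#' Flag junctions as annotated or novel against a gene model
#'
#' @param junctions junction table from [extract_junctions()].
#' @param model a [gene_model()]; a junction is `annotated` when it matches
#'   an intron of any isoform exactly.
#' @return the table with a `status` column added.
#' @export
junction_status <- function(junctions, model) {
  ann <- do.call(rbind, lapply(names(model$isoforms),
                               function(n) introns_of(model, n)))
  key <- paste(junctions$intron_start, junctions$intron_end)
  akey <- paste(ann$start, ann$end)
  junctions$status <- ifelse(junctions$chrom == model$chrom & key %in% akey,
                             "annotated", "novel")
  junctions
}

#' Junction usage proportions at a locus
#'
#' For one sample, the proportion of junction-supporting reads carried by
#' each junction overlapping the locus interval; proportions sum to 1 when
#' coverage is nonzero.
#'
#' @param junctions junction table (see [extract_junctions()]).
#' @param chrom chromosome of the locus.
#' @param locus `c(start, end)`, 1-based inclusive; typically the annotated
#'   intron interval.
#' @param sample sample label.
#' @param target optional `c(intron_start, intron_end)` of one junction;
#'   when given, that junction's proportion (a single number, `NA` if the
#'   denominator is zero) is returned instead of the full table.
#' @return `data.frame` of overlapping junctions with a `proportion`
#'   column, or a single proportion when `target` is given.
#' @export
junction_proportion <- function(junctions, chrom, locus, sample, target = NULL) {
  sel <- junctions$chrom == chrom & junctions$sample == sample &
    junctions$intron_start <= locus[2] & junctions$intron_end >= locus[1]
  df <- junctions[sel, , drop = FALSE]
  tot <- sum(df$count)
  if (!is.null(target)) {
    if (tot == 0) return(NA_real_)
    hit <- df$intron_start == target[1] & df$intron_end == target[2]
    return(sum(df$count[hit]) / tot)
  }
  df$proportion <- if (tot > 0) df$count / tot else NA_real_
  rownames(df) <- NULL
  df
}

#' Fold change between two junction proportions
#'
#' @param p_case proportion in the case (e.g. mutant) sample.
#' @param p_control proportion in the control sample.
#' @return `p_case / p_control`; `Inf` when the control proportion is 0.
#' @export
proportion_fold_change <- function(p_case, p_control) {
  if (any(p_case < 0 | p_case > 1, na.rm = TRUE) ||
      any(p_control < 0 | p_control > 1, na.rm = TRUE))
    ck_stop("proportions must lie in [0, 1]", "bad_input")
  ifelse(p_control == 0, Inf, p_case / p_control)
}

#' Write a junction table as TSV
#'
#' @param junctions junction table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_junction_table <- function(junctions, path) {
  utils::write.table(junctions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
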