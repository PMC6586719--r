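#' Read a Ct table
#'
#' Delimited text with columns `sample`, `gene`, `replicate`, `ct`
#' (case-insensitive header).
#'
#' @param path TSV path.
#' @return `data.frame` with those four columns.
#' @export
read_ct_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  need <- c("sample", "gene", "replicate", "ct")
  if (!all(need %in% names(d)))
    ck_stop("Ct table needs columns sample, gene, replicate, ct", "bad_input")
  d[need]
}

mean_ct <- function(table, sample, gene) {
  v <- table$ct[table$sample == sample & table$gene == gene]
  if (!length(v))
    ck_stop(sprintf("no Ct values for sample '%s', gene '%s'", sample, gene),
            "missing_ct")
  mean(v)
}

#' Relative expression by the 2^-ddCt method
#'
#' Replicate Ct values are averaged (arithmetic mean) per sample and gene;
#' the target gene is normalised to the reference gene within each sample
#' (dCt) and then to the calibrator sample (ddCt); relative expression is
#' `2^-ddCt`, so the calibrator itself scores 1.
#'
#' @param table Ct `data.frame` (see [read_ct_table()]).
#' @param target_gene gene of interest.
#' @param sample sample to quantify; defaults to every sample in the table.
#' @param reference_gene internal-control gene (e.g. `G3PDH`).
#' @param calibrator calibrator sample (e.g. the wild type).
#' @return `data.frame` with `sample`, `dct`, `ddct`, `rel_expr`.
#' @export
delta_delta_ct <- function(table, target_gene, sample = NULL,
                           reference_gene = "G3PDH", calibrator) {
  if (is.null(sample)) sample <- unique(table$sample)
  dct_cal <- mean_ct(table, calibrator, target_gene) -
    mean_ct(table, calibrator, reference_gene)
  out <- lapply(sample, function(s) {
    dct <- mean_ct(table, s, target_gene) - mean_ct(table, s, reference_gene)
    ddct <- dct - dct_cal
    data.frame(sample = s, dct = dct, ddct = ddct, rel_expr = 2^(-ddct),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
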