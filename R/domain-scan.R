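# Per-region summary of all diversity statistics (whole CDS + each declared
# domain), the table the gene-family survey reports.

# mean pairwise Nei-Gojobori over all sample pairs of an in-frame alignment
# (codon pairs with gaps/N dropped pairwise inside nei_gojobori)
mean_pairwise_ng <- function(aln) {
  n <- length(aln$sequences)
  kas <- c(); kss <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ng <- tryCatch(nei_gojobori(aln$sequences[i], aln$sequences[j]),
                   crisprkit_error = function(e) NULL)
    if (!is.null(ng)) { kas <- c(kas, ng$ka); kss <- c(kss, ng$ks) }
  }
  if (!length(kas)) return(list(ka = NA_real_, ks = NA_real_, ka_ks = NA_real_))
  ka <- mean(kas, na.rm = TRUE); ks <- mean(kss, na.rm = TRUE)
  list(ka = ka, ks = ks,
       ka_ks = if (is.finite(ks) && ks > 0 && is.finite(ka)) ka / ks else NA_real_)
}

# trim an alignment interval to whole codons given the alignment-wide frame
codon_trim <- function(start, end, frame_offset) {
  first <- frame_offset + 1L
  s <- start + ((first - start) %% 3 + 3L) %% 3L
  e <- end - ((end - frame_offset) %% 3 + 3L) %% 3L
  if (e - s + 1L < 3L) return(NULL)
  c(s, e)
}

region_summary <- function(aln, region_name, start, end, frame_offset) {
  sub <- subset_alignment(aln, start, end)
  n <- length(sub$sequences)
  S <- segregating_sites(sub)
  pi_raw <- nucleotide_diversity(sub)
  pi_jc <- tryCatch(nucleotide_diversity(sub, corrected = TRUE),
                    crisprkit_saturation = function(e) NA_real_)
  td <- if (n >= 4) tajimas_d(sub) else NA_real_
  cw <- codon_trim(start, end, frame_offset)
  ng <- if (is.null(cw)) list(ka = NA_real_, ks = NA_real_, ka_ks = NA_real_)
        else mean_pairwise_ng(subset_alignment(aln, cw[1], cw[2]))
  data.frame(region_name = region_name, n = n, S = S,
             pi_raw = pi_raw, pi_jc = pi_jc,
             theta_w = theta_watterson(S, n),
             ka = ng$ka, ks = ng$ks, ka_ks = ng$ka_ks,
             tajima_d = td, stringsAsFactors = FALSE)
}

#' Per-domain population-genetics summary
#'
#' Computes, for the whole CDS and each declared domain, the segregating
#' site count, raw and Jukes-Cantor corrected nucleotide diversity,
#' Watterson's estimator, mean pairwise Nei-Gojobori Ka, Ks and Ka/Ks, and
#' Tajima's D. The whole-CDS row always comes first. Ka/Ks for a domain is
#' computed on the domain interval trimmed to whole codons of the
#' alignment-wide reading frame.
#'
#' @param aln a [coding_alignment()]; declared domains (if any) yield one
#'   row each after the CDS row.
#' @param permille report diversities per thousand sites instead of per site.
#' @return `data.frame` with one row per region.
#' @export
domain_scan <- function(aln, permille = FALSE) {
  len <- nchar(aln$sequences[1])
  out <- region_summary(aln, "CDS", 1L, len, aln$frame_offset)
  if (!is.null(aln$domains)) {
    for (i in seq_len(nrow(aln$domains))) {
      d <- aln$domains[i, ]
      out <- rbind(out, region_summary(aln, d$name, d$start, d$end, aln$frame_offset))
    }
  }
  if (permille) {
    out$pi_raw <- out$pi_raw * 1000
    out$pi_jc <- out$pi_jc * 1000
  }
  rownames(out) <- NULL
  out
}

#' Write a region summary table as TSV
#'
#' @param summary a `data.frame` from [domain_scan()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_popgen_summary <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
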