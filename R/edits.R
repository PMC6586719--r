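#' Edit event constructor
#'
#' A normalized insertion/deletion/substitution at a genomic coordinate.
#' `pos` is 1-based: for a deletion or substitution it is the first replaced
#' base; for a pure insertion the inserted bases sit immediately before the
#' base originally at `pos`.
#'
#' @param chrom chromosome label.
#' @param pos 1-based coordinate (leftmost-normalized).
#' @param ref_allele replaced bases (may be `""` for a pure insertion).
#' @param alt_allele inserted bases (may be `""` for a pure deletion).
#' @param kind one of `insertion`, `deletion`, `substitution`, `complex`;
#'   inferred from the alleles when omitted.
#' @return an object of class `EditEvent`.
#' @export
edit_event <- function(chrom, pos, ref_allele, alt_allele, kind = NULL) {
  ref_allele <- clean_seq(ref_allele); alt_allele <- clean_seq(alt_allele)
  if (!nchar(ref_allele) && !nchar(alt_allele))
    ck_stop("ref and alt alleles cannot both be empty", "bad_edit")
  if (is.null(kind)) {
    kind <- if (!nchar(alt_allele)) "deletion"
            else if (!nchar(ref_allele)) "insertion"
            else if (nchar(ref_allele) == nchar(alt_allele)) "substitution"
            else "complex"
  }
  structure(list(chrom = chrom, pos = as.integer(pos),
                 ref_allele = ref_allele, alt_allele = alt_allele, kind = kind),
            class = "EditEvent")
}

#' @export
print.EditEvent <- function(x, ...) {
  cat(sprintf("EditEvent: %s %s:%d %s>%s (len %+d)\n", x$kind, x$chrom, x$pos,
              if (nchar(x$ref_allele)) x$ref_allele else ".",
              if (nchar(x$alt_allele)) x$alt_allele else ".",
              nchar(x$alt_allele) - nchar(x$ref_allele)))
  invisible(x)
}

#' Infer a CRISPR-induced edit from a wild-type/mutant sequence pair
#'
#' Finds the single leftmost-normalized edit block transforming the
#' wild-type target region into the mutant one. Normalization follows the
#' VCF convention: when an indel can be placed at several equivalent
#' positions, the leftmost placement is reported (achieved by claiming the
#' longest common suffix first). Gap characters are stripped before
#' comparison, so alleles can be pasted as printed in a genotyping table.
#'
#' @param wt_region wild-type target-region sequence.
#' @param mut_region mutant target-region sequence.
#' @param chrom chromosome label for the resulting event.
#' @param region_start genomic coordinate of the first base of `wt_region`.
#' @return an [edit_event()]; positions are genomic when `region_start` is
#'   supplied, else relative to the region.
#' @export
infer_edit <- function(wt_region, mut_region, chrom = "region", region_start = 1L) {
  wt <- clean_seq(wt_region, strip_gaps = TRUE)
  mut <- clean_seq(mut_region, strip_gaps = TRUE)
  if (!nchar(wt) || !nchar(mut)) ck_stop("empty input sequence", "bad_input")
  if (wt == mut) ck_stop("sequences are identical: no edit to infer", "no_edit")
  lw <- nchar(wt); lm <- nchar(mut)
  wv <- strsplit(wt, "")[[1]]; mv <- strsplit(mut, "")[[1]]
  # longest common suffix first (=> leftmost placement), then prefix
  lcs <- 0
  while (lcs < min(lw, lm) && wv[lw - lcs] == mv[lm - lcs]) lcs <- lcs + 1
  lcp <- 0
  while (lcp < min(lw, lm) - lcs && wv[lcp + 1] == mv[lcp + 1]) lcp <- lcp + 1
  ref <- substr(wt, lcp + 1, lw - lcs)
  alt <- substr(mut, lcp + 1, lm - lcs)
  edit_event(chrom, region_start + lcp, ref, alt)
}

# map a genomic coordinate through an edit (edited-genome coordinates);
# deleted positions collapse leftward onto pos - 1
map_through_edit <- function(x, edit) {
  p <- edit$pos; r <- nchar(edit$ref_allele); a <- nchar(edit$alt_allele)
  delta <- a - r
  ifelse(x < p, x,
         ifelse(x >= p + r, x + delta, pmin(x, p + a - 1L)))
}

#' Apply an edit to a gene model and its genome sequence
#'
#' Rewrites the chromosome sequence, shifts all downstream model
#' coordinates by the edit's length change, and returns the wild-type and
#' edited spliced CDS. Splice sites outside the edit are untouched. An edit
#' spanning an exon/intron boundary is still applied but flagged.
#'
#' @param model a [gene_model()].
#' @param genome_seq chromosome sequence (string, position 1 = base 1).
#' @param edit an [edit_event()] on the model's chromosome.
#' @param isoform isoform used for the CDS (default first).
#' @return list with `genome` (edited sequence), `model` (remapped
#'   [gene_model()]), `cds_wt`, `cds_mut`, `overlap` (`"cds"`, `"exon"` or
#'   `"none"`) and `boundary_warning` flag.
#' @export
apply_edit <- function(model, genome_seq, edit, isoform = 1L) {
  if (!identical(edit$chrom, model$chrom) && edit$chrom != "region")
    ck_stop("edit is on a different chromosome than the model", "bad_edit")
  p <- edit$pos; r <- nchar(edit$ref_allele); a <- nchar(edit$alt_allele)
  if (p + r - 1L > nchar(genome_seq))
    ck_stop("edit extends beyond the supplied genome sequence", "bad_edit")
  if (r > 0 && substr(genome_seq, p, p + r - 1L) != edit$ref_allele)
    ck_stop("ref allele does not match the genome sequence", "ref_mismatch")
  genome2 <- paste0(substr(genome_seq, 1, p - 1L), edit$alt_allele,
                    substr(genome_seq, p + r, nchar(genome_seq)))
  span <- if (r > 0) c(p, p + r - 1L) else c(p, p - 1L) # insertion: point before p
  touches <- function(s, e) r > 0 && span[1] <= e && span[2] >= s
  inside <- function(s, e) if (r > 0) span[1] >= s && span[2] <= e else p > s && p <= e
  overlap <- "none"; boundary <- FALSE
  isos <- model$isoforms
  for (nm in names(isos)) {
    iso <- isos[[nm]]
    for (i in seq_len(nrow(iso$exons))) {
      s <- iso$exons$start[i]; e <- iso$exons$end[i]
      if (inside(s, e)) {
        cex <- exon_cds_intersections(iso)
        in_cds <- any(if (r > 0) span[1] >= cex$start & span[2] <= cex$end
                      else p > cex$start & p <= cex$end)
        overlap <- if (in_cds) "cds" else if (overlap == "none") "exon" else overlap
      } else if (touches(s, e)) {
        boundary <- TRUE
        overlap <- if (overlap == "none") "exon" else overlap
      }
    }
    isos[[nm]]$exons$start <- map_through_edit(iso$exons$start, edit)
    isos[[nm]]$exons$end <- map_through_edit(iso$exons$end, edit)
    isos[[nm]]$cds_start <- map_through_edit(iso$cds_start, edit)
    isos[[nm]]$cds_end <- map_through_edit(iso$cds_end, edit)
  }
  if (boundary) ck_warn("edit spans an exon/intron boundary", "boundary_overlap")
  model2 <- gene_model(model$gene_id, model$chrom, model$strand, isos)
  list(genome = genome2, model = model2,
       cds_wt = spliced_cds(model, genome_seq, isoform),
       cds_mut = spliced_cds(model2, genome2, isoform),
       overlap = overlap, boundary_warning = boundary)
}

#' Translate a coding sequence
#'
#' Standard genetic code; translation stops at the first stop codon. Codons
#' containing N (or a gap) become `X`. A trailing partial codon is ignored
#' with a warning.
#'
#' @param cds nucleotide string, length >= 3.
#' @return protein string, with attributes `stopped` (a stop codon was
#'   reached) and `partial` (a trailing partial codon was dropped).
#' @export
translate_cds <- function(cds) {
  cds <- clean_seq(cds, strip_gaps = TRUE)
  if (nchar(cds) < 3) ck_stop("coding sequence shorter than one codon", "bad_input")
  partial <- nchar(cds) %% 3 != 0
  if (partial) {
    ck_warn("trailing partial codon ignored", "partial_codon")
    cds <- substr(cds, 1, nchar(cds) - nchar(cds) %% 3)
  }
  codons <- split_codons(cds)
  aa <- ifelse(grepl("[^ACGT]", codons), "X", unname(GC[codons]))
  stop_at <- which(aa == "*")
  stopped <- length(stop_at) > 0
  if (stopped) aa <- aa[seq_len(stop_at[1] - 1)]
  structure(paste(aa, collapse = ""), stopped = stopped, partial = partial)
}

# anchored protein diff: longest common prefix claimed first, then suffix
protein_diff <- function(wt, mut) {
  lw <- nchar(wt); lm <- nchar(mut)
  wv <- strsplit(wt, "")[[1]]; mv <- strsplit(mut, "")[[1]]
  lcp <- 0L
  while (lcp < min(lw, lm) && wv[lcp + 1] == mv[lcp + 1]) lcp <- lcp + 1L
  lcs <- 0L
  while (lcs < min(lw, lm) - lcp && wv[lw - lcs] == mv[lm - lcs]) lcs <- lcs + 1L
  list(lcp = lcp, lcs = lcs, removed = lw - lcp - lcs, inserted = lm - lcp - lcs)
}

#' Classify the protein consequence of an edit
#'
#' Compares the wild-type and edited CDS at the protein level with an
#' anchored diff (longest common prefix claimed first). A CDS length change
#' not divisible by 3 is a frameshift; domains are reported lost when fewer
#' than half of their wild-type residues survive in the mutant protein.
#'
#' @param wt_cds,mut_cds coding sequences starting with ATG.
#' @param domains optional `data.frame` with `name`, `start`, `end` in
#'   wild-type protein coordinates (1-based inclusive).
#' @return object of class `ConsequenceReport`: list with `kind`
#'   (`in_frame_deletion`, `in_frame_insertion`, `frameshift`, `synonymous`,
#'   `missense`, `start_lost` or `no_change`), `aa_removed`, `aa_inserted`,
#'   `premature_stop_at` (codon index of a new stop, or `NA`) and
#'   `domains_lost`.
#' @export
classify_consequence <- function(wt_cds, mut_cds, domains = NULL) {
  wt_cds <- clean_seq(wt_cds, strip_gaps = TRUE)
  mut_cds <- clean_seq(mut_cds, strip_gaps = TRUE)
  if (substr(wt_cds, 1, 3) != "ATG")
    ck_stop("wild-type CDS does not start with ATG", "bad_input")
  if (substr(mut_cds, 1, 3) != "ATG")
    return(consequence_report("start_lost", 0L, 0L, NA_integer_, character(0)))
  pw <- suppressWarnings(translate_cds(wt_cds))
  pm <- suppressWarnings(translate_cds(mut_cds))
  delta <- nchar(mut_cds) - nchar(wt_cds)
  d <- protein_diff(as.character(pw), as.character(pm))
  # a stop is premature when it truncates the mutant CDS itself (i.e. it is
  # not the final codon); an in-frame deletion shortens the protein but
  # still terminates at its own last codon
  mut_stop <- nchar(pm) + 1L
  premature <- if (isTRUE(attr(pm, "stopped")) && mut_stop < nchar(mut_cds) %/% 3L)
    mut_stop else NA_integer_
  kind <- if (wt_cds == mut_cds) "no_change"
          else if (delta %% 3 != 0) "frameshift"
          else if (delta < 0) "in_frame_deletion"
          else if (delta > 0) "in_frame_insertion"
          else if (as.character(pw) == as.character(pm)) "synonymous"
          else "missense"
  lost <- character(0)
  if (!is.null(domains) && nrow(domains)) {
    surviving <- function(s, e) {
      idx <- s:e
      sum(idx <= d$lcp | idx > nchar(pw) - d$lcs) / length(idx)
    }
    frac <- mapply(surviving, domains$start, domains$end)
    lost <- domains$name[frac < 0.5]
  }
  consequence_report(kind, d$removed, d$inserted, premature, lost)
}

consequence_report <- function(kind, aa_removed, aa_inserted, premature_stop_at,
                               domains_lost) {
  structure(list(kind = kind, aa_removed = aa_removed, aa_inserted = aa_inserted,
                 premature_stop_at = premature_stop_at, domains_lost = domains_lost),
            class = "ConsequenceReport")
}

#' @export
print.ConsequenceReport <- function(x, ...) {
  cat(sprintf("ConsequenceReport: %s (-%d aa, +%d aa)", x$kind, x$aa_removed,
              x$aa_inserted))
  if (!is.na(x$premature_stop_at))
    cat(sprintf(", premature stop at codon %d", x$premature_stop_at))
  if (length(x$domains_lost))
    cat(sprintf(", domains lost: %s", paste(x$domains_lost, collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Editing rate from screening counts
#'
#' @param mutants number of plants carrying an edit at the target.
#' @param identified number of PCR-identified positive transgenic plants.
#' @return percentage, `100 * mutants / identified`.
#' @export
editing_rate <- function(mutants, identified) {
  if (any(identified <= 0)) ck_stop("identified count must be positive", "bad_input")
  100 * mutants / identified
}

#' Write edit events as a minimal VCF
#'
#' Pure insertions/deletions are emitted with the VCF anchor-base
#' convention (the base before the event is prepended to both alleles).
#'
#' @param edits list of [edit_event()] objects.
#' @param genome_seq chromosome sequence used for anchor bases.
#' @param path output path.
#' @param sample sample label for the single genotype column.
#' @return `path`, invisibly.
#' @export
write_edits_vcf <- function(edits, genome_seq, path, sample = "mutant") {
  lines <- c("##fileformat=VCFv4.2",
             paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                                 "FILTER", "INFO", "FORMAT", sample), collapse = "\t")))
  for (e in edits) {
    if (e$kind %in% c("insertion", "deletion")) {
      anchor_pos <- e$pos - 1L
      anchor <- substr(genome_seq, anchor_pos, anchor_pos)
      ref <- paste0(anchor, e$ref_allele)
      alt <- paste0(anchor, e$alt_allele)
      pos <- anchor_pos
    } else {
      ref <- e$ref_allele; alt <- e$alt_allele; pos <- e$pos
    }
    lines <- c(lines, paste(e$chrom, pos, ".", ref, alt, ".", "PASS", ".",
                            "GT", "1/1", sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
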