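#' Enumerate frame-restoring alternative donor junctions
#'
#' After a coding indel upstream of an intron, an alternative 5' donor that
#' shifts the junction `s` bases into the exon removes `s` exonic bases;
#' the reading frame downstream is restored exactly when the edit's length
#' change minus the shift is divisible by 3. Each shift in `1..max_shift`
#' is reported with its net frame class. When the genomic sequence is
#' supplied, `restores_frame` additionally requires the shifted intron to
#' retain GT..AG boundaries and the resulting CDS to reach the annotated
#' stop without a premature one; without it, candidates are arithmetic-only
#' and flagged `unverified` in `splice_signal`.
#'
#' @param model a [gene_model()].
#' @param edit an [edit_event()] lying in a coding exon that precedes an
#'   intron.
#' @param max_shift largest donor shift considered (bp, >= 1).
#' @param genome_seq optional chromosome sequence.
#' @param isoform isoform to use (default first).
#' @return `data.frame` with `shift`, `insertion_length`, `net_frame`,
#'   `restores_frame`, `splice_signal`, `junction_start`, `junction_end`
#'   and (with genome) `predicted_protein`; sorted by shift. Empty when the
#'   edit is not in an exon followed by an intron.
#' @export
enumerate_rescue_junctions <- function(model, edit, max_shift, genome_seq = NULL,
                                       isoform = 1L) {
  if (max_shift < 1) ck_stop("max_shift must be >= 1", "bad_input")
  iso <- model$isoforms[[isoform]]
  ex <- iso$exons
  ins_len <- nchar(edit$alt_allele) - nchar(edit$ref_allele)
  host <- which(edit$pos >= ex$start & edit$pos <= ex$end)
  empty <- data.frame(shift = integer(0), insertion_length = integer(0),
                      net_frame = integer(0), restores_frame = logical(0),
                      splice_signal = character(0), junction_start = integer(0),
                      junction_end = integer(0))
  if (!length(host) || host[1] >= nrow(ex)) return(empty)
  host <- host[1]
  introns <- introns_of(model, isoform)
  donor <- introns$start[host]          # first intronic base (wild-type coords)
  acceptor <- introns$end[host]
  out <- data.frame(shift = seq_len(max_shift))
  out$insertion_length <- ins_len
  out$net_frame <- ((ins_len - out$shift) %% 3 + 3) %% 3
  out$restores_frame <- out$net_frame == 0
  out$splice_signal <- "unverified"
  out$junction_start <- donor - out$shift
  out$junction_end <- acceptor
  if (!is.null(genome_seq)) {
    ap <- apply_edit(model, genome_seq, edit, isoform)
    model2 <- ap$model; genome2 <- ap$genome
    introns2 <- introns_of(model2, isoform)
    donor2 <- introns2$start[host]; acceptor2 <- introns2$end[host]
    out$predicted_protein <- NA_character_
    for (i in seq_len(nrow(out))) {
      s <- out$shift[i]
      js <- donor2 - s
      gt <- substr(genome2, js, js + 1L) == "GT"
      ag <- substr(genome2, acceptor2 - 1L, acceptor2) == "AG"
      out$splice_signal[i] <- if (gt && ag) "GT-AG" else "invalid"
      if (!gt || !ag) { out$restores_frame[i] <- FALSE; next }
      if (!out$restores_frame[i]) next
      prot <- shifted_junction_protein(model2, genome2, isoform, host, s)
      if (is.null(prot)) out$restores_frame[i] <- FALSE
      else out$predicted_protein[i] <- prot
    }
  }
  rownames(out) <- NULL
  out
}

# protein from splicing with the donor of intron `host` shifted s bases
# into the exon; NULL unless translation reaches the annotated stop with no
# premature one.
shifted_junction_protein <- function(model, genome_seq, isoform, host, s) {
  iso <- model$isoforms[[isoform]]
  iso$exons$end[host] <- iso$exons$end[host] - s
  model2 <- gene_model(model$gene_id, model$chrom, model$strand,
                       stats::setNames(list(iso), "shifted"))
  cds <- spliced_cds(model2, genome_seq, 1L)
  if (nchar(cds) %% 3 != 0) return(NULL)
  prot <- suppressWarnings(translate_cds(cds))
  if (!isTRUE(attr(prot, "stopped"))) return(NULL)
  if (3 * (nchar(prot) + 1L) != nchar(cds)) return(NULL) # premature stop
  as.character(prot)
}

#' Build a mosaic transcript across two isoforms
#'
#' Joins the coding exonic sequence of isoform A 5' of a breakpoint
#' junction to the coding exonic sequence of isoform B 3' of it, and
#' translates the result — the predicted product when a novel junction
#' splices the upstream part of one annotated isoform onto the downstream
#' part of another.
#'
#' @param model a [gene_model()] carrying both isoforms.
#' @param isoform_a,isoform_b isoform names or indices.
#' @param breakpoint `c(start, end)`: the junction's first and last
#'   skipped bases (1-based inclusive).
#' @param genome_seq chromosome sequence.
#' @return list with `transcript` (nucleotide string) and `protein`.
#' @export
build_mosaic_transcript <- function(model, isoform_a, isoform_b, breakpoint,
                                    genome_seq) {
  pos_a <- cds_positions(model, isoform_a)
  pos_b <- cds_positions(model, isoform_b)
  span <- range(c(pos_a, pos_b))
  if (breakpoint[1] > span[2] + 1L || breakpoint[2] < span[1] - 1L)
    ck_stop("breakpoint outside the isoforms' genomic span", "bad_breakpoint")
  if (model$strand == "+") {
    keep_a <- pos_a[pos_a < breakpoint[1]]
    keep_b <- pos_b[pos_b > breakpoint[2]]
  } else {
    keep_a <- rev(pos_a[pos_a > breakpoint[2]])
    keep_b <- rev(pos_b[pos_b < breakpoint[1]])
  }
  bases <- strsplit(genome_seq, "")[[1]][c(keep_a, keep_b)]
  transcript <- paste(bases, collapse = "")
  if (model$strand == "-")
    transcript <- chartr("ACGT", "TGCA", transcript)
  protein <- as.character(suppressWarnings(translate_cds(transcript)))
  list(transcript = transcript, protein = protein)
}

# genomic positions of CDS bases of an isoform, ascending
cds_positions <- function(model, isoform) {
  cex <- exon_cds_intersections(model$isoforms[[isoform]])
  unlist(mapply(seq, cex$start, cex$end, SIMPLIFY = FALSE))
}
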