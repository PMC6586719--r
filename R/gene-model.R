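#' Gene model container
#'
#' A `GeneModel` holds one gene's chromosome, strand, and one or more
#' isoforms, each with sorted non-overlapping exons and a CDS span. All
#' stored coordinates are genomic, 1-based inclusive (the file convention);
#' converters to half-open coordinates are applied internally only.
#'
#' @param gene_id gene label.
#' @param chrom chromosome label.
#' @param strand `"+"` or `"-"`.
#' @param isoforms named list; each element a list with `exons`
#'   (`data.frame` with `start`, `end`), `cds_start`, `cds_end`.
#' @return an object of class `GeneModel`.
#' @export
gene_model <- function(gene_id, chrom, strand, isoforms) {
  stopifnot(strand %in% c("+", "-"))
  for (nm in names(isoforms)) {
    iso <- isoforms[[nm]]
    ex <- iso$exons[order(iso$exons$start), , drop = FALSE]
    ex$start <- as.integer(ex$start); ex$end <- as.integer(ex$end)
    rownames(ex) <- NULL
    isoforms[[nm]]$cds_start <- as.integer(iso$cds_start)
    isoforms[[nm]]$cds_end <- as.integer(iso$cds_end)
    if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)]))
      ck_stop(sprintf("isoform %s has overlapping exons", nm), "bad_model")
    if (iso$cds_start < min(ex$start) || iso$cds_end > max(ex$end))
      ck_stop(sprintf("isoform %s CDS outside exon union", nm), "bad_model")
    isoforms[[nm]]$exons <- ex
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 isoforms = isoforms), class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s (%s%s): %d isoform(s)\n", x$gene_id, x$chrom,
              x$strand, length(x$isoforms)))
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Uses mRNA/exon/CDS features linked by `Parent`; the CDS span of an
#' isoform is the range of its CDS features. Isoforms lacking exon features
#' take their CDS features as exons.
#'
#' @param path GFF3 file.
#' @return named list of [gene_model()] objects.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  parent <- vapply(df$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                   character(1))
  mrnas <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  mparent <- parent[df$type %in% c("mRNA", "transcript")]
  out <- list()
  for (k in seq_len(nrow(mrnas))) {
    tid <- mrnas$ID[k]
    gid <- if (!is.na(mparent[k])) mparent[k] else tid
    ex <- df[df$type == "exon" & parent == tid, , drop = FALSE]
    cds <- df[df$type == "CDS" & parent == tid, , drop = FALSE]
    if (nrow(ex) == 0) ex <- cds
    if (nrow(ex) == 0) next
    iso <- list(exons = data.frame(start = ex$start, end = ex$end),
                cds_start = if (nrow(cds)) min(cds$start) else min(ex$start),
                cds_end = if (nrow(cds)) max(cds$end) else max(ex$end))
    if (is.null(out[[gid]])) {
      out[[gid]] <- list(chrom = as.character(mrnas$seqnames[k]),
                         strand = as.character(mrnas$strand[k]), isoforms = list())
    }
    out[[gid]]$isoforms[[tid]] <- iso
  }
  lapply(stats::setNames(names(out), names(out)), function(gid) {
    g <- out[[gid]]
    gene_model(gid, g$chrom, g$strand, g$isoforms)
  })
}

#' Write a gene model as GFF3
#'
#' @param model a [gene_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_model <- function(model, path) {
  rows <- list()
  gspan <- range(unlist(lapply(model$isoforms, function(i) c(i$exons$start, i$exons$end))))
  rows[[1]] <- data.frame(type = "gene", start = gspan[1], end = gspan[2],
                          phase = NA_integer_, ID = model$gene_id,
                          Parent = NA_character_)
  for (nm in names(model$isoforms)) {
    iso <- model$isoforms[[nm]]
    rows[[length(rows) + 1]] <- data.frame(type = "mRNA",
      start = min(iso$exons$start), end = max(iso$exons$end),
      phase = NA_integer_, ID = nm, Parent = model$gene_id)
    for (i in seq_len(nrow(iso$exons)))
      rows[[length(rows) + 1]] <- data.frame(type = "exon",
        start = iso$exons$start[i], end = iso$exons$end[i],
        phase = NA_integer_, ID = sprintf("%s.exon%d", nm, i), Parent = nm)
    cex <- exon_cds_intersections(iso)
    lens <- cex$end - cex$start + 1L
    tx_order <- if (model$strand == "+") seq_len(nrow(cex)) else rev(seq_len(nrow(cex)))
    before <- c(0L, cumsum(lens[tx_order]))[seq_len(nrow(cex))]
    phase <- integer(nrow(cex)); phase[tx_order] <- (3L - before %% 3L) %% 3L
    for (i in seq_len(nrow(cex)))
      rows[[length(rows) + 1]] <- data.frame(type = "CDS",
        start = cex$start[i], end = cex$end[i], phase = phase[i],
        ID = sprintf("%s.cds%d", nm, i), Parent = nm)
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(model$chrom,
          IRanges::IRanges(df$start, df$end), strand = model$strand)
  gr$type <- df$type
  gr$phase <- df$phase
  gr$ID <- df$ID
  gr$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# exon pieces overlapping the CDS span, genomic order
exon_cds_intersections <- function(iso) {
  ex <- iso$exons
  s <- pmax(ex$start, iso$cds_start)
  e <- pmin(ex$end, iso$cds_end)
  keep <- s <= e
  data.frame(start = s[keep], end = e[keep])
}

#' Spliced CDS of an isoform
#'
#' Concatenates the CDS portions of the exons in transcript order and
#' reverse-complements minus-strand models.
#'
#' @param model a [gene_model()].
#' @param genome_seq chromosome sequence as a single string (position 1 =
#'   base 1).
#' @param isoform isoform name or index (default first).
#' @return the coding sequence, 5' to 3'.
#' @export
spliced_cds <- function(model, genome_seq, isoform = 1L) {
  iso <- model$isoforms[[isoform]]
  if (is.null(iso)) ck_stop("unknown isoform", "bad_isoform")
  cex <- exon_cds_intersections(iso)
  seq <- paste(substring(genome_seq, cex$start, cex$end), collapse = "")
  if (model$strand == "-") seq <- revcomp(seq) else seq
}

#' Spliced exonic (transcript) sequence of an isoform
#'
#' @inheritParams spliced_cds
#' @return exonic sequence 5' to 3'.
#' @export
spliced_transcript <- function(model, genome_seq, isoform = 1L) {
  iso <- model$isoforms[[isoform]]
  seq <- paste(substring(genome_seq, iso$exons$start, iso$exons$end), collapse = "")
  if (model$strand == "-") seq <- revcomp(seq) else seq
}

#' Introns of an isoform
#'
#' @inheritParams spliced_cds
#' @return `data.frame` with `start`, `end`: first and last intronic bases,
#'   1-based inclusive, genomic order.
#' @export
introns_of <- function(model, isoform = 1L) {
  ex <- model$isoforms[[isoform]]$exons
  if (nrow(ex) < 2) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1] - 1L)
}
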