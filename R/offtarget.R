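#' Effective matched degree of a read
#'
#' Ratio of matched alignment length to whole read length, the per-read
#' statistic thresholded at 0.90 by the effective-mutation filter.
#'
#' @param matched_length aligned (matched) bases.
#' @param read_length whole read length, including soft-clipped bases.
#' @return fraction in `[0, 1]`.
#' @export
effective_matched_degree <- function(matched_length, read_length) {
  if (any(read_length <= 0)) ck_stop("read_length must be positive", "bad_input")
  if (any(matched_length < 0 | matched_length > read_length))
    ck_stop("matched_length must lie in [0, read_length]", "bad_input")
  matched_length / read_length
}

#' Effective matched degree from CIGAR strings
#'
#' Matched length is the sum of M/=/X operations; the read length includes
#' insertions and soft clips (denominator = M + I + S + `=` + X).
#'
#' @param cigars character vector of CIGAR strings.
#' @return numeric vector of fractions.
#' @export
emd_from_cigar <- function(cigars) {
  ops <- GenomicAlignments::explodeCigarOps(cigars)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigars)
  mapply(function(o, l) {
    matched <- sum(l[o %in% c("M", "=", "X")])
    readlen <- sum(l[o %in% c("M", "I", "S", "=", "X")])
    effective_matched_degree(matched, readlen)
  }, ops, lens)
}

#' Read a variant table from VCF
#'
#' Parses CHROM/POS/REF/ALT, the `ARC` (alt-supporting read count), `MQ`
#' (mapping quality) and `EMD` (effective matched degree) INFO keys, and
#' the GT genotype of the first sample column. Multi-allelic records are
#' split into per-allele records before any filtering.
#'
#' @param path VCF file (plain text or gzipped).
#' @param sample label to attach; defaults to the VCF sample column name.
#' @return `data.frame` with `chrom`, `pos`, `ref`, `alt`, `sample`,
#'   `genotype` (`hom_ref`/`het`/`hom_alt`/`NA`), `alt_read_count`,
#'   `mapping_quality`, `emd`.
#' @export
read_variant_table <- function(path, sample = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  info_get <- function(key) suppressWarnings(
    as.numeric(vcfR::extract.info(v, element = key)))
  arc <- info_get("ARC"); mq <- info_get("MQ"); emd <- info_get("EMD")
  gt_raw <- if (ncol(v@gt) >= 2) {
    if (is.null(sample)) sample <- colnames(v@gt)[2]
    sub(":.*", "", v@gt[, 2])
  } else rep(NA_character_, nrow(fix))
  if (is.null(sample)) sample <- "sample"
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    for (k in seq_along(alts)) {
      gt <- genotype_class(gt_raw[i], k)
      rows[[length(rows) + 1]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[k], sample = sample,
        genotype = gt, alt_read_count = arc[i], mapping_quality = mq[i],
        emd = emd[i], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

genotype_class <- function(gt, allele_index) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_character_)
  a <- strsplit(gt, "[/|]")[[1]]
  hits <- sum(a == as.character(allele_index))
  if (hits == length(a)) "hom_alt"
  else if (hits > 0) "het"
  else if (all(a == "0")) "hom_ref"
  else "het"
}

#' The effective-mutation filter
#'
#' Keeps a mutant variant when it is homozygous for the alternate allele,
#' differs from the wild-type call at the same site, is supported by
#' strictly more than `min_alt_reads` reads, has mapping quality at least
#' `min_mq` and effective matched degree at least `min_emd`. Mutant sites
#' with no wild-type call are flagged unresolved and excluded with a
#' warning. Raising any threshold can only shrink the passing set.
#'
#' @param variants mutant variant `data.frame` (see [read_variant_table()]).
#' @param wildtype wild-type variant `data.frame` for the same genome.
#' @param min_alt_reads strict lower bound on alt-supporting reads
#'   (default 3, i.e. reads > 3 pass).
#' @param min_mq minimum mapping quality (inclusive, default 50).
#' @param min_emd minimum effective matched degree (inclusive, default 0.90).
#' @return the passing subset, with an `unresolved` attribute listing
#'   excluded sites lacking a wild-type call.
#' @export
effective_mutation_filter <- function(variants, wildtype,
                                      min_alt_reads = 3, min_mq = 50,
                                      min_emd = 0.90) {
  key <- function(d) paste(d$chrom, d$pos)
  wt_key <- key(wildtype)
  mk <- key(variants)
  resolved <- mk %in% wt_key
  if (any(!resolved))
    ck_warn(sprintf("%d variant(s) without a wild-type call excluded",
                    sum(!resolved)), "unresolved_wildtype")
  # wild-type allele at each site: its alt when called hom_alt, else ref
  wt_allele <- ifelse(wildtype$genotype == "hom_alt" & !is.na(wildtype$genotype),
                      wildtype$alt, wildtype$ref)
  names(wt_allele) <- wt_key
  differs <- resolved & variants$alt != wt_allele[mk]
  pass <- resolved & differs &
    !is.na(variants$genotype) & variants$genotype == "hom_alt" &
    variants$alt_read_count > min_alt_reads &
    variants$mapping_quality >= min_mq &
    variants$emd >= min_emd
  pass[is.na(pass)] <- FALSE
  out <- variants[pass, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unresolved") <- variants[!resolved, , drop = FALSE]
  out
}

#' Annotate variants with region class and coding effect
#'
#' Classifies each variant position as `exon` (coding), `UTR`, `intron` or
#' `intergenic` (precedence in that order) against a set of gene models.
#' For exonic single-nucleotide variants with a genome sequence supplied,
#' the amino-acid effect (`synonymous`/`missense`/`nonsense`) is derived by
#' substituting the base in its codon.
#'
#' @param variants variant `data.frame`.
#' @param models named list of [gene_model()] objects (see
#'   [read_gene_models()]).
#' @param genome_seqs optional named list/vector of chromosome sequences.
#' @return `variants` with `region` and `effect` columns added.
#' @export
annotate_variants <- function(variants, models, genome_seqs = NULL) {
  variants$region <- vapply(seq_len(nrow(variants)), function(i)
    classify_region(variants$chrom[i], variants$pos[i], models), character(1))
  variants$effect <- NA_character_
  if (!is.null(genome_seqs)) {
    snv <- which(variants$region == "exon" &
                 nchar(variants$ref) == 1 & nchar(variants$alt) == 1)
    for (i in snv) {
      gs <- genome_seqs[[variants$chrom[i]]]
      if (is.null(gs)) next
      variants$effect[i] <- coding_effect(variants$chrom[i], variants$pos[i],
                                          variants$alt[i], models, gs)
    }
  }
  variants
}

classify_region <- function(chrom, pos, models) {
  region <- "intergenic"
  for (m in models) {
    if (m$chrom != chrom) next
    for (iso in m$isoforms) {
      span <- range(c(iso$exons$start, iso$exons$end))
      if (pos < span[1] || pos > span[2]) next
      in_exon <- any(pos >= iso$exons$start & pos <= iso$exons$end)
      if (!in_exon) { region <- max_region(region, "intron"); next }
      cex <- exon_cds_intersections(iso)
      in_cds <- any(pos >= cex$start & pos <= cex$end)
      region <- max_region(region, if (in_cds) "exon" else "UTR")
    }
  }
  region
}

# precedence: exon > UTR > intron > intergenic
max_region <- function(a, b) {
  lev <- c(intergenic = 1, intron = 2, UTR = 3, exon = 4)
  names(which.max(lev[c(a, b)]))
}

coding_effect <- function(chrom, pos, alt, models, genome_seq) {
  for (m in models) {
    if (m$chrom != chrom) next
    for (nm in names(m$isoforms)) {
      cpos <- cds_positions(m, nm)
      if (m$strand == "-") cpos <- rev(cpos)
      idx <- match(pos, cpos)
      if (is.na(idx)) next
      codon_i <- (idx - 1) %/% 3
      cod_pos <- cpos[(codon_i * 3 + 1):(codon_i * 3 + 3)]
      bases <- strsplit(genome_seq, "")[[1]][cod_pos]
      alt_b <- alt
      if (m$strand == "-") { bases <- chartr("ACGT", "TGCA", bases); alt_b <- chartr("ACGT", "TGCA", alt) }
      wt_codon <- paste(bases, collapse = "")
      mut <- bases; mut[(idx - 1) %% 3 + 1] <- alt_b
      mut_codon <- paste(mut, collapse = "")
      aa_wt <- codon_aa(wt_codon); aa_mut <- codon_aa(mut_codon)
      return(if (identical(aa_mut, "*") && !identical(aa_wt, "*")) "nonsense"
             else if (identical(aa_wt, aa_mut)) "synonymous" else "missense")
    }
  }
  NA_character_
}

#' Summarise passing variants by region and variant type
#'
#' @param variants annotated variant `data.frame` (with `region`).
#' @return `data.frame` of counts for every region
#'   (`intergenic`/`intron`/`UTR`/`exon`) by type (`SNP`/`INDEL`); counts
#'   sum to `nrow(variants)`.
#' @export
summarize_by_region <- function(variants) {
  regions <- c("intergenic", "intron", "UTR", "exon")
  types <- c("SNP", "INDEL")
  type <- ifelse(nchar(variants$ref) == 1 & nchar(variants$alt) == 1,
                 "SNP", "INDEL")
  out <- expand.grid(region = regions, type = types, stringsAsFactors = FALSE)
  out$count <- mapply(function(r, t)
    sum(variants$region == r & type == t), out$region, out$type)
  out
}

#' Per-gene off-target verdicts for a candidate gene list
#'
#' Applies the effective-mutation filter restricted to each listed gene's
#' span (the algorithmic stand-in for a by-eye browser inspection of the
#' gene family).
#'
#' @param variants mutant variant `data.frame`.
#' @param wildtype wild-type variant `data.frame`.
#' @param models named list of [gene_model()]; names are the genes screened.
#' @param ... thresholds passed to [effective_mutation_filter()].
#' @return `data.frame` with `gene`, `n_effective`, `verdict`
#'   (`clean`/`mutated`).
#' @export
screen_gene_list <- function(variants, wildtype, models, ...) {
  rows <- lapply(names(models), function(g) {
    m <- models[[g]]
    span <- range(unlist(lapply(m$isoforms, function(i) c(i$exons$start, i$exons$end))))
    sel <- variants$chrom == m$chrom & variants$pos >= span[1] & variants$pos <= span[2]
    pass <- suppressWarnings(
      effective_mutation_filter(variants[sel, , drop = FALSE], wildtype, ...))
    data.frame(gene = g, n_effective = nrow(pass),
               verdict = if (nrow(pass)) "mutated" else "clean",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a variant table as a minimal VCF
#'
#' Emits `ARC`, `MQ` and `EMD` INFO keys and a single GT genotype column.
#'
#' @param variants variant `data.frame` (see [read_variant_table()]).
#' @param path output path.
#' @param sample genotype column label; defaults to the table's sample.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(variants, path, sample = NULL) {
  if (is.null(sample))
    sample <- if (nrow(variants)) variants$sample[1] else "sample"
  gt <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1")
  header <- c("##fileformat=VCFv4.2",
    "##INFO=<ID=ARC,Number=1,Type=Integer,Description=\"Alt-supporting read count\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##INFO=<ID=EMD,Number=1,Type=Float,Description=\"Effective matched degree\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", sample), collapse = "\t")))
  body <- if (nrow(variants)) {
    ord <- order(variants$chrom, variants$pos)
    v <- variants[ord, ]
    paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS",
          sprintf("ARC=%d;MQ=%g;EMD=%g", as.integer(v$alt_read_count),
                  v$mapping_quality, v$emd),
          "GT", ifelse(is.na(v$genotype), "./.", gt[v$genotype]), sep = "\t")
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}
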