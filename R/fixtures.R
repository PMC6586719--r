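# Packaged fixtures: the printed wild-type/mutant target-region alleles of
# the OsIAA23 T0 genotyping table, a synthetic in-frame gene embedding the
# 47-nt target, and a synthetic multi-exon gene for splice-rescue analysis.
# Both genes are synthetic stand-ins: the real chr06 locus coordinates are
# not reproduced, only the coding-frame relationships that matter.

TARGET_47MER <- "GGGCGTACAGGCGGAACGCGCTGCGGGAGGACGCCGCGAGGGCGAAG"

#' Printed target-region alleles of the OsIAA23 T0 plants
#'
#' Returns the 47-nt wild-type target region around the Domain II spacer and
#' the four mutant alleles observed in T0 plants (a 3-bp deletion, a 39-bp
#' deletion, a G insertion, a T insertion), exactly as printed (gap
#' characters retained where printed), plus a synthetic gene model that
#' embeds the 47-mer in frame. The embedding offset is chosen so the 3-bp
#' deletion removes one complete GCG (alanine) codon.
#'
#' @return list with `wild_type` (47-mer), `mutants` (named list `del3`,
#'   `del39`, `insG`, `insT`), `gene` (a [gene_model()]), `genome` (the
#'   synthetic chromosome string), `region_start` (genomic coordinate of the
#'   47-mer's first base), `domains_protein` (`data.frame` of Domains I-IV in
#'   protein coordinates), and `counts` (the T0 screening counts per
#'   variety: PCR-identified plants and mutants).
#' @export
table2_fixture <- function() {
  wt <- TARGET_47MER
  mutants <- list(
    del3  = "GG-TACAGGCGGAACGCGCTGCGGGAGGACGCCGCGAGGGCGAAG",
    del39 = "GG-GCGAAG",
    insG  = "GGGCGGTACAGGCGGAACGCGCTGCGGGAGGACGCCGCGAGGGCGAAG",
    insT  = "GGGCGTTACAGGCGGAACGCGCTGCGGGAGGACGCCGCGAGGGCGAAG")
  g <- fixture_gene()
  list(wild_type = wt, mutants = mutants, gene = g$model, genome = g$genome,
       region_start = g$region_start, domains_protein = g$domains_protein,
       counts = table1_counts())
}

#' T0 editing screen counts
#'
#' PCR-identified positive transgenic plants and confirmed mutants per
#' recipient variety, as printed in the T0 screening table.
#'
#' @return `data.frame` with `variety`, `identified`, `mutants`.
#' @export
table1_counts <- function() {
  data.frame(variety = c("Kasalath", "Wuyunjing24"),
             identified = c(6L, 5L),
             mutants = c(2L, 5L),
             stringsAsFactors = FALSE)
}

# single-exon synthetic gene carrying the 47-mer at codon phase 2 (its third
# base starts a codon), with an Aux/IAA-like domain layout.
fixture_gene <- function() {
  upstream <- paste0(
    "ATG",
    "GCTTCTGATCTTCGTGAAATTGAGAAACTTCAGGCAGAGCTTGTCAAAGGTTTCGAGCATATCCTTGATGCTCCA",
    "GGATGGCCTCCTGTT",  # GWPPV degron core, residues 27-31
    "AAG", "GCA", "C")   # 100 nt total; trailing C opens codon 34
  tail <- paste0(paste(rep(c("GAA", "GAC", "CTG", "AAG", "TCC", "GCT"), 13),
                       collapse = ""), "GAAGACCTG", "TAA")
  cds <- paste0(upstream, TARGET_47MER, tail)
  pad5 <- paste(rep("ACGTACGTAC", 5), collapse = "")
  pad3 <- paste(rep("TTGCAATGCA", 5), collapse = "")
  genome <- paste0(pad5, cds, pad3)
  cds_start <- nchar(pad5) + 1L
  cds_end <- nchar(pad5) + nchar(cds)
  model <- gene_model("synthIAA23", "chrF", "+", list(
    synthIAA23.1 = list(exons = data.frame(start = cds_start, end = cds_end),
                        cds_start = cds_start, cds_end = cds_end)))
  list(model = model, genome = genome,
       region_start = nchar(pad5) + 100L + 1L,
       domains_protein = data.frame(
         name = c("DomainI", "DomainII", "DomainIII", "DomainIV"),
         start = c(5L, 22L, 80L, 100L),
         end = c(20L, 40L, 95L, 115L),
         stringsAsFactors = FALSE))
}

#' Synthetic gene fixture for splice-junction rescue analysis
#'
#' A plus-strand three-exon gene whose second exon ends with donor-like GT
#' dinucleotides 13 bp and 11 bp upstream of the annotated second intron,
#' emulating the two novel junctions observed at the edited locus. The exon
#' body is a GCA-repeat so that no reading frame of the exonic sequence can
#' contain a stop codon except the annotated terminal TAA.
#'
#' @return list with `model` (a [gene_model()]), `genome` (chromosome
#'   string, label `chrS`), `insertion_pos` (genomic coordinate for a 1-bp
#'   coding insertion 20 bp upstream of the second donor site), and
#'   `intron2` (`c(start, end)` of the annotated second intron).
#' @export
rescue_fixture <- function() {
  exon1 <- paste0("ATG", paste(rep("GCA", 19), collapse = ""))          # 60
  exon2 <- paste0(paste(rep("GCA", 25), collapse = ""), "GC",
                  "GTGTGCAGCAGCA")                                       # 90
  exon3 <- paste0(paste(rep("GCA", 19), collapse = ""), "TAA")          # 60
  intron <- paste0("GT", paste(rep("C", 56), collapse = ""), "AG")      # 60
  pad <- "ACGTACGTAC"
  genome <- paste0(pad, exon1, intron, exon2, intron, exon3, pad)
  e1s <- 11L; e1e <- e1s + 59L              # 11..70
  e2s <- e1e + 61L; e2e <- e2s + 89L        # 131..220
  e3s <- e2e + 61L; e3e <- e3s + 59L        # 281..340
  model <- gene_model("synthRescue", "chrS", "+", list(
    synthRescue.1 = list(exons = data.frame(start = c(e1s, e2s, e3s),
                                            end = c(e1e, e2e, e3e)),
                         cds_start = e1s, cds_end = e3e)))
  list(model = model, genome = genome,
       insertion_pos = e2e - 19L,           # before this base; 20 bp from donor
       intron2 = c(e2e + 1L, e3s - 1L))
}
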