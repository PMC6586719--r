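test_that("effective matched degree is the matched fraction of the whole read", {
  expect_equal(effective_matched_degree(95, 100), 0.95)
  expect_equal(effective_matched_degree(100, 100), 1)
  expect_lt(effective_matched_degree(89, 100), 0.90)
  expect_error(effective_matched_degree(5, 0), class = "crisprkit_bad_input")
  expect_error(effective_matched_degree(101, 100), class = "crisprkit_bad_input")
  # soft clips count in the denominator, not the numerator
  expect_equal(emd_from_cigar(c("100M", "90M10S", "45M1D45M10S")),
               c(1, 0.9, 0.9))
})

make_variant <- function(pos = 100L, genotype = "hom_alt", arc = 4L, mq = 55,
                         emd = 0.95, alt = "T") {
  data.frame(chrom = "chr1", pos = pos, ref = "A", alt = alt, sample = "mut",
             genotype = genotype, alt_read_count = arc, mapping_quality = mq,
             emd = emd, stringsAsFactors = FALSE)
}
wt_call <- function(pos = 100L, genotype = "hom_ref", alt = "T") {
  data.frame(chrom = "chr1", pos = pos, ref = "A", alt = alt, sample = "wt",
             genotype = genotype, alt_read_count = 0L, mapping_quality = 60,
             emd = 0.99, stringsAsFactors = FALSE)
}

test_that("the effective-mutation filter enforces every threshold with the stated strictness", {
  expect_identical(nrow(effective_mutation_filter(make_variant(), wt_call())), 1L)
  # 'mutated reads > 3' is strict: exactly 3 fails, 4 passes
  expect_identical(nrow(effective_mutation_filter(make_variant(arc = 3L), wt_call())), 0L)
  expect_identical(nrow(effective_mutation_filter(make_variant(arc = 4L), wt_call())), 1L)
  # mapping quality and matched degree are inclusive bounds
  expect_identical(nrow(effective_mutation_filter(make_variant(mq = 49), wt_call())), 0L)
  expect_identical(nrow(effective_mutation_filter(make_variant(mq = 50), wt_call())), 1L)
  expect_identical(nrow(effective_mutation_filter(make_variant(emd = 0.89), wt_call())), 0L)
  expect_identical(nrow(effective_mutation_filter(make_variant(emd = 0.90), wt_call())), 1L)
  # heterozygous calls and sites equal to the wild-type call are excluded
  expect_identical(nrow(effective_mutation_filter(make_variant(genotype = "het"),
                                                  wt_call())), 0L)
  expect_identical(nrow(effective_mutation_filter(
    make_variant(), wt_call(genotype = "hom_alt"))), 0L)
  # missing wild-type call: excluded with a warning
  expect_warning(
    out <- effective_mutation_filter(make_variant(pos = 999L), wt_call()),
    class = "crisprkit_unresolved_wildtype")
  expect_identical(nrow(out), 0L)
  expect_identical(nrow(attr(out, "unresolved")), 1L)
})

test_that("the filter is monotone: raising any threshold never grows the passing set", {
  set.seed(91)
  n <- 200
  vars <- data.frame(chrom = "chr1", pos = seq_len(n) * 10L, ref = "A", alt = "T",
                     sample = "mut",
                     genotype = sample(c("hom_alt", "het", "hom_ref"), n, TRUE),
                     alt_read_count = sample(0:12, n, TRUE),
                     mapping_quality = runif(n, 30, 70),
                     emd = runif(n, 0.7, 1), stringsAsFactors = FALSE)
  wt <- data.frame(chrom = "chr1", pos = seq_len(n) * 10L, ref = "A", alt = "T",
                   sample = "wt", genotype = "hom_ref", alt_read_count = 0L,
                   mapping_quality = 60, emd = 0.99, stringsAsFactors = FALSE)
  base <- effective_mutation_filter(vars, wt)
  for (args in list(list(min_alt_reads = 6), list(min_mq = 60),
                    list(min_emd = 0.97))) {
    tighter <- do.call(effective_mutation_filter, c(list(vars, wt), args))
    expect_true(all(tighter$pos %in% base$pos))
    expect_lte(nrow(tighter), nrow(base))
  }
})

test_that("region annotation follows the exon > UTR > intron > intergenic precedence", {
  # gene with UTRs: exon 1..30, CDS 11..25
  m_utr <- gene_model("g1", "chrU", "+", list(
    t1 = list(exons = data.frame(start = 1, end = 30), cds_start = 11, cds_end = 25)))
  # overlapping second gene whose CDS covers position 5
  m_cds <- gene_model("g2", "chrU", "+", list(
    t2 = list(exons = data.frame(start = 3, end = 20), cds_start = 3, cds_end = 20)))
  v <- data.frame(chrom = "chrU", pos = c(5L, 5L), ref = "A", alt = "T",
                  sample = "m", genotype = "hom_alt", alt_read_count = 5L,
                  mapping_quality = 60, emd = 0.99, stringsAsFactors = FALSE)
  only_utr <- annotate_variants(v[1, ], list(g1 = m_utr))
  expect_identical(only_utr$region, "UTR")
  both <- annotate_variants(v[1, ], list(g1 = m_utr, g2 = m_cds))
  expect_identical(both$region, "exon") # precedence
  # intron and intergenic
  m_introny <- gene_model("g3", "chrU", "+", list(
    t3 = list(exons = data.frame(start = c(100, 200), end = c(150, 250)),
              cds_start = 100, cds_end = 250)))
  vi <- data.frame(chrom = "chrU", pos = c(170L, 500L), ref = "A", alt = "T",
                   sample = "m", genotype = "hom_alt", alt_read_count = 5L,
                   mapping_quality = 60, emd = 0.99, stringsAsFactors = FALSE)
  ai <- annotate_variants(vi, list(g3 = m_introny))
  expect_identical(ai$region, c("intron", "intergenic"))
})

test_that("coding effects are read off the codon table, honouring strand", {
  fx <- table2_fixture()
  rs <- fx$region_start # 47-mer start; GCG codon occupies rs+2 .. rs+4
  mk <- function(pos, alt) data.frame(chrom = "chrF", pos = pos, ref = "G",
    alt = alt, sample = "m", genotype = "hom_alt", alt_read_count = 5L,
    mapping_quality = 60, emd = 0.99, stringsAsFactors = FALSE)
  genome <- list(chrF = fx$genome)
  models <- list(g = fx$gene)
  syn <- annotate_variants(mk(rs + 4L, "A"), models, genome) # GCG -> GCA
  expect_identical(syn$effect, "synonymous")
  mis <- annotate_variants(mk(rs + 2L, "C"), models, genome) # GCG -> CCG
  expect_identical(mis$effect, "missense")
  # same codon on the minus strand of a mirrored model
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fx$genome)))
  L <- nchar(fx$genome)
  ex <- fx$gene$isoforms[[1]]$exons
  m_rev <- gene_model("grev", "chrR", "-", list(
    t1 = list(exons = data.frame(start = L - ex$end + 1, end = L - ex$start + 1),
              cds_start = L - ex$end + 1, cds_end = L - ex$start + 1)))
  pos_rev <- L - (rs + 4L) + 1L
  v_rev <- data.frame(chrom = "chrR", pos = pos_rev, ref = "C", alt = "T",
                      sample = "m", genotype = "hom_alt", alt_read_count = 5L,
                      mapping_quality = 60, emd = 0.99, stringsAsFactors = FALSE)
  a_rev <- annotate_variants(v_rev, list(g = m_rev), list(chrR = rc))
  expect_identical(a_rev$effect, "synonymous") # GCG -> GCA seen from the + strand
})

test_that("region summaries partition the passing set", {
  planted <- data.frame(region = c(rep("intergenic", 6), rep("intron", 3),
                                   rep("UTR", 2), "exon"),
                        stringsAsFactors = FALSE)
  v <- data.frame(chrom = "chr1", pos = seq_len(12) * 5L,
                  ref = c(rep("A", 9), "AT", "A", "A"),
                  alt = c(rep("T", 9), "A", "ACG", "C"),
                  region = planted$region, stringsAsFactors = FALSE)
  s <- summarize_by_region(v)
  expect_identical(sum(s$count), 12L)
  expect_identical(s$count[s$region == "intergenic" & s$type == "SNP"], 6L)
  expect_identical(s$count[s$region == "intron" & s$type == "SNP"], 3L)
  expect_identical(sum(s$count[s$type == "INDEL"]), 2L)
  empty <- summarize_by_region(v[0, ])
  expect_identical(sum(empty$count), 0L)
})

test_that("variant tables round-trip through VCF, splitting multi-allelic records", {
  v <- make_variant(pos = c(10L, 20L), alt = c("T", "G"))
  v$genotype <- c("hom_alt", "het")
  path <- tempfile(fileext = ".vcf")
  write_variant_vcf(v, path)
  back <- read_variant_table(path, sample = "mut")
  expect_identical(back$pos, v$pos)
  expect_identical(back$genotype, v$genotype)
  expect_equal(back$emd, v$emd)
  expect_equal(back$alt_read_count, v$alt_read_count)
  # hand-written multi-allelic record splits into per-allele rows
  multi <- c("##fileformat=VCFv4.2",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tmut",
             "chr1\t50\t.\tA\tT,G\t.\tPASS\tARC=6;MQ=60;EMD=0.97\tGT\t1/2")
  mpath <- tempfile(fileext = ".vcf")
  writeLines(multi, mpath)
  mv <- read_variant_table(mpath)
  expect_identical(nrow(mv), 2L)
  expect_identical(mv$alt, c("T", "G"))
  expect_identical(mv$genotype, c("het", "het"))
})

test_that("gene-list screening gives per-gene verdicts", {
  fx <- rescue_fixture()
  v <- rbind(make_variant(pos = 140L), make_variant(pos = 5000L))
  v$chrom <- "chrS"
  wt <- rbind(wt_call(pos = 140L), wt_call(pos = 5000L))
  wt$chrom <- "chrS"
  verdicts <- screen_gene_list(v, wt, list(synthRescue = fx$model))
  expect_identical(verdicts$verdict, "mutated")
  clean <- screen_gene_list(make_variant(pos = 5000L), wt, list(synthRescue = fx$model))
  expect_identical(clean$verdict, "clean")
})
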