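fx <- table2_fixture()

test_that("the printed genotyping-table alleles yield the expected edit events", {
  del3 <- infer_edit(fx$wild_type, fx$mutants$del3)
  expect_identical(del3$kind, "deletion")
  expect_identical(nchar(del3$ref_allele), 3L)
  del39 <- infer_edit(fx$wild_type, fx$mutants$del39)
  expect_identical(del39$kind, "deletion")
  expect_identical(nchar(del39$ref_allele), 39L)
  insG <- infer_edit(fx$wild_type, fx$mutants$insG)
  expect_identical(insG$kind, "insertion")
  expect_identical(insG$alt_allele, "G")
  insT <- infer_edit(fx$wild_type, fx$mutants$insT)
  expect_identical(insT$kind, "insertion")
  expect_identical(insT$alt_allele, "T")
})

test_that("edit placement is leftmost-normalized", {
  # deleting GCG after GG is equivalent to deleting GGC one base earlier;
  # the leftmost placement must be reported
  e <- infer_edit("GGGCGTACA", "GGTACA")
  expect_identical(e$pos, 2L)
  expect_identical(e$ref_allele, "GGC")
  # homopolymer insertion shifts to the run's left edge
  e2 <- infer_edit("CTAAAG", "CTAAAAG")
  expect_identical(e2$pos, 3L)
  expect_identical(e2$alt_allele, "A")
})

test_that("identical or multi-block inputs are handled", {
  expect_error(infer_edit("ACGT", "ACGT"), class = "crisprkit_no_edit")
  e <- infer_edit("AAACCCGGG", "AAATTGGG") # CCC -> TT, one complex block
  expect_identical(e$kind, "complex")
  expect_identical(e$ref_allele, "CCC")
  expect_identical(e$alt_allele, "TT")
})

apply_to_string <- function(wt, e) {
  paste0(substr(wt, 1, e$pos - 1), e$alt_allele,
         substr(wt, e$pos + nchar(e$ref_allele), nchar(wt)))
}

test_that("infer/apply round-trips leftmost-normalized edits on random sequences", {
  set.seed(71)
  for (rep in 1:1000) {
    wt <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
    kind <- sample(c("ins", "del", "sub"), 1)
    pos <- sample(2:50, 1)
    mut <- switch(kind,
      ins = paste0(substr(wt, 1, pos - 1),
                   paste(sample(c("A", "C", "G", "T"), sample(1:5, 1),
                                replace = TRUE), collapse = ""),
                   substr(wt, pos, 60)),
      del = paste0(substr(wt, 1, pos - 1), substr(wt, pos + sample(1:5, 1), 60)),
      sub = { v <- strsplit(wt, "")[[1]]
              v[pos] <- setdiff(c("A", "C", "G", "T"), v[pos])[1]
              paste(v, collapse = "") })
    if (mut == wt) next
    e <- infer_edit(wt, mut)
    expect_identical(apply_to_string(wt, e), mut)
    # the inferred event is a fixed point of inference (already normalized)
    e2 <- infer_edit(wt, apply_to_string(wt, e))
    expect_identical(e2[c("pos", "ref_allele", "alt_allele")],
                     e[c("pos", "ref_allele", "alt_allele")])
  }
})

rfx <- rescue_fixture()

test_that("applying edits to a gene model shifts downstream coordinates correctly", {
  # 3-bp deletion wholly inside exon 2
  del <- edit_event("chrS", 140L, substr(rfx$genome, 140, 142), "")
  ap <- apply_edit(rfx$model, rfx$genome, del)
  expect_identical(nchar(ap$cds_mut), nchar(ap$cds_wt) - 3L)
  expect_identical(ap$overlap, "cds")
  # 1-bp insertion: CDS longer by 1, downstream donor shifts +1
  ins <- edit_event("chrS", 140L, "", "T")
  ap2 <- apply_edit(rfx$model, rfx$genome, ins)
  expect_identical(nchar(ap2$cds_mut), nchar(ap2$cds_wt) + 1L)
  wt_introns <- introns_of(rfx$model)
  mut_introns <- introns_of(ap2$model)
  expect_identical(mut_introns$start[2], wt_introns$start[2] + 1L)
  expect_identical(mut_introns$start[1], wt_introns$start[1]) # upstream untouched
  # edit upstream of the gene leaves the CDS unchanged
  up <- edit_event("chrS", 3L, substr(rfx$genome, 3, 3), "")
  ap3 <- apply_edit(rfx$model, rfx$genome, up)
  expect_identical(ap3$cds_mut, ap3$cds_wt)
  expect_identical(ap3$overlap, "none")
})

test_that("an edit spanning an exon/intron boundary is applied with a warning flag", {
  del <- edit_event("chrS", 68L, substr(rfx$genome, 68, 74), "")
  expect_warning(ap <- apply_edit(rfx$model, rfx$genome, del),
                 class = "crisprkit_boundary_overlap")
  expect_true(ap$boundary_warning)
  expect_identical(nchar(ap$genome), nchar(rfx$genome) - 7L)
})

test_that("translation follows the standard code with stop/partial/N handling", {
  expect_identical(as.character(translate_cds("ATGAAATAA")), "MK")
  expect_identical(as.character(translate_cds("ATGGGATGGCCTCCTGTT")), "MGWPPV")
  expect_warning(p <- translate_cds("ATGAA"), class = "crisprkit_partial_codon")
  expect_identical(as.character(p), "M")
  expect_identical(as.character(translate_cds("ATGANAAAA")), "MXK")
})

test_that("consequence classification covers the kinds and the domain-loss rule", {
  wt <- paste0("ATG", strrep("GCT", 30), "TAA")
  # codon-aligned in-frame deletion of k codons removes exactly k residues
  for (k in c(1, 4)) {
    mut <- paste0("ATG", strrep("GCT", 30 - k), "TAA")
    rep <- classify_consequence(wt, mut)
    expect_identical(rep$kind, "in_frame_deletion")
    expect_equal(rep$aa_removed, k)
    expect_true(is.na(rep$premature_stop_at))
  }
  # synonymous and missense single-base changes
  expect_identical(classify_consequence(wt, sub("GCT", "GCC", wt))$kind, "synonymous")
  expect_identical(classify_consequence(wt, sub("GCT", "CCT", wt))$kind, "missense")
  # frameshift never reported for in-frame length changes (random trials)
  set.seed(81)
  for (rep_i in 1:50) {
    k <- sample(1:5, 1) * 3
    at <- sample(seq(4, 80, by = 1), 1)
    mut <- paste0(substr(wt, 1, at - 1), substr(wt, at + k, nchar(wt)))
    expect_false(classify_consequence(wt, mut)$kind == "frameshift")
  }
  # start loss
  expect_identical(classify_consequence(wt, sub("^ATG", "CTG", wt))$kind,
                   "start_lost")
})

test_that("editing rate reproduces the screening percentages", {
  counts <- table1_counts()
  rates <- editing_rate(counts$mutants, counts$identified)
  expect_equal(round(rates[counts$variety == "Kasalath"], 1), 33.3)
  expect_equal(rates[counts$variety == "Wuyunjing24"], 100)
  expect_error(editing_rate(1, 0), class = "crisprkit_bad_input")
})

test_that("edit events round-trip through the VCF writer with anchor bases", {
  e <- infer_edit(fx$wild_type, fx$mutants$del39, chrom = "chrF",
                  region_start = fx$region_start)
  path <- tempfile(fileext = ".vcf")
  write_edits_vcf(list(e), fx$genome, path)
  v <- read_variant_table(path)
  expect_identical(nrow(v), 1L)
  expect_identical(nchar(v$ref) - nchar(v$alt), 39L)
  expect_identical(v$pos, e$pos - 1L) # anchor-base convention
})
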