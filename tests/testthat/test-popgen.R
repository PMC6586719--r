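test_that("Jukes-Cantor correction matches the closed form and its boundaries", {
  expect_identical(jc_corrected_distance(0), 0)
  expect_equal(jc_corrected_distance(0.3), -0.75 * log(0.6), tolerance = 1e-12)
  expect_equal(jc_corrected_distance(0.3), 0.38312, tolerance = 1e-4)
  expect_gte(jc_corrected_distance(0.5), 0.5)
  expect_error(jc_corrected_distance(0.75), class = "crisprkit_saturation")
  expect_error(jc_corrected_distance(-0.01), class = "crisprkit_domain")
})

test_that("nucleotide diversity counts pairwise differences with gap/N masking", {
  a100 <- strrep("A", 100)
  expect_identical(nucleotide_diversity(coding_alignment(c(a = a100, b = a100))), 0)
  one_diff <- paste0("T", strrep("A", 99))
  expect_equal(nucleotide_diversity(coding_alignment(c(a = a100, b = one_diff))),
               0.01)
  # gap in one member masks that site for that pair only
  gapped <- paste0("-", strrep("A", 99))
  expect_equal(nucleotide_diversity(coding_alignment(c(a = a100, b = gapped))), 0)
  expect_error(nucleotide_diversity(coding_alignment(c(a = a100))),
               class = "crisprkit_insufficient_samples")
  masked <- coding_alignment(c(a = "NNNN", b = "AAAA"))
  expect_true(is.na(nucleotide_diversity(masked)))
})

test_that("three-sample diversity equals the mean of hand-enumerated pairwise values", {
  set.seed(11)
  seqs <- random_alignment(3, 60, p_mut = 0.1)
  expected <- mean(c(
    sum(strsplit(seqs[1], "")[[1]] != strsplit(seqs[2], "")[[1]]) / 60,
    sum(strsplit(seqs[1], "")[[1]] != strsplit(seqs[3], "")[[1]]) / 60,
    sum(strsplit(seqs[2], "")[[1]] != strsplit(seqs[3], "")[[1]]) / 60))
  expect_equal(nucleotide_diversity(coding_alignment(seqs)), expected)
})

test_that("corrected diversity dominates raw diversity, equality only at zero", {
  set.seed(21)
  for (rep in 1:20) {
    seqs <- random_alignment(sample(2:8, 1), 90, p_mut = runif(1, 0, 0.2))
    aln <- coding_alignment(seqs)
    raw <- nucleotide_diversity(aln)
    jc <- nucleotide_diversity(aln, corrected = TRUE)
    if (raw == 0) expect_identical(jc, 0) else expect_gt(jc, raw)
  }
})

test_that("Tajima constants match an independently written transcription for n = 4..20", {
  for (n in 4:20) {
    k <- tajima_constants(n)
    i <- seq_len(n - 1)
    a1 <- sum(1 / i); a2 <- sum(i^-2)
    b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
    expect_equal(k$a1, a1); expect_equal(k$a2, a2)
    expect_equal(k$e1, c1 / a1, tolerance = 1e-12)
    expect_equal(k$e2, c2 / (a1 * a1 + a2), tolerance = 1e-12)
  }
  expect_error(tajima_constants(3), class = "crisprkit_insufficient_samples")
})

test_that("Tajima's D equals the constant-by-constant oracle on hand-built and random alignments", {
  # n = 4, S = 3, enumerable by hand
  seqs <- c(s1 = "AAAAAAAAAA", s2 = "TAAAAAAAAA", s3 = "TCAAAAAAAA",
            s4 = "TCGAAAAAAA")
  expect_equal(tajimas_d(coding_alignment(seqs)), oracle_tajimas_d(seqs),
               tolerance = 1e-12)
  expect_true(is.na(tajimas_d(coding_alignment(c(a = "ACGT", b = "ACGT",
                                                 c = "ACGT", d = "ACGT")))))
  set.seed(31)
  for (rep in 1:25) {
    seqs <- random_alignment(sample(4:15, 1), 120, p_mut = runif(1, 0.01, 0.15))
    expect_equal(tajimas_d(coding_alignment(seqs)), oracle_tajimas_d(seqs),
                 tolerance = 1e-10)
  }
})

test_that("Tajima's D uses complete deletion: a gap column drops from both S and khat", {
  base <- c(s1 = "AAAAAAAAA", s2 = "TAAAAAAAA", s3 = "AACAAAAAA", s4 = "AAAAAAAAG")
  with_gap <- sub("^A", "-", base[["s1"]]) # masks the segregating first column
  gapped <- c(s1 = with_gap, base[-1])
  expect_equal(tajimas_d(coding_alignment(gapped)),
               oracle_tajimas_d(gapped), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(tajimas_d(coding_alignment(base)),
                                tajimas_d(coding_alignment(gapped)))))
})

test_that("K2P distance matches the closed form and saturates correctly", {
  s1 <- strrep("A", 100)
  expect_identical(k2p_distance(s1, s1), 0)
  v <- rep("A", 100); v[1:10] <- "G"; v[11:15] <- "C" # P = 0.1, Q = 0.05
  s2 <- paste(v, collapse = "")
  expect_equal(k2p_distance(s1, s2), 0.17018, tolerance = 1e-4)
  w <- rep("A", 100); w[1:50] <- "G" # P = 0.5, Q = 0
  expect_error(k2p_distance(s1, paste(w, collapse = "")),
               class = "crisprkit_saturation")
})

test_that("domain scan reports the whole CDS first and resolves regional contrast", {
  # domain covering everything duplicates the CDS row
  set.seed(41)
  seqs <- random_alignment(5, 90, 0.05)
  dom_all <- data.frame(name = "All", start = 1, end = 90)
  sc <- domain_scan(coding_alignment(seqs, domains = dom_all))
  expect_identical(sc$region_name, c("CDS", "All"))
  expect_equal(sc$pi_raw[1], sc$pi_raw[2])
  expect_equal(sc$tajima_d[1], sc$tajima_d[2])
  # no domains: a single CDS row
  sc1 <- domain_scan(coding_alignment(seqs))
  expect_identical(sc1$region_name, "CDS")
  # constructed elevated-density region exceeds the CDS-wide value
  set.seed(42)
  quiet <- random_alignment(6, 120, 0.01)
  hot <- random_alignment(6, 60, 0.25)
  seqs2 <- paste0(quiet, hot)
  names(seqs2) <- names(quiet)
  aln2 <- coding_alignment(seqs2,
    domains = data.frame(name = "DomainII", start = 121, end = 180))
  sc2 <- domain_scan(aln2)
  expect_gt(sc2$pi_raw[sc2$region_name == "DomainII"], sc2$pi_raw[1])
  # permille display scales diversities by 1000
  expect_equal(domain_scan(aln2, permille = TRUE)$pi_raw, sc2$pi_raw * 1000)
})

test_that("Watterson's estimator is S over the harmonic number", {
  expect_equal(theta_watterson(19, 20), 19 / sum(1 / (1:19)))
})
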