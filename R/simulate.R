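#' Simulation configuration
#'
#' Bundles the knobs shared by the synthetic-data generators. All
#' generators are seed-deterministic: the same config yields byte-identical
#' outputs.
#'
#' @param seed integer RNG seed.
#' @param n_samples sampled sequences (coalescent) or reads per sample.
#' @param sequence_length alignment length in bp (multiple of 3 for
#'   CDS-mode alignments).
#' @param theta population mutation parameter (per locus, > 0 unless the
#'   zero-mutation limit is wanted).
#' @param domain_layout optional `data.frame` with `name`, `start`, `end`,
#'   `rate_multiplier` for regionally elevated mutation rates.
#' @param junction_mixture named numeric vector of expected junction
#'   proportions (`annotated` plus `shift<k>` entries, summing to <= 1).
#' @param read_depth junction-spanning reads to simulate.
#' @param noise_n number of sub-threshold noise variants for variant-table
#'   simulation.
#' @return list of class `SimulationConfig`.
#' @export
simulation_config <- function(seed = 1L, n_samples = 20L,
                              sequence_length = 999L, theta = 5,
                              domain_layout = NULL,
                              junction_mixture = c(annotated = 0.99,
                                                   shift13 = 0.01),
                              read_depth = 10000L, noise_n = 50L) {
  if (theta < 0) ck_stop("theta must be nonnegative", "bad_input")
  if (sum(junction_mixture) > 1 + 1e-9)
    ck_stop("junction_mixture proportions must sum to <= 1", "bad_input")
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 sequence_length = as.integer(sequence_length), theta = theta,
                 domain_layout = domain_layout,
                 junction_mixture = junction_mixture,
                 read_depth = as.integer(read_depth),
                 noise_n = as.integer(noise_n)),
            class = "SimulationConfig")
}

#' Simulate a neutral coalescent alignment
#'
#' Hudson's algorithm: exponential coalescence times for a sample of size
#' n, infinite-sites mutations placed as Poisson(theta * L / 2) with L the
#' total branch length (time in units of 2N generations), each mutation
#' assigned to a uniformly chosen branch point and a distinct site. Under
#' this null, E[S] = theta * a1. Optional per-domain rate multipliers
#' reweight the site where each mutation lands, emulating regionally
#' relaxed or elevated substitution density.
#'
#' @param cfg a [simulation_config()].
#' @return a [coding_alignment()] of `n_samples` sequences.
#' @export
simulate_coalescent_alignment <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_samples
  if (n < 2) ck_stop("need at least 2 samples", "insufficient_samples")
  L <- cfg$sequence_length
  # genealogy: active lineages hold the leaf sets below them
  active <- lapply(seq_len(n), identity)
  branches <- list()  # each: leaves (tip set), length (time span)
  k <- n; t_now <- 0
  births <- rep(0, n)  # time each active lineage was created
  while (k > 1) {
    t_now <- t_now + stats::rexp(1, rate = k * (k - 1) / 2)
    pair <- sample.int(k, 2)
    for (p in pair)
      branches[[length(branches) + 1]] <- list(leaves = active[[p]],
                                               len = t_now - births[p])
    merged <- c(active[[pair[1]]], active[[pair[2]]])
    active <- c(active[-pair], list(merged))
    births <- c(births[-pair], t_now)
    k <- k - 1
  }
  blens <- vapply(branches, `[[`, numeric(1), "len")
  total_len <- sum(blens)
  n_mut <- stats::rpois(1, cfg$theta * total_len / 2)
  # per-site landing weights
  w <- rep(1, L)
  if (!is.null(cfg$domain_layout))
    for (i in seq_len(nrow(cfg$domain_layout))) {
      d <- cfg$domain_layout[i, ]
      w[d$start:d$end] <- w[d$start:d$end] * d$rate_multiplier
    }
  anc <- sample(BASES, L, replace = TRUE)
  seqs <- matrix(rep(anc, n), nrow = n, byrow = TRUE)
  if (n_mut > 0) {
    n_mut <- min(n_mut, L)  # infinite-sites: distinct sites
    sites <- sample.int(L, n_mut, prob = w)
    hit_branch <- sample.int(length(branches), n_mut, replace = TRUE,
                             prob = blens)
    for (m in seq_len(n_mut)) {
      site <- sites[m]
      carriers <- branches[[hit_branch[m]]]$leaves
      derived <- sample(setdiff(BASES, anc[site]), 1)
      seqs[carriers, site] <- derived
    }
  }
  dl <- cfg$domain_layout
  coding_alignment(apply(seqs, 1, paste, collapse = ""),
                   sample_ids = sprintf("s%02d", seq_len(n)),
                   domains = if (!is.null(dl)) dl[c("name", "start", "end")])
}

#' Simulate a gene with junction-spanning reads
#'
#' Emits the multi-exon rescue-fixture gene (GT-AG introns), its genome
#' FASTA and GFF3, and a SAM file of reads spanning the second intron whose
#' junction choice is drawn multinomially from `cfg$junction_mixture`
#' (`annotated`, or `shift<k>` for a donor moved k bases into the exon) at
#' depth `cfg$read_depth`.
#'
#' @param cfg a [simulation_config()].
#' @param out_dir output directory (created if needed).
#' @param sample sample label (used in file names).
#' @return list with `model`, `genome`, paths `fasta`, `gff3`, `sam`, and
#'   `truth` (the mixture actually drawn, as counts per junction).
#' @export
simulate_gene_with_reads <- function(cfg, out_dir = tempfile("reads"),
                                     sample = "sample1") {
  set.seed(cfg$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fx <- rescue_fixture()
  model <- fx$model; genome <- fx$genome
  mix <- cfg$junction_mixture
  if (sum(mix) < 1) mix <- c(mix, other = 1 - sum(mix))
  depth <- cfg$read_depth
  counts <- if (depth > 0)
    as.vector(stats::rmultinom(1, depth, mix)) else rep(0L, length(mix))
  names(counts) <- names(mix)
  counts <- counts[names(counts) != "other"]
  anchor <- 40L
  donor <- fx$intron2[1]; acceptor <- fx$intron2[2]
  sam <- file.path(out_dir, paste0(sample, ".sam"))
  lines <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", model$chrom, nchar(genome)))
  rid <- 0L
  for (jn in names(counts)) {
    shift <- if (jn == "annotated") 0L else as.integer(sub("^shift", "", jn))
    js <- donor - shift; je <- acceptor
    ilen <- je - js + 1L
    start <- js - anchor
    seqread <- paste0(substr(genome, start, js - 1L),
                      substr(genome, je + 1L, je + anchor))
    cigar <- sprintf("%dM%dN%dM", anchor, ilen, anchor)
    for (r in seq_len(counts[[jn]])) {
      rid <- rid + 1L
      lines <- c(lines, paste(sprintf("r%06d", rid), 0, model$chrom, start, 60,
                              cigar, "*", 0, 0, seqread,
                              strrep("I", nchar(seqread)), sep = "\t"))
    }
  }
  writeLines(lines, sam)
  fasta <- file.path(out_dir, "genome.fa")
  ss <- Biostrings::DNAStringSet(genome); names(ss) <- model$chrom
  Biostrings::writeXStringSet(ss, fasta)
  gff3 <- file.path(out_dir, "gene.gff3")
  write_gene_model(model, gff3)
  list(model = model, genome = genome, fasta = fasta, gff3 = gff3, sam = sam,
       truth = counts)
}

#' Simulate mutant and wild-type variant tables
#'
#' Planted edits are emitted as clean homozygous calls safely above every
#' filter threshold (alt reads >= 5, MQ >= 55, EMD >= 0.95); noise variants
#' each violate exactly one named threshold (too few alt reads, low mapping
#' quality, low matched degree, heterozygous call, or identical to a
#' wild-type non-reference call), so the effective-mutation filter must
#' recover exactly the planted set. A truth sidecar records every record's
#' label and expected verdict.
#'
#' @param cfg a [simulation_config()]; `cfg$noise_n` noise records.
#' @param planted_edits `data.frame` with `chrom`, `pos`, `ref`, `alt`
#'   (distinct positions), or a list of [edit_event()] objects.
#' @param out_dir output directory.
#' @return list with paths `mutant_vcf`, `wildtype_vcf`, `truth_tsv` and
#'   the `truth` `data.frame`.
#' @export
simulate_variant_table <- function(cfg, planted_edits,
                                   out_dir = tempfile("variants")) {
  set.seed(cfg$seed + 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.list(planted_edits) && inherits(planted_edits[[1]], "EditEvent"))
    planted_edits <- do.call(rbind, lapply(planted_edits, function(e)
      data.frame(chrom = e$chrom, pos = e$pos,
                 ref = if (nchar(e$ref_allele)) e$ref_allele else "N",
                 alt = if (nchar(e$alt_allele)) e$alt_allele else "N",
                 stringsAsFactors = FALSE)))
  if (anyDuplicated(planted_edits$pos))
    ck_stop("planted edits must have distinct positions", "bad_input")
  planted <- data.frame(planted_edits,
                        sample = "mutant", genotype = "hom_alt",
                        alt_read_count = 5L + stats::rpois(nrow(planted_edits), 5),
                        mapping_quality = 55 + stats::rnorm(nrow(planted_edits), 3, 1),
                        emd = pmin(1, 0.95 + stats::runif(nrow(planted_edits), 0, 0.05)),
                        label = "planted", stringsAsFactors = FALSE)
  kinds <- c("low_reads", "low_mq", "low_emd", "het", "same_as_wt")
  nn <- cfg$noise_n
  noise <- NULL
  if (nn > 0) {
    pos_pool <- setdiff(seq(1000, 1000 + 10 * (nn + nrow(planted)), by = 10),
                        planted_edits$pos)
    pos <- sample(pos_pool, nn)
    kind <- rep_len(kinds, nn)
    ref <- sample(BASES, nn, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), character(1))
    noise <- data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
                        sample = "mutant",
                        genotype = ifelse(kind == "het", "het", "hom_alt"),
                        alt_read_count = ifelse(kind == "low_reads", 3L,
                                                5L + stats::rpois(nn, 5)),
                        mapping_quality = ifelse(kind == "low_mq", 49,
                                                 55 + abs(stats::rnorm(nn, 3, 1))),
                        emd = ifelse(kind == "low_emd", 0.89,
                                     pmin(1, 0.95 + stats::runif(nn, 0, 0.05))),
                        label = kind, stringsAsFactors = FALSE)
  }
  mut <- rbind(planted[names(planted)], if (!is.null(noise)) noise[names(planted)])
  # wild-type calls: hom_ref everywhere except the same_as_wt sites
  wt <- mut
  wt$sample <- "wildtype"
  same <- mut$label == "same_as_wt"
  wt$genotype <- ifelse(same, "hom_alt", "hom_ref")
  wt$alt_read_count <- ifelse(same, 10L, 0L)
  wt$mapping_quality <- 60; wt$emd <- 0.99
  mutant_vcf <- file.path(out_dir, "mutant.vcf")
  wildtype_vcf <- file.path(out_dir, "wildtype.vcf")
  write_variant_vcf(mut, mutant_vcf, sample = "mutant")
  write_variant_vcf(wt, wildtype_vcf, sample = "wildtype")
  truth <- data.frame(chrom = mut$chrom, pos = mut$pos, label = mut$label,
                      expected_pass = mut$label == "planted",
                      stringsAsFactors = FALSE)
  truth <- truth[order(truth$chrom, truth$pos), ]
  truth_tsv <- file.path(out_dir, "truth.tsv")
  utils::write.table(truth, truth_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  list(mutant_vcf = mutant_vcf, wildtype_vcf = wildtype_vcf,
       truth_tsv = truth_tsv, truth = truth)
}
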