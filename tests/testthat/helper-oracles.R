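# Independent oracles used to pin expected values. These deliberately avoid
# the package's own code paths: translation goes through seqinr, pathway
# enumeration is a direct DFS over substitution orderings, and distances are
# evaluated from the closed forms inline.

oracle_translate_codon <- function(codon) {
  seqinr::translate(seqinr::s2c(codon))
}

# Nei-Gojobori site and difference counting, brute force.
oracle_ng_counts <- function(cds1, cds2) {
  codons1 <- substring(cds1, seq(1, nchar(cds1), 3), seq(3, nchar(cds1), 3))
  codons2 <- substring(cds2, seq(1, nchar(cds2), 3), seq(3, nchar(cds2), 3))
  syn_sites <- function(codon) {
    b <- seqinr::s2c(codon)
    aa <- oracle_translate_codon(codon)
    s <- 0
    for (i in 1:3) for (alt in setdiff(c("A", "C", "G", "T"), b[i])) {
      m <- b; m[i] <- alt
      if (oracle_translate_codon(paste(m, collapse = "")) == aa) s <- s + 1 / 3
    }
    s
  }
  # DFS over all substitution orderings between two codons, skipping
  # orderings that pass through a stop codon (fall back to all if none valid)
  path_counts <- function(c1, c2, allow_stop = FALSE) {
    b1 <- seqinr::s2c(c1); b2 <- seqinr::s2c(c2)
    res <- list()
    dfs <- function(cur, remaining, sd, nd) {
      if (!length(remaining)) { res[[length(res) + 1]] <<- c(sd, nd); return() }
      for (i in seq_along(remaining)) {
        p <- remaining[i]
        nxt <- cur; nxt[p] <- b2[p]
        aa_next <- oracle_translate_codon(paste(nxt, collapse = ""))
        if (!allow_stop && aa_next == "*" && length(remaining) > 1) next
        aa_cur <- oracle_translate_codon(paste(cur, collapse = ""))
        dfs(nxt, remaining[-i], sd + (aa_cur == aa_next), nd + (aa_cur != aa_next))
      }
    }
    dfs(b1, which(b1 != b2), 0, 0)
    if (!length(res)) return(path_counts(c1, c2, allow_stop = TRUE))
    m <- do.call(rbind, res)
    c(sd = mean(m[, 1]), nd = mean(m[, 2]))
  }
  S_sites <- (sum(vapply(codons1, syn_sites, numeric(1))) +
              sum(vapply(codons2, syn_sites, numeric(1)))) / 2
  diffs <- mapply(path_counts, codons1, codons2)
  list(s_sites = S_sites, n_sites = 3 * length(codons1) - S_sites,
       sd = sum(diffs["sd", ]), nd = sum(diffs["nd", ]))
}

# random in-frame CDS without stop codons
random_cds <- function(n_codons) {
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   names(which(Biostrings::GENETIC_CODE == "*")))
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# mutate a CDS at k codon positions without creating stops
mutate_cds <- function(cds, k) {
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   names(which(Biostrings::GENETIC_CODE == "*")))
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  idx <- sample(seq_along(codons), k)
  codons[idx] <- sample(sense, k, replace = TRUE)
  paste(codons, collapse = "")
}

# Tajima's D assembled from scratch: hand-counted pairwise differences and
# segregating sites on complete columns, constants written out directly.
oracle_tajimas_d <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  keep <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  S <- sum(apply(m, 2, function(col) length(unique(col)) > 1))
  if (S == 0) return(NA_real_)
  diffs <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) diffs <- c(diffs, sum(m[i, ] != m[j, ]))
  khat <- mean(diffs)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (khat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# random alignment with given per-site mutation probability
random_alignment <- function(n, len, p_mut = 0.05) {
  anc <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    s <- anc
    hit <- runif(len) < p_mut
    s[hit] <- vapply(s[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- paste0("s", seq_len(n))
  seqs
}

# splice-then-translate oracle for frame restoration on the rescue fixture:
# apply the edit to the genome, shorten the host exon by `shift`, splice,
# translate, and call it restored when translation terminates exactly at
# the transcript's final codon with no premature stop.
oracle_rescued <- function(fx, edit, shift) {
  ap <- apply_edit(fx$model, fx$genome, edit)
  iso <- ap$model$isoforms[[1]]
  iso$exons$end[2] <- iso$exons$end[2] - shift
  m2 <- gene_model("o", ap$model$chrom, "+", list(o.1 = iso))
  cds <- spliced_cds(m2, ap$genome)
  aa <- seqinr::translate(seqinr::s2c(cds))
  stops <- which(aa == "*")
  length(stops) > 0 && stops[1] == length(aa) && nchar(cds) %% 3 == 0
}

write_sam <- function(path, reads, chrom = "chrS", chrom_len = 400L) {
  lines <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
  for (i in seq_along(reads)) {
    r <- reads[[i]]
    seqlen <- sum(as.integer(
      regmatches(r$cigar, gregexpr("[0-9]+(?=[MIS=X])", r$cigar, perl = TRUE))[[1]]))
    lines <- c(lines, paste(sprintf("r%03d", i), 0, chrom, r$pos, 60, r$cigar,
                            "*", 0, 0, strrep("A", seqlen), strrep("I", seqlen),
                            sep = "\t"))
  }
  writeLines(lines, path)
  path
}
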