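# Nei-Gojobori (1986) synonymous/nonsynonymous distances with equal-weight
# pathway averaging for multi-hit codons.

GC <- Biostrings::GENETIC_CODE
BASES <- c("A", "C", "G", "T")

codon_aa <- function(codon) unname(GC[codon])
is_stop <- function(codon) identical(unname(GC[codon]), "*")

# fraction of synonymous sites per codon: at each position the 3 possible
# changes are scored synonymous/not; changes creating stops count as
# nonsynonymous, so s + n = 3 exactly for every sense codon.
codon_syn_sites <- function(codon) {
  b <- strsplit(codon, "")[[1]]
  aa <- codon_aa(codon)
  s <- 0
  for (pos in 1:3) {
    for (alt in setdiff(BASES, b[pos])) {
      mut <- b; mut[pos] <- alt
      if (identical(codon_aa(paste(mut, collapse = "")), aa)) s <- s + 1 / 3
    }
  }
  s
}

# observed synonymous/nonsynonymous differences between two sense codons,
# averaged over all substitution orderings that avoid stop-codon
# intermediates (all orderings if every pathway is blocked).
codon_path_diffs <- function(c1, c2) {
  b1 <- strsplit(c1, "")[[1]]; b2 <- strsplit(c2, "")[[1]]
  pos <- which(b1 != b2)
  k <- length(pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  perms <- all_permutations(pos)
  tally <- function(require_no_stop) {
    res <- NULL
    for (ord in perms) {
      cur <- b1; sd <- 0; nd <- 0; ok <- TRUE
      for (step in seq_along(ord)) {
        nxt <- cur; nxt[ord[step]] <- b2[ord[step]]
        codon_next <- paste(nxt, collapse = "")
        if (require_no_stop && step < k && is_stop(codon_next)) { ok <- FALSE; break }
        if (identical(codon_aa(paste(cur, collapse = "")), codon_aa(codon_next)))
          sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (ok) res <- rbind(res, c(sd, nd))
    }
    res
  }
  res <- tally(TRUE)
  if (is.null(res)) res <- tally(FALSE)
  c(sd = mean(res[, 1]), nd = mean(res[, 2]))
}

all_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in all_permutations(x[-i])) out <- c(out, list(c(x[i], rest)))
  out
}

split_codons <- function(seq) {
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

#' Nei-Gojobori synonymous and nonsynonymous distances
#'
#' Counts potential synonymous (S) and nonsynonymous (N) sites per codon as
#' the fraction of the nine single-base neighbours that preserve the amino
#' acid, averaged between the two sequences; observed differences at codons
#' differing at more than one position are averaged with equal weight over
#' all substitution orderings that avoid stop-codon intermediates. The
#' resulting proportions pS and pN are Jukes-Cantor corrected to Ks and Ka.
#'
#' Codon pairs containing a gap or N in either sequence are excluded.
#'
#' @param cds1,cds2 in-frame coding sequences of equal length (multiple of
#'   3, no internal stop codons).
#' @return list with `ka`, `ks`, `ka_ks` (`NA` when `ks = 0`), the raw
#'   proportions `pn`, `ps`, site counts `n_sites`, `s_sites`, observed
#'   difference counts `nd`, `sd`, and a `saturated` flag (`TRUE` when pN or
#'   pS reaches 3/4, in which case the corresponding distance is `NA`).
#' @export
nei_gojobori <- function(cds1, cds2) {
  cds1 <- clean_seq(cds1); cds2 <- clean_seq(cds2)
  if (nchar(cds1) != nchar(cds2))
    ck_stop("coding sequences differ in length", "length_mismatch")
  if (nchar(cds1) %% 3 != 0)
    ck_stop("coding sequence length is not a multiple of 3", "bad_frame")
  co1 <- split_codons(cds1); co2 <- split_codons(cds2)
  usable <- !grepl("[^ACGT]", co1) & !grepl("[^ACGT]", co2)
  co1 <- co1[usable]; co2 <- co2[usable]
  if (any(vapply(co1, is_stop, logical(1))) || any(vapply(co2, is_stop, logical(1))))
    ck_stop("internal stop codon in input", "internal_stop")
  s1 <- sum(vapply(co1, codon_syn_sites, numeric(1)))
  s2 <- sum(vapply(co2, codon_syn_sites, numeric(1)))
  s_sites <- (s1 + s2) / 2
  n_sites <- 3 * length(co1) - s_sites
  diffs <- mapply(function(a, b) codon_path_diffs(a, b), co1, co2)
  sd <- sum(diffs["sd", ]); nd <- sum(diffs["nd", ])
  ps <- if (s_sites > 0) sd / s_sites else 0
  pn <- if (n_sites > 0) nd / n_sites else 0
  saturated <- ps >= 0.75 || pn >= 0.75
  ks <- if (ps >= 0.75) NA_real_ else jc_corrected_distance(ps)
  ka <- if (pn >= 0.75) NA_real_ else jc_corrected_distance(pn)
  ka_ks <- if (is.na(ka) || is.na(ks) || ks == 0) NA_real_ else ka / ks
  list(ka = ka, ks = ks, ka_ks = ka_ks, pn = pn, ps = ps,
       n_sites = n_sites, s_sites = s_sites, nd = nd, sd = sd,
       saturated = saturated)
}
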