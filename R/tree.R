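#' Kimura 2-parameter distance
#'
#' K = -(1/2) log(1 - 2P - Q) - (1/4) log(1 - 2Q), with P and Q the
#' proportions of transition and transversion differences over sites valid
#' in both sequences (gaps and N excluded pairwise).
#'
#' @param seq1,seq2 equal-length (aligned) nucleotide strings.
#' @return the K2P distance.
#' @export
k2p_distance <- function(seq1, seq2) {
  a <- strsplit(clean_seq(seq1), "")[[1]]
  b <- strsplit(clean_seq(seq2), "")[[1]]
  if (length(a) != length(b)) ck_stop("sequences differ in length", "length_mismatch")
  ok <- is_base(a) & is_base(b)
  a <- a[ok]; b <- b[ok]
  if (!length(a)) ck_stop("no valid sites shared by the pair", "all_masked")
  diff <- a != b
  transition <- diff & ((a %in% PURINES & b %in% PURINES) |
                        (a %in% PYRIMIDINES & b %in% PYRIMIDINES))
  P <- sum(transition) / length(a)
  Q <- sum(diff & !transition) / length(a)
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0)
    ck_stop("K2P distance is saturated (log argument <= 0)", "saturation")
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

#' Pairwise K2P distance matrix for an alignment
#'
#' @param aln a [coding_alignment()].
#' @return symmetric matrix with sample labels as dimnames.
#' @export
k2p_matrix <- function(aln) {
  n <- length(aln$sequences)
  m <- matrix(0, n, n, dimnames = list(aln$sample_ids, aln$sample_ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    m[i, j] <- m[j, i] <- k2p_distance(aln$sequences[i], aln$sequences[j])
  m
}

validate_distance_matrix <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm))
    ck_stop("distance matrix must be square", "bad_matrix")
  if (is.null(rownames(dm))) {
    rownames(dm) <- colnames(dm) <- paste0("t", seq_len(nrow(dm)))
  }
  if (max(abs(dm - t(dm))) > 1e-8) ck_stop("distance matrix is asymmetric", "bad_matrix")
  if (any(dm < 0)) ck_stop("distance matrix has negative entries", "bad_matrix")
  if (any(abs(diag(dm)) > 1e-12)) ck_stop("distance matrix diagonal must be zero", "bad_matrix")
  dm
}

#' Neighbor-joining tree
#'
#' Saitou & Nei agglomeration on a symmetric distance matrix, returning an
#' unrooted tree in Newick text. Ties in the Q criterion are broken by
#' joining the pair whose (sorted) cluster labels are lexicographically
#' smallest, where a cluster is labelled by its smallest leaf label; a
#' negative branch length is clamped to zero and the deficit moved to the
#' sibling branch so the joined path length is preserved.
#'
#' @param dm symmetric distance matrix with zero diagonal (>= 3 taxa);
#'   dimnames are the leaf labels.
#' @return Newick string (terminated by `;`).
#' @export
neighbor_joining <- function(dm) {
  dm <- validate_distance_matrix(dm)
  if (nrow(dm) < 3) ck_stop("neighbor joining needs at least 3 taxa", "too_few_taxa")
  labels <- rownames(dm)
  frags <- labels          # newick fragment per active node
  minlab <- labels         # smallest constituent leaf label, for tie-breaks
  d <- dm
  while (nrow(d) > 3) {
    N <- nrow(d)
    r <- rowSums(d)
    q <- (N - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(ij) {
      lab <- sort(c(minlab[ij[1]], minlab[ij[2]]))
      paste(lab, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (N - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- d[i, j]; li <- 0 }
    if (lj < 0) { li <- d[i, j]; lj <- 0 }
    if (minlab[j] < minlab[i]) { tmp <- i; i <- j; j <- tmp; tl <- li; li <- lj; lj <- tl }
    frag <- sprintf("(%s:%s,%s:%s)", frags[i], fmt_bl(li), frags[j], fmt_bl(lj))
    newlab <- min(minlab[i], minlab[j])
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(N), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]), c(dnew[keep], 0))
    frags <- c(frags[keep], frag)
    minlab <- c(minlab[keep], newlab)
    rownames(d2) <- colnames(d2) <- minlab
    d <- d2
  }
  # final trifurcation via the three-point formulas
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  v <- pmax(c(v1, v2, v3), 0)
  ord <- order(minlab)
  paste0("(", paste(sprintf("%s:%s", frags[ord], vapply(v[ord], fmt_bl, character(1))),
                    collapse = ","), ");")
}

fmt_bl <- function(x) sprintf("%.10g", x)

#' Write a Newick string to a file
#'
#' @param newick Newick text (from [neighbor_joining()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(newick, path) {
  writeLines(newick, path)
  invisible(path)
}
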