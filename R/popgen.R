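#' Jukes-Cantor corrected distance
#'
#' Corrects an observed proportion of differing sites for multiple hits under
#' the one-parameter substitution model: d = -(3/4) log(1 - 4p/3).
#'
#' @param p proportion of differing sites, `0 <= p < 0.75`.
#' @return corrected distance per site (`d >= p`).
#' @examples
#' jc_corrected_distance(0.3) # 0.3831...
#' @export
jc_corrected_distance <- function(p) {
  if (any(p < 0)) ck_stop("p must be nonnegative", "domain")
  if (any(p >= 0.75))
    ck_stop("p >= 3/4: Jukes-Cantor correction is saturated", "saturation")
  -0.75 * log(1 - 4 * p / 3)
}

# per-pair proportion of differing sites with pairwise gap/N exclusion;
# returns c(diffs, valid_sites)
pair_diff <- function(a, b) {
  ok <- is_base(a) & is_base(b)
  c(diffs = sum(a[ok] != b[ok]), valid = sum(ok))
}

#' Nucleotide diversity (pi)
#'
#' Mean over all unordered sample pairs of the per-site difference
#' proportion. Sites with a gap or N in either member of a pair are excluded
#' for that pair (pairwise deletion). With `corrected = TRUE` each pairwise
#' proportion is Jukes-Cantor corrected before averaging.
#'
#' @param aln a [coding_alignment()].
#' @param region optional name of a declared domain; statistics are then
#'   restricted to that interval.
#' @param corrected apply the Jukes-Cantor correction per pair.
#' @return per-site diversity; `NA` if every site is masked for some pair.
#' @export
nucleotide_diversity <- function(aln, region = NULL, corrected = FALSE) {
  if (!is.null(region)) aln <- extract_region(aln, region)
  m <- seq_matrix(aln$sequences)
  n <- nrow(m)
  if (n < 2) ck_stop("nucleotide diversity needs at least 2 samples", "insufficient_samples")
  vals <- numeric(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- pair_diff(m[i, ], m[j, ])
    if (d["valid"] == 0) return(NA_real_)
    p <- unname(d["diffs"] / d["valid"])
    vals <- c(vals, if (corrected) jc_corrected_distance(p) else p)
  }
  mean(vals)
}

extract_region <- function(aln, region) {
  if (is.null(aln$domains) || !region %in% aln$domains$name)
    ck_stop(sprintf("region '%s' is not a declared domain", region), "unknown_region")
  r <- aln$domains[aln$domains$name == region, ][1, ]
  subset_alignment(aln, r$start, r$end)
}

# columns free of gaps and N across all samples (complete deletion)
complete_columns <- function(m) {
  apply(m, 2, function(col) all(is_base(col)))
}

#' Segregating sites under complete deletion
#'
#' @param aln a [coding_alignment()].
#' @return number of polymorphic columns after removing any column with a
#'   gap or N in any sample.
#' @export
segregating_sites <- function(aln) {
  m <- seq_matrix(aln$sequences)
  m <- m[, complete_columns(m), drop = FALSE]
  if (ncol(m) == 0) return(0L)
  sum(apply(m, 2, function(col) length(unique(col)) > 1))
}

#' Tajima's D constants
#'
#' The a1..e2 normalising constants of the D statistic for sample size `n`.
#'
#' @param n number of sampled sequences (`n >= 4`).
#' @return named list with `a1, a2, b1, b2, c1, c2, e1, e2`.
#' @export
tajima_constants <- function(n) {
  if (n < 4) ck_stop("Tajima's D requires n >= 4", "insufficient_samples")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Tajima's D
#'
#' Normalised difference between the mean pairwise difference count and the
#' scaled number of segregating sites. Columns containing any gap or N are
#' removed before counting (complete deletion); the pairwise count is
#' uncorrected, as in the original statistic.
#'
#' @param aln a [coding_alignment()] with `n >= 4` samples.
#' @return the D statistic, or `NA` when there is no polymorphism.
#' @export
tajimas_d <- function(aln) {
  m <- seq_matrix(aln$sequences)
  n <- nrow(m)
  k <- tajima_constants(n) # validates n
  m <- m[, complete_columns(m), drop = FALSE]
  S <- if (ncol(m)) sum(apply(m, 2, function(col) length(unique(col)) > 1)) else 0L
  if (S == 0) return(NA_real_)
  # mean pairwise difference count over complete columns
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(m[i, ] != m[j, ])
    np <- np + 1
  }
  khat <- tot / np
  (khat - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Watterson's estimator
#'
#' @param S number of segregating sites.
#' @param n sample count.
#' @return `S / a1`, the per-region estimate of theta.
#' @export
theta_watterson <- function(S, n) {
  i <- seq_len(n - 1)
  S / sum(1 / i)
}
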