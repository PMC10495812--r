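#' Squared codominant genotype distance
#'
#' Inter-individual squared distance in the Smouse-Peakall codominant
#' convention: per locus, genotypes are allele-count vectors `c` and
#' `d2 = sum((c_i - c_j)^2)/2` (0 for identical genotypes, 1 for one shared
#' allele with one substituted, 4 for opposite homozygotes), summed over
#' loci. Pairs missing a locus in either individual drop that locus
#' (pairwise deletion).
#'
#' @param x an [msat_table()].
#' @return an `n x n` symmetric matrix of squared distances.
#' @export
genotype_dist <- function(x) {
  n <- n_ind(x); L <- n_loci(x)
  d2 <- matrix(0, n, n)
  for (l in seq_len(L)) {
    a1 <- x$alleles[, l, 1L]; a2 <- x$alleles[, l, 2L]
    ok <- !is.na(a1)
    states <- sort(unique(c(a1[ok], a2[ok])))
    if (!length(states)) next
    cnt <- matrix(0L, n, length(states))
    cnt[cbind(seq_len(n), match(a1, states))] <- cnt[cbind(seq_len(n), match(a1, states))] + 1L
    cnt[cbind(seq_len(n), match(a2, states))] <- cnt[cbind(seq_len(n), match(a2, states))] + 1L
    okm <- outer(ok, ok, "&")
    # squared Euclidean distance on count vectors, halved
    g <- tcrossprod(cnt)
    sq <- diag(g)
    dl <- (outer(sq, sq, "+") - 2 * g) / 2
    dl[!okm] <- 0
    d2 <- d2 + dl
  }
  dimnames(d2) <- list(x$ids, x$ids)
  d2
}

#' Squared allele-size distance between individuals
#'
#' Sum over loci of the squared difference of individual mean allele sizes
#' times 2 plus within-individual squared spread; used only for reporting.
#' For RST itself gene copies are analysed directly (see
#' [rst_permutation_test()]).
#' @noRd
allele_size_dist <- function(x) {
  n <- n_ind(x)
  d2 <- matrix(0, n, n)
  for (l in seq_len(n_loci(x))) {
    a1 <- x$alleles[, l, 1L]; a2 <- x$alleles[, l, 2L]
    ok <- !is.na(a1)
    okm <- outer(ok, ok, "&")
    dl <- outer(a1, a1, "-")^2 + outer(a2, a2, "-")^2
    dl[!okm] <- 0
    d2 <- d2 + dl
  }
  d2
}
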