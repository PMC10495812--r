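#' Multiallelic Weir-Cockerham theta (FST)
#'
#' Moment estimator of Wright's FST from allele frequencies, combining
#' loci and alleles as a ratio of summed variance components (Weir &
#' Cockerham 1984, ignoring the within-individual component by using the
#' allele-frequency form with heterozygosity correction).
#'
#' @param x an [msat_table()].
#' @param by stratification, `"pop"` or `"group"`.
#' @return estimate of theta (can be slightly negative near zero
#'   differentiation).
#' @export
wright_fst <- function(x, by = c("group", "pop")) {
  by <- match.arg(by)
  f <- strata_labels(x, by)
  demes <- unique(f)
  r <- length(demes)
  if (r < 2L) stop_input("need at least 2 strata")
  num <- den <- 0
  for (l in seq_len(n_loci(x))) {
    a1 <- x$alleles[, l, 1L]; a2 <- x$alleles[, l, 2L]
    ok <- !is.na(a1)
    states <- sort(unique(c(a1[ok], a2[ok])))
    if (length(states) < 2L) next
    n_i <- vapply(demes, function(d) sum(ok & f == d), numeric(1))
    if (any(n_i < 1)) next
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    for (s in states) {
      p_i <- vapply(demes, function(d) {
        rows <- which(ok & f == d)
        mean(c(a1[rows], a2[rows]) == s)
      }, numeric(1))
      h_i <- vapply(demes, function(d) {
        rows <- which(ok & f == d)
        mean((a1[rows] == s) != (a2[rows] == s))
      }, numeric(1))
      pbar <- sum(n_i * p_i) / (r * nbar)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / (r * nbar)
      a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                               hbar / 4) / (nbar - 1))
      b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

#' Nei's GST between strata
#'
#' `GST = (HT - HS)/HT` with `HS` the unweighted mean within-stratum gene
#' diversity and `HT` the gene diversity of unweighted mean allele
#' frequencies, averaged over loci as a ratio of means.
#'
#' @param x an [msat_table()].
#' @param by `"group"` or `"pop"`.
#' @return GST in `[0, 1]` (clamped at 0).
#' @export
nei_gst <- function(x, by = c("group", "pop")) {
  by <- match.arg(by)
  f <- strata_labels(x, by)
  demes <- unique(f)
  if (length(demes) < 2L) stop_input("need at least 2 strata")
  ht_sum <- hs_sum <- 0
  for (l in seq_len(n_loci(x))) {
    freqs <- lapply(demes, function(d) locus_freqs(x, l, which(f == d)))
    states <- sort(unique(unlist(lapply(freqs, names))))
    if (!length(states)) next
    pm <- vapply(freqs, function(p) {
      v <- setNames(numeric(length(states)), states)
      v[names(p)] <- p
      v
    }, numeric(length(states)))
    pm <- matrix(pm, nrow = length(states))
    hs <- mean(1 - colSums(pm^2))
    pbar <- rowMeans(pm)
    ht <- 1 - sum(pbar^2)
    hs_sum <- hs_sum + hs
    ht_sum <- ht_sum + ht
  }
  if (ht_sum == 0) return(0)
  max(0, (ht_sum - hs_sum) / ht_sum)
}

# recode alleles so each stratum's alleles are private to it (frequencies
# preserved); basis of the maximal-differentiation standardization
recode_private <- function(x, f) {
  g_idx <- match(f, unique(f))
  a <- x$alleles
  for (l in seq_len(n_loci(x))) {
    for (k in 1:2) {
      v <- a[, l, k]
      ok <- !is.na(v)
      key <- paste(g_idx[ok], v[ok])
      a[ok, l, k] <- as.integer(factor(key, levels = unique(key)))
    }
  }
  msat_table(a, ids = x$ids, loci = x$loci, pop = x$pop, group = x$group,
             coords = x$coords, repeat_unit = 1L)
}

# allele-identity squared distance between gene copies (2n x 2n, 0/1 per
# locus summed over loci, pairwise deletion); copy i and copy n+i belong
# to individual i
allele_identity_dist <- function(x) {
  n <- n_ind(x)
  d2 <- matrix(0, 2L * n, 2L * n)
  for (l in seq_len(n_loci(x))) {
    v <- c(x$alleles[, l, 1L], x$alleles[, l, 2L])
    ok <- !is.na(v)
    dl <- 1 * outer(v, v, "!=")
    dl[!ok, ] <- 0; dl[, !ok] <- 0
    d2 <- d2 + dl
  }
  d2
}

#' AMOVA-based FST between groups and its standardized form F'ST
#'
#' `fst_amova()` is the among-group fixation index of an AMOVA at the
#' gene-copy level (each allele copy is a unit; distance is allele
#' non-identity summed over loci), which is on the Wright FST scale --
#' distinct from the individual-level codominant-distance AMOVA of
#' [amova()], whose among fraction is the phi-statistic used for
#' variance-percentage reporting. `fst_prime()` divides FST by the
#' maximum attainable value `FST(max)`, obtained by re-running the same
#' AMOVA on a table recoded so that every group's alleles are private to it
#' (allele frequencies preserved) -- the Meirmans standardization.
#'
#' @param x an [msat_table()].
#' @param by `"group"` or `"pop"`.
#' @return `fst_prime()` returns a list with `fst`, `fst_max` and
#'   `fst_prime` (`NA` with all loci monomorphic).
#' @export
fst_amova <- function(x, by = c("group", "pop")) {
  f <- strata_labels(x, match.arg(by))
  res <- amova_dist(allele_identity_dist(x), pop = rep(f, 2L), n_perm = 0L)
  unname(res$phi["phi_ST"])
}

#' @rdname fst_amova
#' @export
fst_prime <- function(x, by = c("group", "pop")) {
  by <- match.arg(by)
  f <- strata_labels(x, by)
  fst <- fst_amova(x, by)
  xr <- recode_private(x, f)
  fst_max <- fst_amova(xr, by)
  if (!is.finite(fst_max) || fst_max <= 0)
    return(list(fst = fst, fst_max = fst_max, fst_prime = NA_real_))
  list(fst = fst, fst_max = fst_max, fst_prime = fst / fst_max)
}
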