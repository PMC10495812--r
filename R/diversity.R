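# allele frequencies at one locus within a set of rows; named numeric
locus_freqs <- function(x, locus, rows = seq_len(n_ind(x))) {
  a <- c(x$alleles[rows, locus, 1L], x$alleles[rows, locus, 2L])
  a <- a[!is.na(a)]
  if (!length(a)) return(numeric(0))
  tab <- table(a)
  setNames(as.numeric(tab) / sum(tab), names(tab))
}

#' Per-locus, per-stratum diversity statistics
#'
#' Computes, for each locus within each stratum, the number of alleles
#' (`Na`), effective number of alleles (`Ne = 1/sum(p^2)`), observed
#' heterozygosity (`Ho`), expected heterozygosity (`He = 1 - sum(p^2)`,
#' optionally with the small-sample `2n/(2n-1)` correction) and the
#' inbreeding coefficient `FIS = (He - Ho)/He` (NA-flagged when `He = 0`).
#' Frequencies use non-missing gene copies; `Ho` is the heterozygote
#' fraction among non-missing genotypes.
#'
#' @param x an [msat_table()].
#' @param by stratification: `"pop"`, `"group"` or `"total"`.
#' @param unbiased apply the `2n/(2n-1)` correction to He (off by default,
#'   matching the uncorrected Nei gene-diversity convention).
#' @return a `diversity_report`: data frame with one row per
#'   stratum x locus plus `"mean"` rows per stratum.
#' @export
diversity <- function(x, by = c("pop", "group", "total"), unbiased = FALSE) {
  by <- match.arg(by)
  strata <- strata_labels(x, by)
  out <- list()
  for (s in unique(strata)) {
    rows <- which(strata == s)
    per <- lapply(seq_len(n_loci(x)), function(l) {
      locus_diversity(x, l, rows, unbiased = unbiased)
    })
    df <- do.call(rbind, per)
    df$locus <- x$loci
    df$stratum <- s
    means <- data.frame(
      Na = mean(df$Na, na.rm = TRUE), Ne = mean(df$Ne, na.rm = TRUE),
      Ho = mean(df$Ho, na.rm = TRUE), He = mean(df$He, na.rm = TRUE),
      Fis = mean(df$Fis, na.rm = TRUE),
      n_typed = mean(df$n_typed), locus = "mean", stratum = s)
    out[[s]] <- rbind(df, means)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- res[, c("stratum", "locus", "n_typed", "Na", "Ne", "Ho", "He", "Fis")]
  class(res) <- c("diversity_report", "data.frame")
  res
}

locus_diversity <- function(x, locus, rows, unbiased = FALSE) {
  a1 <- x$alleles[rows, locus, 1L]; a2 <- x$alleles[rows, locus, 2L]
  ok <- !is.na(a1)
  n_typed <- sum(ok)
  if (n_typed == 0L)
    return(data.frame(Na = NA_real_, Ne = NA_real_, Ho = NA_real_,
                      He = NA_real_, Fis = NA_real_, n_typed = 0))
  p <- locus_freqs(x, locus, rows)
  sp2 <- sum(p^2)
  he <- 1 - sp2
  if (unbiased) {
    nc <- 2 * n_typed
    he <- he * nc / (nc - 1)
  }
  ho <- mean(a1[ok] != a2[ok])
  data.frame(
    Na = length(p), Ne = 1 / sp2, Ho = ho, He = he,
    Fis = if (he > 0) (he - ho) / he else NA_real_,
    n_typed = n_typed)
}

#' @export
print.diversity_report <- function(x, digits = 3, ...) {
  cat("Diversity report (", length(unique(x$stratum)), " strata)\n", sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Monte-Carlo Hardy-Weinberg test at one locus in one population
#'
#' The 2n non-missing gene copies are repeatedly shuffled into random
#' diploids; the test statistic is the absolute deviation of the
#' heterozygote count from its expectation under random pairing, and the
#' p-value is `(#{perm >= obs} + 1)/(n_perm + 1)` (two-sided by
#' construction). A Monte-Carlo stand-in for the classical exact test.
#'
#' @param x an [msat_table()].
#' @param locus locus name or index.
#' @param pop population label (NULL uses all individuals).
#' @param n_perm number of shuffles (must be >= 1).
#' @param seed optional RNG seed.
#' @return list with `p`, `het_obs`, `het_expected`, `n`, and `monomorphic`
#'   flag (p = 1 when the locus has a single allele).
#' @export
hwe_test <- function(x, locus, pop = NULL, n_perm = 999L, seed = NULL) {
  if (!is_count(n_perm)) stop_input("`n_perm` must be a positive count")
  if (is.character(locus)) locus <- match(locus, x$loci)
  rows <- if (is.null(pop)) seq_len(n_ind(x)) else which(x$pop == pop)
  a1 <- x$alleles[rows, locus, 1L]; a2 <- x$alleles[rows, locus, 2L]
  ok <- !is.na(a1)
  copies <- c(a1[ok], a2[ok])
  n <- sum(ok)
  if (n < 2L) stop_input("fewer than 2 genotypes at this locus/population")
  counts <- table(copies)
  m <- 2L * n
  # E[het] under random pairing without replacement
  e_het <- n * (1 - sum(as.numeric(counts) * (as.numeric(counts) - 1)) /
                  (m * (m - 1)))
  if (length(counts) == 1L)
    return(list(p = 1, het_obs = 0L, het_expected = 0, n = n,
                monomorphic = TRUE))
  obs <- abs(sum(a1[ok] != a2[ok]) - e_het)
  with_seed(seed, {
    perm <- replicate(n_perm, {
      s <- sample(copies)
      abs(sum(s[seq_len(n)] != s[n + seq_len(n)]) - e_het)
    })
    list(p = perm_pvalue(perm, obs),
         het_obs = sum(a1[ok] != a2[ok]), het_expected = e_het, n = n,
         monomorphic = FALSE)
  })
}

#' Sequential Bonferroni (Holm) adjustment in the Rice (1989) ordering
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values in the input order.
#' @export
sequential_bonferroni <- function(p) stats::p.adjust(p, method = "holm")
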