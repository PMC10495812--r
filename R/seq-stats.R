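# Chloroplast-sequence diversity statistics. Site policy follows the
# complete-deletion convention: columns containing a gap or N are excluded
# alignment-wide before nucleotide statistics; haplotype collapse keeps
# gap characters (indel haplotypes are distinct) but masks N columns.

usable_sites <- function(m, exclude = c("-", "N")) {
  keep <- !apply(m, 2, function(col) any(col %in% exclude))
  which(keep)
}

#' Collapse identical sequences into haplotypes
#'
#' Sequences identical over the comparable sites share a haplotype id.
#' Columns containing `N` are masked before comparison (missing-data
#' policy); gap characters are retained so indel variants remain distinct
#' haplotypes.
#'
#' @param aln a [seq_alignment()].
#' @param mask_n drop N-containing columns before comparing (default TRUE).
#' @return list with `haplotype` (integer id per sequence, first-occurrence
#'   order), `freqs` (counts per haplotype) and `H` (haplotype count).
#' @export
collapse_haplotypes <- function(aln, mask_n = TRUE) {
  m <- aln$matrix
  if (mask_n) {
    keep <- usable_sites(m, exclude = "N")
    m <- m[, keep, drop = FALSE]
  }
  key <- apply(m, 1, paste, collapse = "")
  hap <- as.integer(factor(key, levels = unique(key)))
  freqs <- as.integer(table(factor(hap, levels = seq_len(max(hap)))))
  list(haplotype = hap, freqs = freqs, H = length(freqs))
}

#' Haplotype (gene) diversity, unbiased form
#'
#' `h = n/(n-1) * (1 - sum((f_i/n)^2))` (Nei's unbiased gene diversity).
#'
#' @param freqs haplotype counts.
#' @param n total sequences (default `sum(freqs)`).
#' @return h in `[0, 1]`; `NA` when `n < 2`.
#' @export
hap_diversity <- function(freqs, n = sum(freqs)) {
  if (sum(freqs) != n) stop_input("`freqs` must sum to `n`")
  if (n < 2) return(NA_real_)
  n / (n - 1) * (1 - sum((freqs / n)^2))
}

# pairwise difference counts over the usable sites; returns list with the
# mean pairwise difference (pi_total) and per-site pi
pairwise_diffs <- function(m) {
  n <- nrow(m)
  L <- ncol(m)
  if (n < 2 || L < 1) return(list(pi_total = NA_real_, pi = NA_real_, L = L))
  # column-wise: mean pairwise difference = sum over sites of 2*sum_a
  # c_a*(n-c_a)/ (n(n-1)) using counts
  total <- 0
  for (j in seq_len(L)) {
    cnt <- table(m[, j])
    total <- total + (choose(n, 2) - sum(choose(as.numeric(cnt), 2)))
  }
  pi_total <- total / choose(n, 2)
  list(pi_total = pi_total, pi = pi_total / L, L = L)
}

#' Nucleotide diversity
#'
#' Average proportion of differing sites over all unordered sequence pairs,
#' after complete deletion of gap/N columns.
#'
#' @param aln a [seq_alignment()].
#' @param per_site return per-site value (default) or the mean number of
#'   pairwise differences (`pi_total`).
#' @return numeric; `NA` if fewer than 2 sequences or no usable sites.
#' @export
nucleotide_diversity <- function(aln, per_site = TRUE) {
  m <- aln$matrix[, usable_sites(aln$matrix), drop = FALSE]
  pd <- pairwise_diffs(m)
  if (per_site) pd$pi else pd$pi_total
}

#' Sequence diversity summary
#'
#' @param aln a [seq_alignment()].
#' @return a `seq_diversity` list: `n`, `H` (haplotypes), `h` (haplotype
#'   diversity), `pi` (per site), `pi_total` (mean pairwise differences),
#'   `S` (segregating sites), `eta` (total mutations, counting all minor
#'   states per site), `eta_s` (singleton mutations), `usable_sites`.
#' @export
seq_diversity <- function(aln) {
  n <- nrow(aln$matrix)
  hap <- collapse_haplotypes(aln)
  m <- aln$matrix[, usable_sites(aln$matrix), drop = FALSE]
  pd <- pairwise_diffs(m)
  S <- eta <- eta_s <- 0L
  for (j in seq_len(ncol(m))) {
    cnt <- table(m[, j])
    if (length(cnt) > 1L) {
      S <- S + 1L
      eta <- eta + length(cnt) - 1L
      minor <- sort(as.integer(cnt), decreasing = TRUE)[-1]
      eta_s <- eta_s + sum(minor == 1L)
    }
  }
  structure(list(n = n, H = hap$H, h = hap_diversity(hap$freqs),
                 pi = pd$pi, pi_total = pd$pi_total,
                 S = S, eta = eta, eta_s = eta_s,
                 usable_sites = ncol(m)),
            class = "seq_diversity")
}

#' @export
print.seq_diversity <- function(x, ...) {
  cat(sprintf(
    "n = %d, H = %d, h = %.4f, pi = %.6g, S = %d, eta = %d, eta_s = %d\n",
    x$n, x$H, x$h, x$pi, x$S, x$eta, x$eta_s))
  invisible(x)
}
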