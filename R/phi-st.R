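# Sequence differentiation by AMOVA on pairwise nucleotide differences.

# n x n matrix of pairwise difference counts over usable sites
seq_diff_matrix <- function(aln) {
  m <- aln$matrix[, usable_sites(aln$matrix), drop = FALSE]
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (j in seq_len(ncol(m))) {
    neq <- outer(m[, j], m[, j], "!=")
    d <- d + neq
  }
  dimnames(d) <- list(aln$ids, aln$ids)
  d
}

#' phiST and standardized phi'ST between sequence groups
#'
#' Two-level AMOVA on pairwise nucleotide-difference distances, with a
#' permutation p-value from shuffling group labels. `phi_st_max` comes
#' from the maximal-differentiation recoding: haplotypes shared between
#' groups are made group-private (so no haplotype is shared across
#' groups) while within-group distances and haplotype frequencies are
#' preserved. `phi_st_prime = phi_st/phi_st_max`; it equals 1 when the
#' groups already share no haplotypes.
#'
#' @param aln a [seq_alignment()].
#' @param grouping label per sequence, or `"clade"` / `"pop"` to use the
#'   alignment's own labels.
#' @param n_perm label permutations.
#' @param seed optional RNG seed.
#' @return list with `phi_st`, `phi_st_max`, `phi_st_prime`, `p`, `n_perm`.
#' @export
phi_st <- function(aln, grouping = "clade", n_perm = 999L, seed = NULL) {
  f <- if (length(grouping) == 1L && is.character(grouping)) {
    lab <- aln[[grouping]]
    if (is.null(lab)) stop_input("alignment has no `", grouping, "` labels")
    lab
  } else as.character(grouping)
  if (length(f) != nrow(aln$matrix)) stop_input("grouping length mismatch")
  sizes <- table(f)
  if (length(sizes) < 2L) stop_input("need at least 2 groups")
  if (any(sizes < 2L))
    stop_input("group of size < 2: ", names(sizes)[which(sizes < 2L)[1]])

  d2 <- seq_diff_matrix(aln)
  res <- amova_dist(d2, pop = f, n_perm = n_perm, seed = seed)
  obs <- unname(res$phi["phi_ST"])

  # maximal-differentiation recoding: within-group distances are kept;
  # haplotypes shared between groups become group-private (distance >= 1
  # mutation between any between-group pair), frequencies preserved
  hap <- collapse_haplotypes(aln)$haplotype
  same_hap <- outer(hap, hap, "==")
  diff_group <- outer(f, f, "!=")
  d2max <- d2
  d2max[same_hap & diff_group] <- 1
  res_max <- amova_dist(d2max, pop = f, n_perm = 0L)
  mx <- unname(res_max$phi["phi_ST"])
  list(phi_st = obs, phi_st_max = mx,
       phi_st_prime = if (is.finite(mx) && mx > 0) obs / mx else NA_real_,
       p = unname(res$p_values["phi_ST"]), n_perm = as.integer(n_perm))
}
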