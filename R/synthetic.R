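# Synthetic-data generators. Defaults emulate the study conditions the
# analysis was designed for: ~467 diploid trees in two clusters typed at 8
# unlinked microsatellite loci with between-group FST around 0.11, and a
# two-clade chloroplast haplotype set that is admixed in space.

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Balding-Nichols (F-model) genotype table
#'
#' For each group and locus, allele frequencies are drawn from a Dirichlet
#' with parameters `p_ancestral * (1 - F)/F`, so that across groups
#' `Var(p) = F * p * (1 - p)` -- giving direct control of the expected
#' Wright FST. Genotypes are then drawn by binomial sampling from the
#' group frequencies (Hardy-Weinberg within groups). `target_fst = 0`
#' uses the ancestral frequencies identically in every group.
#'
#' @param n_ind_per_group diploid sample sizes (length = number of groups);
#'   default two groups of 234 and 233.
#' @param n_loci number of loci.
#' @param target_fst F in `[0, 1)`.
#' @param n_alleles alleles per locus used with the `"uniform-k"` /
#'   `"geometric-k"` ancestral frequency presets.
#' @param ancestral_freqs `"geometric-k"` (default; frequencies
#'   proportional to `freq_ratio^(0:(k-1))`, giving the moderate gene
#'   diversity typical of the emulated dataset), `"uniform-k"`, or a list
#'   of per-locus frequency vectors named by allele size.
#' @param freq_ratio decay ratio of the geometric preset (0.3 yields
#'   ancestral gene diversity near 0.45).
#' @param msat_range integer support from which allele sizes are drawn.
#' @param seed optional RNG seed.
#' @return an [msat_table()] with one population per group.
#' @export
balding_nichols_table <- function(n_ind_per_group = c(234L, 233L),
                                  n_loci = 8L, target_fst = 0.11,
                                  n_alleles = 6L,
                                  ancestral_freqs = "geometric-k",
                                  freq_ratio = 0.3,
                                  msat_range = 10:40, seed = NULL) {
  if (target_fst < 0 || target_fst >= 1)
    stop_input("`target_fst` must be in [0, 1)")
  G <- length(n_ind_per_group)
  if (G < 1L || any(n_ind_per_group < 1L)) stop_input("counts must be positive")
  with_seed(seed, {
    anc <- if (is.character(ancestral_freqs) && length(ancestral_freqs) == 1L) {
      weights <- switch(ancestral_freqs,
        "uniform-k" = rep(1, n_alleles),
        "geometric-k" = freq_ratio^(0:(n_alleles - 1L)),
        stop_input("unknown ancestral frequency preset: ", ancestral_freqs))
      lapply(seq_len(n_loci), function(l) {
        sizes <- sort(sample(msat_range, min(n_alleles, length(msat_range))))
        w <- weights[seq_along(sizes)]
        setNames(sample(w / sum(w)), sizes)  # random size-frequency pairing
      })
    } else {
      if (length(ancestral_freqs) != n_loci)
        stop_input("need one ancestral frequency vector per locus")
      lapply(ancestral_freqs, function(p) {
        if (abs(sum(p) - 1) > 1e-8) stop_input("frequencies must sum to 1")
        p
      })
    }
    n <- sum(n_ind_per_group)
    alleles <- array(NA_integer_, dim = c(n, n_loci, 2L))
    group <- rep(paste0("group", seq_len(G)), n_ind_per_group)
    for (l in seq_len(n_loci)) {
      p0 <- anc[[l]]
      sizes <- as.integer(names(p0))
      row0 <- 0L
      for (g in seq_len(G)) {
        pg <- if (target_fst == 0) unname(p0) else
          rdirichlet1(p0 * (1 - target_fst) / target_fst)
        ng <- n_ind_per_group[g]
        draws <- sample(sizes, 2L * ng, replace = TRUE, prob = pg)
        alleles[row0 + seq_len(ng), l, 1L] <- draws[seq_len(ng)]
        alleles[row0 + seq_len(ng), l, 2L] <- draws[ng + seq_len(ng)]
        row0 <- row0 + ng
      }
    }
    msat_table(alleles, pop = group, group = group, repeat_unit = 1L)
  })
}

#' Two-clade chloroplast alignment, spatially admixed
#'
#' Two star-like haplotype clusters separated by `n_mut_between` fixed
#' differences; within each clade, `n_mut_within` private mutations each
#' define one derived haplotype radiating from the clade founder.
#' Individuals receive random spatial (`pop`) labels, so the clades carry
#' no geographic signal -- mimicking admixed-in-space plastid lineages.
#'
#' @param n_seq sequences (default 172); split between clades via
#'   `clade_fraction`.
#' @param seq_len alignment length (default 2827).
#' @param n_mut_within derived haplotypes per clade (default 22).
#' @param n_mut_between fixed differences between clades (>= 1; default 3).
#' @param clade_fraction fraction of sequences in clade A.
#' @param founder_prob probability a sequence keeps its clade founder
#'   haplotype (rest pick a derived haplotype uniformly).
#' @param n_pops number of random spatial labels.
#' @param seed optional RNG seed.
#' @return a [seq_alignment()] with `clade` and `pop` labels.
#' @export
two_clade_cpdna <- function(n_seq = 172L, seq_len = 2827L,
                            n_mut_within = 22L, n_mut_between = 3L,
                            clade_fraction = 84 / 172, founder_prob = 0.35,
                            n_pops = 6L, seed = NULL) {
  if (n_mut_between < 1L) stop_input("`n_mut_between` must be >= 1")
  need <- n_mut_between + 2L * n_mut_within
  if (seq_len < need)
    stop_input("`seq_len` too small for the requested mutations (need >= ",
               need, ")")
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    founderA <- sample(bases, seq_len, replace = TRUE)
    sites <- sample.int(seq_len, need)
    between_sites <- sites[seq_len(n_mut_between)]
    within_sites <- matrix(sites[-seq_len(n_mut_between)],
                           nrow = max(n_mut_within, 1L))
    founderB <- founderA
    for (s in between_sites)
      founderB[s] <- sample(setdiff(bases, founderA[s]), 1L)
    nA <- round(n_seq * clade_fraction)
    nB <- n_seq - nA
    build_clade <- function(founder, n_cl, site_col) {
      out <- matrix(rep(founder, n_cl), nrow = n_cl, byrow = TRUE)
      if (n_mut_within > 0L && n_cl > 0L) {
        hap_of <- ifelse(runif(n_cl) < founder_prob, 0L,
                         sample.int(n_mut_within, n_cl, replace = TRUE))
        derived <- vapply(seq_len(n_mut_within), function(k) {
          s <- within_sites[k, site_col]
          sample(setdiff(bases, founder[s]), 1L)
        }, character(1))
        for (i in which(hap_of > 0L)) {
          s <- within_sites[hap_of[i], site_col]
          out[i, s] <- derived[hap_of[i]]
        }
      }
      out
    }
    mA <- build_clade(founderA, nA, 1L)
    mB <- build_clade(founderB, nB, 2L)
    m <- rbind(mA, mB)
    clade <- rep(c("cladeA", "cladeB"), c(nA, nB))
    # balanced random allocation so every site holds >= 2 sequences
    pop <- sample(rep(paste0("site", seq_len(n_pops)),
                      length.out = n_seq))
    ord <- sample.int(n_seq)  # spatially admixed: shuffle storage order too
    seq_alignment(m[ord, , drop = FALSE],
                  ids = paste0("seq", seq_len(n_seq)),
                  clade = clade[ord], pop = pop[ord])
  })
}
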