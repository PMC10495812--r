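#' Simulate a diploid microsatellite dataset under a demographic model
#'
#' Independent loci: per-locus mutation rates are drawn from the
#' gamma-heterogeneity model, a genealogy is simulated per locus, GSM
#' mutation is overlaid, and gene copies are paired at random into
#' diploids within each deme (Hardy-Weinberg within demes).
#'
#' @param model a `demographic_model`.
#' @param mutation a [mutation_model()].
#' @param n_loci number of unlinked loci.
#' @param sample_sizes diploid individuals per deme; names become group
#'   labels (defaults `group1`, `group2`).
#' @param root_size repeat count at the root of each genealogy.
#' @param seed optional RNG seed.
#' @return an [msat_table()] with `pop` and `group` set per deme.
#' @export
simulate_msat_dataset <- function(model, mutation, n_loci, sample_sizes,
                                  root_size = 25L, seed = NULL) {
  stopifnot(inherits(model, "demographic_model"),
            inherits(mutation, "mutation_model"), is_count(n_loci))
  sample_sizes <- as.integer(sample_sizes)
  D <- n_demes(model)
  if (length(sample_sizes) != D) stop_input("need ", D, " sample sizes")
  labels <- names(sample_sizes) %||% paste0("group", seq_len(D))
  n <- sum(sample_sizes)
  with_seed(seed, {
    mus <- draw_locus_rates(mutation, n_loci)
    alleles <- array(NA_integer_, dim = c(n, n_loci, 2L))
    copies_per_deme <- 2L * sample_sizes
    for (l in seq_len(n_loci)) {
      gen <- simulate_genealogy(model, copies_per_deme)
      sizes <- overlay_gsm(gen, mus[l], mutation$p_gsm, root_size)
      offset_copy <- 0L; offset_ind <- 0L
      for (d in seq_len(D)) {
        nc <- copies_per_deme[d]
        deme_sizes <- sizes[offset_copy + seq_len(nc)]
        perm <- sample.int(nc)
        paired <- matrix(deme_sizes[perm], ncol = 2L)
        rows <- offset_ind + seq_len(sample_sizes[d])
        alleles[rows, l, 1L] <- paired[, 1L]
        alleles[rows, l, 2L] <- paired[, 2L]
        offset_copy <- offset_copy + nc
        offset_ind <- offset_ind + sample_sizes[d]
      }
    }
    # guard against non-positive drifted sizes (no boundaries imposed):
    # shift the whole locus so the minimum size is at least 1
    for (l in seq_len(n_loci)) {
      mn <- min(alleles[, l, ], na.rm = TRUE)
      if (mn < 1L) alleles[, l, ] <- alleles[, l, ] + (1L - mn)
    }
    msat_table(alleles,
               pop = rep(labels, sample_sizes),
               group = rep(labels, sample_sizes),
               repeat_unit = 1L)
  })
}

#' Coalescent-simulated genotype table (synthetic-data front end)
#'
#' Thin wrapper over [simulate_msat_dataset()] used by the synthetic-data
#' layer when temporal/demographic structure matters.
#' @inheritParams simulate_msat_dataset
#' @export
coalescent_table <- function(model, mutation, sample_sizes, n_loci,
                             seed = NULL) {
  simulate_msat_dataset(model, mutation, n_loci, sample_sizes, seed = seed)
}
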