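#' ARLSUMSTAT-style microsatellite summary statistics
#'
#' Single-group mode: mean and SD across loci of the number of alleles
#' (`K`), expected heterozygosity (`He`) and allele-size range (`R`, max
#' minus min size). Pair mode: the same six statistics per group, plus the
#' mean pooled total allele-size range across loci and Nei's `GST` between
#' the two groups.
#'
#' @param x an [msat_table()].
#' @param mode `"single"` or `"pair"`.
#' @return named numeric vector (constant layout per mode).
#' @export
summarize_msat <- function(x, mode = c("single", "pair")) {
  mode <- match.arg(mode)
  single_stats <- function(rows, prefix = "") {
    K <- He <- R <- numeric(n_loci(x))
    for (l in seq_len(n_loci(x))) {
      p <- locus_freqs(x, l, rows)
      K[l] <- length(p)
      He[l] <- if (length(p)) 1 - sum(p^2) else NA_real_
      sizes <- as.integer(names(p))
      R[l] <- if (length(sizes)) diff(range(sizes)) else NA_real_
    }
    setNames(c(mean(K), sd(K), mean(He), sd(He), mean(R), sd(R)),
             paste0(prefix, c("K_mean", "K_sd", "He_mean", "He_sd",
                              "R_mean", "R_sd")))
  }
  if (mode == "single") return(single_stats(seq_len(n_ind(x))))
  if (is.null(x$group) || length(unique(x$group)) != 2L)
    stop_input("pair mode needs exactly 2 groups")
  gs <- unique(x$group)
  s1 <- single_stats(which(x$group == gs[1]), "g1_")
  s2 <- single_stats(which(x$group == gs[2]), "g2_")
  Rtot <- vapply(seq_len(n_loci(x)), function(l) {
    p <- locus_freqs(x, l)
    sizes <- as.integer(names(p))
    if (length(sizes)) diff(range(sizes)) else NA_real_
  }, numeric(1))
  c(s1, s2, R_total_mean = mean(Rtot), GST = nei_gst(x, by = "group"))
}
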