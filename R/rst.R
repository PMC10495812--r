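# Slatkin's RST from allele sizes, and the allele-size permutation test
# that contrasts the observed RST with its distribution when sizes are
# randomly reassigned to allelic states (pRST). RST substantially above
# pRST indicates phylogeographic structure: stepwise-related alleles
# co-occur within groups more than expected.

# one-way variance components on gene copies for one locus
rst_locus_components <- function(sizes, deme) {
  demes <- unique(deme)
  r <- length(demes)
  n_i <- vapply(demes, function(d) sum(deme == d), numeric(1))
  N <- sum(n_i)
  if (r < 2L || any(n_i < 1)) return(c(b = NA_real_, w = NA_real_))
  gm <- mean(sizes)
  means <- vapply(demes, function(d) mean(sizes[deme == d]), numeric(1))
  ss_b <- sum(n_i * (means - gm)^2)
  ss_w <- sum((sizes - means[match(deme, demes)])^2)
  ms_b <- ss_b / (r - 1)
  ms_w <- ss_w / (N - r)
  n0 <- (N - sum(n_i^2) / N) / (r - 1)
  c(b = (ms_b - ms_w) / n0, w = ms_w)
}

rst_from_copies <- function(size_list, deme_list) {
  comp <- mapply(function(s, d) rst_locus_components(s, d),
                 size_list, deme_list)
  b <- sum(comp["b", ], na.rm = TRUE)
  w <- sum(comp["w", ], na.rm = TRUE)
  if (b + w == 0) return(NA_real_)
  b / (b + w)
}

#' RST and the permuted-RST (pRST) test for phylogeographic structure
#'
#' RST is the among-stratum fraction of allele-size variance (one-way
#' variance components on gene copies, summed over loci). The null is
#' built by permuting, within each locus, the size values assigned to the
#' allelic states (allele identities and their distribution across strata
#' are kept; only the stepwise size information is destroyed), recomputing
#' RST for each permutation. Monomorphic loci are excluded with a warning.
#'
#' @param x an [msat_table()] with allele sizes on the repeat scale (use
#'   [to_repeat_scale()] first if stored in base pairs).
#' @param by stratification, `"group"` or `"pop"`.
#' @param n_perm number of size permutations.
#' @param seed optional RNG seed.
#' @return an `rst_test` list: `rst`, `p_rst` (mean permuted RST), `p`
#'   (one-sided, `(#{perm >= obs}+1)/(n_perm+1)`), `n_perm`, `perm_summary`.
#' @export
rst_permutation_test <- function(x, by = c("group", "pop"),
                                 n_perm = 1000L, seed = NULL) {
  by <- match.arg(by)
  if (x$repeat_unit != 1L)
    stop_input("allele sizes must be on the repeat scale; ",
               "call to_repeat_scale() first")
  f <- strata_labels(x, by)
  size_list <- list(); deme_list <- list(); kept <- character(0)
  for (l in seq_len(n_loci(x))) {
    a1 <- x$alleles[, l, 1L]; a2 <- x$alleles[, l, 2L]
    ok <- !is.na(a1)
    s <- c(a1[ok], a2[ok]); d <- c(f[ok], f[ok])
    if (length(unique(s)) < 2L) {
      warning("locus ", x$loci[l], " is monomorphic; excluded from RST")
      next
    }
    size_list[[length(size_list) + 1L]] <- s
    deme_list[[length(deme_list) + 1L]] <- d
    kept <- c(kept, x$loci[l])
  }
  if (!length(size_list)) stop_input("no polymorphic loci for RST")
  obs <- rst_from_copies(size_list, deme_list)
  with_seed(seed, {
    perm <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      perm_sizes <- lapply(size_list, function(s) {
        states <- unique(s)
        new_sizes <- sample(states)
        new_sizes[match(s, states)]
      })
      perm[b] <- rst_from_copies(perm_sizes, deme_list)
    }
    structure(list(rst = obs, p_rst = mean(perm),
                   p = perm_pvalue(perm, obs),
                   n_perm = as.integer(n_perm), loci = kept,
                   perm_summary = summary(perm)),
              class = "rst_test")
  })
}

#' @export
print.rst_test <- function(x, ...) {
  cat(sprintf("RST = %.4f, pRST = %.4f, p = %.4g (%d permutations)\n",
              x$rst, x$p_rst, x$p, x$n_perm))
  invisible(x)
}
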