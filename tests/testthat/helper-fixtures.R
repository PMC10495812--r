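# shared fixture builders (all data generated in code)

toy_table <- function(genotypes, pop = NULL, group = NULL, loci = NULL) {
  # genotypes: list of n x 2 matrices, one per locus
  n <- nrow(genotypes[[1]])
  al <- array(NA_integer_, dim = c(n, length(genotypes), 2L))
  for (l in seq_along(genotypes)) {
    al[, l, 1L] <- genotypes[[l]][, 1L]
    al[, l, 2L] <- genotypes[[l]][, 2L]
  }
  msat_table(al, pop = pop, group = group, loci = loci)
}

random_table <- function(n = 12, L = 8, n_pop = 2, missing_rate = 0.1,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  al <- array(sample(5:60, n * L * 2, replace = TRUE), dim = c(n, L, 2L))
  drop <- matrix(runif(n * L) < missing_rate, n, L)
  for (l in seq_len(L)) al[drop[, l], l, ] <- NA_integer_
  # ensure each locus retains data
  for (l in seq_len(L)) if (all(is.na(al[, l, 1]))) al[1, l, ] <- c(10L, 11L)
  msat_table(al, pop = rep(paste0("pop", seq_len(n_pop)),
                           each = ceiling(n / n_pop))[seq_len(n)])
}

random_alignment <- function(n = 10, L = 40, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  m <- matrix(rep(base, n), nrow = n, byrow = TRUE)
  for (k in seq_len(max(1, L %/% 8))) {
    j <- sample(L, 1)
    i <- sample(n, sample(1:(n - 1), 1))
    m[i, j] <- sample(setdiff(c("A", "C", "G", "T"), base[j]), 1)
  }
  seq_alignment(m)
}
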