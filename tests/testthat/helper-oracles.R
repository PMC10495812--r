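# Brute-force oracle implementations, written independently of the package
# internals: explicit loops and direct evaluation of the published formulas.

oracle_locus_stats <- function(a1, a2) {
  ok <- !is.na(a1) & !is.na(a2)
  copies <- c(a1[ok], a2[ok])
  p <- as.numeric(table(copies)) / length(copies)
  he <- 1 - sum(p^2)
  ho <- sum(a1[ok] != a2[ok]) / sum(ok)
  list(Na = length(p), Ne = 1 / sum(p^2), Ho = ho, He = he,
       Fis = if (he > 0) (he - ho) / he else NA_real_)
}

# squared codominant genotype distance by explicit allele-count loops
oracle_genotype_dist <- function(x) {
  n <- dim(x$alleles)[1]; L <- dim(x$alleles)[2]
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    tot <- 0
    for (l in seq_len(L)) {
      gi <- x$alleles[i, l, ]; gj <- x$alleles[j, l, ]
      if (anyNA(gi) || anyNA(gj)) next
      states <- unique(c(gi, gj))
      ci <- sapply(states, function(s) sum(gi == s))
      cj <- sapply(states, function(s) sum(gj == s))
      tot <- tot + sum((ci - cj)^2) / 2
    }
    d[i, j] <- tot
  }
  d
}

# two-level AMOVA components from first principles (explicit pair loops)
oracle_amova2 <- function(d2, f) {
  n <- nrow(d2)
  ss_tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) ss_tot <- ss_tot + d2[i, j]
  ss_tot <- ss_tot / n
  ss_w <- 0
  for (s in unique(f)) {
    idx <- which(f == s)
    acc <- 0
    if (length(idx) > 1)
      for (a in 1:(length(idx) - 1)) for (b in (a + 1):length(idx))
        acc <- acc + d2[idx[a], idx[b]]
    ss_w <- ss_w + acc / length(idx)
  }
  G <- length(unique(f)); sizes <- table(f)
  ms_a <- (ss_tot - ss_w) / (G - 1); ms_w <- ss_w / (n - G)
  n0 <- (n - sum(sizes^2) / n) / (G - 1)
  sw <- ms_w; sa <- (ms_a - ms_w) / n0
  c(among = sa, within = sw)
}

oracle_pi <- function(m) {
  # all-pairs Hamming proportion; m = char matrix without gap/N columns
  n <- nrow(m); tot <- 0; np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(m[i, ] != m[j, ])
    np <- np + 1
  }
  list(pi_total = tot / np, pi = tot / np / ncol(m))
}

oracle_tajima <- function(pi_total, S, n) {
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pi_total - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

oracle_fu_li <- function(pi_total, eta, eta_s, n) {
  a <- sum(1 / (1:(n - 1))); b <- sum(1 / (1:(n - 1))^2); an1 <- a + 1 / n
  cn <- if (n == 2) 1 else 2 * (n * a - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vds <- ((n / (n - 1))^2 * b + a^2 * dn -
            2 * (n * a * (a + 1)) / (n - 1)^2) / (a^2 + b)
  uds <- (n / (n - 1)) * (a - n / (n - 1)) - vds
  Dstar <- ((n / (n - 1)) * eta - a * eta_s) / sqrt(uds * eta + vds * eta^2)
  vfs <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
            2 * (n - 1) * a / n^2 - 8 * b / n) / (a^2 + b)
  ufs <- ((4 * n^2 + 19 * n + 3 - 12 * (n + 1) * an1) /
            (3 * n * (n - 1))) / a - vfs
  Fstar <- (pi_total - ((n - 1) / n) * eta_s) / sqrt(ufs * eta + vfs * eta^2)
  list(D_star = Dstar, F_star = Fstar)
}
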