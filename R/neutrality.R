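# Frequency-spectrum neutrality tests. All work from the segregating-site
# summaries of seq_diversity(); statistics are NA-flagged when S = 0.

harmonic <- function(n, power = 1) sum(1 / seq_len(n - 1)^power)

#' Tajima's D
#'
#' `D = (pi_total - S/a1) / sqrt(e1*S + e2*S*(S-1))` with the standard
#' constants; `pi_total` is the mean number of pairwise differences (not
#' per site).
#'
#' @param aln a [seq_alignment()] (or a `seq_diversity` object).
#' @return list with `D` and `S`; `D = NA` when `S = 0`.
#' @export
tajimas_d <- function(aln) {
  sd_ <- if (inherits(aln, "seq_diversity")) aln else seq_diversity(aln)
  n <- sd_$n; S <- sd_$S
  if (S == 0L || n < 4L) return(list(D = NA_real_, S = S))
  a1 <- harmonic(n); a2 <- harmonic(n, 2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (sd_$pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  list(D = D, S = S)
}

#' Fu and Li's D* and F* (no outgroup)
#'
#' Singleton-based neutrality tests using total mutations `eta` and
#' singleton mutations `eta_s`, with the corrected variance constants used
#' by the standard sequence-analysis software.
#'
#' @param aln a [seq_alignment()] (or a `seq_diversity` object).
#' @return list with `D_star`, `F_star`, `eta`, `eta_s`; statistics NA
#'   when `S = 0`.
#' @export
fu_li_star <- function(aln) {
  sd_ <- if (inherits(aln, "seq_diversity")) aln else seq_diversity(aln)
  n <- sd_$n
  eta <- sd_$eta; eta_s <- sd_$eta_s
  if (sd_$S == 0L || n < 4L)
    return(list(D_star = NA_real_, F_star = NA_real_,
                eta = eta, eta_s = eta_s))
  a <- harmonic(n); b <- harmonic(n, 2)
  a1 <- a + 1 / n  # a_{n+1}
  cn <- if (n == 2) 1 else 2 * (n * a - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (3 / 2 - (2 * a1 - 3) / (n - 2) - 1 / n)
  vds <- ((n / (n - 1))^2 * b + a^2 * dn -
            2 * (n * a * (a + 1)) / (n - 1)^2) / (a^2 + b)
  uds <- (n / (n - 1)) * (a - n / (n - 1)) - vds
  D_star <- ((n / (n - 1)) * eta - a * eta_s) /
    sqrt(uds * eta + vds * eta^2)
  vfs <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
            2 * (n - 1) * a / n^2 - 8 * b / n) / (a^2 + b)
  ufs <- ((4 * n^2 + 19 * n + 3 - 12 * (n + 1) * a1) /
            (3 * n * (n - 1))) / a - vfs
  F_star <- (sd_$pi_total - ((n - 1) / n) * eta_s) /
    sqrt(ufs * eta + vfs * eta^2)
  list(D_star = D_star, F_star = F_star, eta = eta, eta_s = eta_s)
}

#' Neutrality-test report
#'
#' @param aln a [seq_alignment()].
#' @return list with `tajima_D`, `fu_li_D_star`, `fu_li_F_star` and the
#'   underlying counts.
#' @export
neutrality_tests <- function(aln) {
  sd_ <- seq_diversity(aln)
  td <- tajimas_d(sd_)
  fl <- fu_li_star(sd_)
  list(tajima_D = td$D, fu_li_D_star = fl$D_star, fu_li_F_star = fl$F_star,
       S = sd_$S, eta = sd_$eta, eta_s = sd_$eta_s, n = sd_$n)
}
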