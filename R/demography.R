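#' Demographic models for the microsatellite coalescent
#'
#' Constructors for the four model families compared in the analysis.
#' Sizes are diploid effective population sizes, times are generations,
#' migration rates are per gene copy per generation (backward lineage
#' rates; `m12` moves a lineage from deme 1 to deme 2 back in time, which
#' corresponds to forward gene flow from deme 2 into deme 1).
#'
#' * `snm_model(N)`: constant size (standard neutral model).
#' * `pgm_model(N, G, t)`: size-change model whose backward-time size is
#'   `N(s) = N * exp(G * s)` for `s` in `[0, t]` and constant
#'   `Na = N * exp(G * t)` earlier. `G < 0` therefore describes forward
#'   exponential growth (ancestral size smaller than current).
#' * `srm_model(N, Nb, t1)`: instantaneous size reduction -- current size
#'   `N`, ancestral size `Nb > N` before `t1` generations ago.
#' * `dvm_model(N1, N2, Nanc, T, m12, m21)`: two demes of sizes `N1`
#'   (west) and `N2` (east) that split from an ancestral deme of size
#'   `Nanc` at time `T`; migration is active between the present and `T`.
#'
#' @param N,N1,N2,Nanc,Nb diploid effective sizes (> 0).
#' @param G exponential rate per generation (sign convention above).
#' @param t,t1,T event times in generations (>= 0).
#' @param m12,m21 backward migration rates in `[0, 1]`.
#' @return an object of class `demographic_model`.
#' @export
snm_model <- function(N) {
  stopifnot(N > 0)
  structure(list(kind = "SNM", N = N), class = "demographic_model")
}

#' @rdname snm_model
#' @export
pgm_model <- function(N, G, t) {
  stopifnot(N > 0, t >= 0)
  Na <- N * exp(G * t)
  structure(list(kind = "PGM", N = N, G = G, t = t, Na = Na),
            class = "demographic_model")
}

#' @rdname snm_model
#' @export
srm_model <- function(N, Nb, t1) {
  stopifnot(N > 0, Nb > 0, t1 >= 0)
  if (N >= Nb) stop_input("SRM requires N < Nb")
  structure(list(kind = "SRM", N = N, Nb = Nb, t1 = t1),
            class = "demographic_model")
}

#' @rdname snm_model
#' @export
dvm_model <- function(N1, N2, Nanc, T, m12 = 0, m21 = 0) {
  stopifnot(N1 > 0, N2 > 0, Nanc > 0, T >= 0,
            m12 >= 0, m12 <= 1, m21 >= 0, m21 <= 1)
  if (max(N1, N2) >= Nanc) stop_input("DVM requires N_CUR < N_ANC")
  structure(list(kind = "DVM", N1 = N1, N2 = N2, Nanc = Nanc, T = T,
                 m12 = m12, m21 = m21),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  pars <- x[setdiff(names(x), "kind")]
  cat(x$kind, "model: ",
      paste(names(pars), signif(unlist(pars), 4), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

n_demes <- function(model) if (model$kind == "DVM") 2L else 1L

#' Microsatellite mutation model (GSM)
#'
#' Generalized stepwise mutation: mutations arrive as a Poisson process at
#' per-locus rate `mu`, each changing the repeat count by `+/- k` with
#' equiprobable direction and `k` geometric,
#' `P(k) = (1 - p_gsm) * p_gsm^(k-1)`, `k >= 1`. `p_gsm = 0` is the strict
#' one-step model (SMM). Per-locus rates are `mu_mean` multiplied by a
#' gamma(shape, rate = shape) draw (mean 1); with `normalize_mu` the draws
#' are rescaled so the realized across-locus mean equals `mu_mean` exactly.
#'
#' @param mu_mean mean per-locus per-generation rate (default 5e-4).
#' @param p_gsm geometric parameter in `[0, 1)`.
#' @param gamma_shape shape of the rate-heterogeneity gamma; `NULL` (or
#'   `Inf`) gives equal rates across loci.
#' @param normalize_mu rescale per-locus draws to the exact mean.
#' @return an object of class `mutation_model`.
#' @export
mutation_model <- function(mu_mean = 5e-4, p_gsm = 0, gamma_shape = NULL,
                           normalize_mu = TRUE) {
  stopifnot(mu_mean >= 0, p_gsm >= 0, p_gsm < 1)
  if (!is.null(gamma_shape)) stopifnot(gamma_shape > 0)
  structure(list(mu_mean = mu_mean, p_gsm = p_gsm,
                 gamma_shape = gamma_shape,
                 normalize_mu = isTRUE(normalize_mu)),
            class = "mutation_model")
}

draw_locus_rates <- function(mutation, n_loci) {
  sh <- mutation$gamma_shape
  if (is.null(sh) || !is.finite(sh)) return(rep(mutation$mu_mean, n_loci))
  w <- rgamma(n_loci, shape = sh, rate = sh)
  if (mutation$normalize_mu && mean(w) > 0) w <- w / mean(w)
  mutation$mu_mean * w
}
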