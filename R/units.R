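# Conservation-unit decision rules and unit conversions.

#' Unit conversions for reporting
#'
#' `generations_to_years()` multiplies a time in generations by the
#' generation length (default 25 years for this long-lived conifer).
#' `migration_fraction()` converts a number of migrants per generation
#' `Nm` into a per-capita migration rate `m = Nm / N`.
#'
#' @param generations time in generations.
#' @param generation_length years per generation.
#' @export
generations_to_years <- function(generations, generation_length = 25) {
  generations * generation_length
}

#' @rdname generations_to_years
#' @param Nm migrants per generation.
#' @param N effective population size of the receiving group.
#' @export
migration_fraction <- function(Nm, N) {
  stopifnot(N > 0)
  Nm / N
}

#' Delimit evolutionarily significant units and management units
#'
#' Decision rule for two candidate groups: they are distinct MUs iff the
#' nuclear allele-frequency divergence is significant (`nuclear_p < alpha`)
#' AND dispersal between them is below 10% per generation in both
#' directions (`max(m) < 0.10`). They are distinct ESUs iff, additionally,
#' the plastid clades are reciprocally monophyletic and spatially
#' segregated (clade-vs-geography structure). Missing plastid evidence
#' leaves the ESU decision at 1 with an indeterminate flag.
#'
#' @param nuclear_p p-value of nuclear differentiation (e.g. from AMOVA).
#' @param migration_rates numeric vector of per-generation migration
#'   rates (one per direction).
#' @param plastid_clades_monophyletic logical (or NA when unknown).
#' @param plastid_spatially_segregated logical (or NA): does clade
#'   membership track geography?
#' @param alpha significance level, in (0, 1).
#' @param m_threshold dispersal threshold (default 0.10).
#' @return a `unit_decision`: `n_ESU`, `n_MU`, per-criterion flags and
#'   rationale strings.
#' @export
delimit_units <- function(nuclear_p, migration_rates,
                          plastid_clades_monophyletic = NA,
                          plastid_spatially_segregated = NA,
                          alpha = 0.05, m_threshold = 0.10) {
  if (!(alpha > 0 && alpha < 1)) stop_input("`alpha` must be in (0, 1)")
  stopifnot(is.numeric(nuclear_p), length(nuclear_p) == 1L,
            is.numeric(migration_rates), length(migration_rates) >= 1L)
  nuclear_sig <- nuclear_p < alpha
  m_max <- max(migration_rates)
  low_dispersal <- m_max < m_threshold
  n_MU <- if (nuclear_sig && low_dispersal) 2L else 1L
  plastid_ok <- isTRUE(plastid_clades_monophyletic) &&
    isTRUE(plastid_spatially_segregated)
  esu_indeterminate <- n_MU == 2L &&
    (is.na(plastid_clades_monophyletic) ||
       is.na(plastid_spatially_segregated))
  n_ESU <- if (n_MU == 2L && plastid_ok) 2L else 1L
  rationale <- c(
    sprintf("nuclear divergence %s (p = %.3g, alpha = %.3g)",
            if (nuclear_sig) "significant" else "not significant",
            nuclear_p, alpha),
    sprintf("max migration rate %.4g %s threshold %.2g", m_max,
            if (low_dispersal) "below" else "at/above", m_threshold),
    if (n_MU == 2L)
      sprintf("plastid clades %s", if (plastid_ok)
        "monophyletic and spatially segregated: distinct ESUs"
        else if (esu_indeterminate) "indeterminate: single ESU retained"
        else "not spatially segregated: single ESU"))
  structure(list(n_ESU = n_ESU, n_MU = n_MU,
                 nuclear_divergence_significant = nuclear_sig,
                 nuclear_p = nuclear_p,
                 migration_below_threshold = low_dispersal,
                 max_migration = m_max,
                 plastid_reciprocal_monophyly_spatial = plastid_ok,
                 esu_indeterminate = esu_indeterminate,
                 rationale = rationale),
            class = "unit_decision")
}

#' @export
print.unit_decision <- function(x, ...) {
  cat(sprintf("Conservation units: %d ESU, %d MU\n", x$n_ESU, x$n_MU))
  for (r in x$rationale) cat("  -", r, "\n")
  invisible(x)
}
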