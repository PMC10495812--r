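# Prior specifications and prior-predictive reference tables.

#' Prior specification for ABC
#'
#' Each entry describes one free (or fixed) quantity by name:
#' `prior_uniform(lo, hi)`, `prior_loguniform(lo, hi)`,
#' `prior_gamma(shape, rate)` or `prior_fixed(value)`.
#'
#' @param ... named prior entries.
#' @return a `prior_spec` list.
#' @export
prior_spec <- function(...) {
  entries <- list(...)
  if (!length(entries) || is.null(names(entries)) || any(!nzchar(names(entries))))
    stop_input("all prior entries must be named")
  structure(entries, class = "prior_spec")
}

#' @rdname prior_spec
#' @param lo,hi finite bounds, `lo < hi`.
#' @export
prior_uniform <- function(lo, hi) {
  stopifnot(is.finite(lo), is.finite(hi), lo < hi)
  list(dist = "uniform", lo = lo, hi = hi)
}

#' @rdname prior_spec
#' @export
prior_loguniform <- function(lo, hi) {
  stopifnot(is.finite(lo), is.finite(hi), 0 < lo, lo < hi)
  list(dist = "loguniform", lo = lo, hi = hi)
}

#' @rdname prior_spec
#' @param shape,rate gamma hyperparameters.
#' @export
prior_gamma <- function(shape, rate) {
  stopifnot(shape > 0, rate > 0)
  list(dist = "gamma", shape = shape, rate = rate)
}

#' @rdname prior_spec
#' @param value the fixed value.
#' @export
prior_fixed <- function(value) list(dist = "fixed", value = value)

draw_prior <- function(spec) {
  vapply(spec, function(e) switch(e$dist,
    uniform = runif(1, e$lo, e$hi),
    loguniform = exp(runif(1, log(e$lo), log(e$hi))),
    gamma = rgamma(1, shape = e$shape, rate = e$rate),
    fixed = e$value,
    stop_input("unknown prior distribution: ", e$dist)), numeric(1))
}

#' Default priors for the demographic model families
#'
#' Config-exposed defaults used when no explicit priors are supplied:
#' sizes log-uniform on `1e2..1e4`, event times uniform on `1..1e4`,
#' divergence-model `T ~ U(1, 1e4)`, `Nanc ~ U(1e2, 1e4)` and
#' `m ~ U(1e-5, 0.3)`; GSM nuisance parameters `shape ~ U(0.5, 5)` and
#' `p_gsm ~ U(0, 0.99)`. The growth-rate prior is negative (forward
#' expansion) under the literal ancestral-size reconstruction
#' `Na = N * exp(G * t)`. Structural constraints are enforced by
#' resampling: `Nanc > max(N1, N2)` for the divergence model, and at
#' least a two-fold size change for the growth and reduction models
#' (`Na <= N/2`, `Nb >= 2N`), so that the size-change alternatives are
#' genuinely distinct from the constant-size null.
#'
#' @param kind model family tag (`"SNM"`, `"PGM"`, `"SRM"`, `"DVM"`).
#' @param fixed named list of values to pin (become `prior_fixed` entries).
#' @return a [prior_spec()] including the mutation nuisance parameters.
#' @export
default_priors <- function(kind, fixed = list()) {
  base <- switch(kind,
    SNM = list(N = prior_loguniform(1e2, 1e4)),
    PGM = list(N = prior_loguniform(1e2, 1e4),
               G = prior_uniform(-1e-2, -1e-5),
               t = prior_uniform(1, 1e4)),
    SRM = list(N = prior_loguniform(1e2, 1e4),
               Nb = prior_loguniform(1e2, 1e4),
               t1 = prior_uniform(1, 1e4)),
    DVM = list(N1 = prior_loguniform(1e2, 1e4),
               N2 = prior_loguniform(1e2, 1e4),
               Nanc = prior_uniform(1e2, 1e4),
               T = prior_uniform(1, 1e4),
               m12 = prior_uniform(1e-5, 0.3),
               m21 = prior_uniform(1e-5, 0.3)),
    stop_input("unknown model kind: ", kind))
  base$gsm_shape <- prior_uniform(0.5, 5)
  base$p_gsm <- prior_uniform(0, 0.99)
  for (nm in names(fixed)) base[[nm]] <- prior_fixed(fixed[[nm]])
  do.call(prior_spec, base)
}

# instantiate a demographic model from a named parameter draw
model_from_draw <- function(kind, th) {
  switch(kind,
    SNM = snm_model(th[["N"]]),
    PGM = pgm_model(th[["N"]], th[["G"]], th[["t"]]),
    SRM = srm_model(th[["N"]], th[["Nb"]], th[["t1"]]),
    DVM = dvm_model(th[["N1"]], th[["N2"]], th[["Nanc"]], th[["T"]],
                    th[["m12"]], th[["m21"]]))
}

# rejection-resample a draw until the model's structural constraints hold
draw_valid_params <- function(kind, priors, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    th <- draw_prior(priors)
    ok <- switch(kind,
      # alternatives to the constant-size model must describe a real size
      # change (at least two-fold), otherwise the comparison is ill-posed:
      # a no-change SRM/PGM is observationally identical to SNM
      # ... and the change must fall inside the coalescent time window of
      # the current size (an event far beyond ~4N generations leaves no
      # trace in the sample and is unidentifiable)
      SRM = th[["Nb"]] >= 2 * th[["N"]] && th[["t1"]] <= 4 * th[["N"]],
      PGM = exp(th[["G"]] * th[["t"]]) <= 0.5 && th[["t"]] <= 4 * th[["N"]],
      DVM = max(th[["N1"]], th[["N2"]]) < th[["Nanc"]],
      TRUE)
    if (ok) return(th)
  }
  stop_input("could not draw structurally valid parameters for ", kind,
             " in ", max_tries, " tries; check the priors")
}

#' Build a prior-predictive reference table
#'
#' Rows are allocated to the candidate models with equal prior weight
#' (round-robin); for each row, parameters are drawn from the model's
#' priors (structural constraints enforced by resampling), a dataset is
#' simulated under the coalescent with GSM mutation, and the summary
#' statistics are recorded. Deterministic under `seed`.
#'
#' @param models named list: model-family tag (`"SNM"`, `"PGM"`, `"SRM"`,
#'   `"DVM"`) per candidate model name.
#' @param priors named list of [prior_spec()]s, one per model (defaults
#'   from [default_priors()] when `NULL`).
#' @param n_sims total rows (>= number of models).
#' @param sample_sizes diploids per deme passed to the simulator.
#' @param n_loci loci per dataset.
#' @param mu_mean mean mutation rate.
#' @param mode summary-statistic mode (`"single"` or `"pair"`).
#' @param seed optional RNG seed.
#' @return a `reference_table`: data frame with `model`, parameter columns
#'   (NA where not applicable) and `stat_*` columns; attributes `stat_names`
#'   and `mode`.
#' @export
build_reference_table <- function(models, priors = NULL, n_sims,
                                  sample_sizes, n_loci = 8L,
                                  mu_mean = 5e-4,
                                  mode = c("single", "pair"), seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(names(models))) names(models) <- unlist(models)
  M <- length(models)
  if (n_sims < M) stop_input("`n_sims` must be at least the number of models")
  if (is.null(priors))
    priors <- lapply(models, default_priors)
  with_seed(seed, {
    assign_model <- rep(names(models), length.out = n_sims)
    rows <- vector("list", n_sims)
    retries <- 0L
    for (i in seq_len(n_sims)) {
      mname <- assign_model[i]
      kind <- models[[mname]]
      ok <- FALSE
      for (attempt in 1:20) {
        th <- draw_valid_params(kind, priors[[mname]])
        mut <- mutation_model(mu_mean = mu_mean,
                              p_gsm = th[["p_gsm"]],
                              gamma_shape = th[["gsm_shape"]])
        fit <- try({
          tab <- simulate_msat_dataset(model_from_draw(kind, th),
                                       mut, n_loci, sample_sizes)
          summarize_msat(tab, mode)
        }, silent = TRUE)
        if (!inherits(fit, "try-error") && !anyNA(fit)) { ok <- TRUE; break }
        retries <- retries + 1L
      }
      if (!ok) stop_input("simulation kept failing for model ", mname)
      rows[[i]] <- list(model = mname, params = th, stats = fit)
    }
    all_params <- unique(unlist(lapply(rows, function(r) names(r$params))))
    stat_names <- names(rows[[1]]$stats)
    pm <- matrix(NA_real_, n_sims, length(all_params),
                 dimnames = list(NULL, all_params))
    sm <- matrix(NA_real_, n_sims, length(stat_names),
                 dimnames = list(NULL, paste0("stat_", stat_names)))
    for (i in seq_len(n_sims)) {
      pm[i, names(rows[[i]]$params)] <- rows[[i]]$params
      sm[i, ] <- rows[[i]]$stats
    }
    out <- data.frame(model = vapply(rows, `[[`, character(1), "model"),
                      pm, sm, check.names = FALSE)
    attr(out, "stat_names") <- stat_names
    attr(out, "param_names") <- all_params
    attr(out, "mode") <- mode
    attr(out, "retries") <- retries
    class(out) <- c("reference_table", "data.frame")
    out
  })
}

ref_stats <- function(ref) {
  as.matrix(ref[, paste0("stat_", attr(ref, "stat_names")), drop = FALSE])
}

ref_params <- function(ref) {
  as.matrix(ref[, attr(ref, "param_names"), drop = FALSE])
}
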