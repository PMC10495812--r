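#' Simulate a per-locus genealogy under a demographic model
#'
#' Event-driven structured Kingman coalescent: within a deme of diploid
#' size `N`, `k` lineages coalesce at rate `k(k-1)/2` per `2N` generations;
#' lineages migrate at their backward per-copy rates; at the divergence
#' time the demes merge into the ancestral deme; size changes and the
#' exponential trajectory of the size-change models are applied as phase
#' events. Returns an ultrametric genealogy with tips at time 0.
#'
#' @param model a [snm_model()], [pgm_model()], [srm_model()] or
#'   [dvm_model()].
#' @param sample_sizes gene copies sampled per deme (length 1 for
#'   single-deme models, 2 for the divergence model).
#' @param seed optional RNG seed.
#' @return a `genealogy`: list with `parent` (node id of each node's
#'   ancestor, 0 for the root), `time` (node times in generations; tips
#'   1..n at 0, internal nodes in coalescence order), `n_tips`, `tip_deme`.
#' @export
simulate_genealogy <- function(model, sample_sizes, seed = NULL) {
  stopifnot(inherits(model, "demographic_model"))
  sample_sizes <- as.integer(sample_sizes)
  if (any(sample_sizes < 0) || sum(sample_sizes) < 1L)
    stop_input("zero sampled lineages")
  D <- n_demes(model)
  if (length(sample_sizes) != D)
    stop_input("`sample_sizes` must have one entry per deme (", D, ")")
  args <- switch(model$kind,
    SNM = list(sizes = model$N, mig = matrix(0, 1, 1), merge_time = Inf,
               merge_size = 1, change_time = Inf, change_size = 1,
               G = 0, growth_end = Inf),
    PGM = list(sizes = model$N, mig = matrix(0, 1, 1), merge_time = Inf,
               merge_size = 1, change_time = Inf, change_size = 1,
               G = model$G, growth_end = model$t),
    SRM = list(sizes = model$N, mig = matrix(0, 1, 1), merge_time = Inf,
               merge_size = 1, change_time = model$t1,
               change_size = model$Nb, G = 0, growth_end = Inf),
    DVM = list(sizes = c(model$N1, model$N2),
               mig = matrix(c(0, model$m21, model$m12, 0), 2, 2),
               merge_time = model$T, merge_size = model$Nanc,
               change_time = Inf, change_size = 1, G = 0,
               growth_end = Inf))
  with_seed(seed, {
    res <- .sim_genealogy_cpp(sample_sizes, args$sizes, args$mig,
                              args$merge_time, args$merge_size,
                              args$change_time, args$change_size,
                              args$G, args$growth_end)
    structure(res, class = "genealogy")
  })
}

#' @export
print.genealogy <- function(x, ...) {
  cat("genealogy:", x$n_tips, "tips, TMRCA =",
      signif(max(x$time), 5), "generations\n")
  invisible(x)
}

#' Total time to the most recent common ancestor
#' @param gen a `genealogy`.
#' @export
tmrca <- function(gen) max(gen$time)

#' Overlay generalized stepwise mutation on a genealogy
#'
#' Mutations fall on each branch as Poisson with mean `mu * length`; each
#' mutation shifts the allele size by a geometric step (`p_gsm` as in
#' [mutation_model()]) in an equiprobable direction. No size boundaries
#' are imposed.
#'
#' @param gen a `genealogy` from [simulate_genealogy()].
#' @param mu per-generation mutation rate (>= 0).
#' @param p_gsm geometric parameter in `[0, 1)`.
#' @param root_size allele size (repeat count) at the root.
#' @param seed optional RNG seed.
#' @return integer allele sizes at the tips, in tip order.
#' @export
overlay_gsm <- function(gen, mu, p_gsm = 0, root_size = 25L, seed = NULL) {
  stopifnot(inherits(gen, "genealogy"), mu >= 0, p_gsm >= 0, p_gsm < 1)
  n <- gen$n_tips
  n_nodes <- 2L * n - 1L
  with_seed(seed, {
    if (n == 1L) return(as.integer(root_size))
    parent <- gen$parent
    time <- gen$time
    blen <- numeric(n_nodes)
    has_parent <- parent > 0L
    blen[has_parent] <- time[parent[has_parent]] - time[has_parent]
    k <- rpois(n_nodes, mu * blen)
    delta <- numeric(n_nodes)
    idx <- which(k > 0L)
    for (i in idx) {
      steps <- rgeom(k[i], prob = 1 - p_gsm) + 1L
      signs <- sample(c(-1L, 1L), k[i], replace = TRUE)
      delta[i] <- sum(steps * signs)
    }
    value <- numeric(n_nodes)
    value[n_nodes] <- root_size
    for (i in seq(n_nodes - 1L, 1L))
      value[i] <- value[parent[i]] + delta[i]
    as.integer(value[seq_len(n)])
  })
}
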