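# Analysis of molecular variance (Excoffier-style) on a squared-distance
# matrix, with permutation inference. Core engine shared by the genotype
# AMOVA, the sequence phiST and the standardized differentiation measures.

ss_within_strata <- function(d2, f) {
  ss <- 0
  for (s in unique(f)) {
    idx <- which(f == s)
    if (length(idx) > 1L)
      ss <- ss + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  ss
}

amova_components_2level <- function(d2, strata) {
  n <- nrow(d2)
  f <- as.character(strata)
  sizes <- table(f)
  G <- length(sizes)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_w <- ss_within_strata(d2, f)
  ss_a <- ss_total - ss_w
  df_a <- G - 1L; df_w <- n - G
  ms_a <- ss_a / df_a; ms_w <- ss_w / df_w
  n0 <- (n - sum(sizes^2) / n) / (G - 1)
  sigma_w <- ms_w
  sigma_a <- (ms_a - ms_w) / n0
  c(among = sigma_a, within = sigma_w)
}

amova_components_3level <- function(d2, pop, group) {
  n <- nrow(d2)
  pop <- as.character(pop); group <- as.character(group)
  pops <- unique(pop); groups <- unique(group)
  P <- length(pops); G <- length(groups)
  n_p <- table(pop); n_g <- table(group)
  pop_group <- vapply(pops, function(p) group[match(p, pop)], character(1))

  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_wp <- ss_within_strata(d2, pop)
  ss_wg <- ss_within_strata(d2, group)
  ss_ap <- ss_wg - ss_wp          # among pops within groups
  ss_ag <- ss_total - ss_wg       # among groups

  df_ag <- G - 1L; df_ap <- P - G; df_wp <- n - P
  ms_ag <- ss_ag / df_ag; ms_ap <- ss_ap / df_ap; ms_wp <- ss_wp / df_wp

  sum_np2_over_ng <- sum(vapply(groups, function(g) {
    np <- n_p[pops[pop_group == g]]
    sum(np^2) / n_g[[g]]
  }, numeric(1)))
  n1 <- (n - sum_np2_over_ng) / (P - G)
  n2 <- (sum_np2_over_ng - sum(n_p^2) / n) / (G - 1)
  n3 <- (n - sum(n_g^2) / n) / (G - 1)

  sigma_c <- ms_wp
  sigma_b <- (ms_ap - sigma_c) / n1
  sigma_a <- (ms_ag - sigma_c - n2 * sigma_b) / n3
  c(among_groups = sigma_a, among_pops = sigma_b, within = sigma_c)
}

#' AMOVA on a squared-distance matrix
#'
#' Hierarchical partition of molecular variance from sums of squared
#' inter-individual distances, two-level (one stratum factor) or
#' three-level (populations nested in groups), with fixation indices and
#' permutation p-values. Two-level output reports `phi_ST`; three-level
#' reports `phi_CT` (among groups), `phi_SC` (among populations within
#' groups) and `phi_ST` (overall). Permutation schemes: individuals among
#' strata (phi_ST two-level); individuals among populations within groups
#' (phi_SC); whole populations among groups (phi_CT); individuals anywhere
#' (three-level phi_ST).
#'
#' @param d2 symmetric matrix of squared distances, zero diagonal.
#' @param pop stratum (or population) label per individual.
#' @param group optional higher-level label per individual (three-level).
#' @param n_perm permutations for p-values (0 disables inference).
#' @param seed optional RNG seed.
#' @return an `amova_result`: list with `components` (named variance
#'   components), `percent`, `phi` (named fixation indices), `p_values`,
#'   `df`, and `n_perm`.
#' @export
amova_dist <- function(d2, pop, group = NULL, n_perm = 999L, seed = NULL) {
  d2 <- as.matrix(d2)
  if (nrow(d2) != ncol(d2) || any(abs(d2 - t(d2)) > 1e-8))
    stop_input("`d2` must be a symmetric matrix")
  pop <- as.character(pop)
  if (length(pop) != nrow(d2)) stop_input("`pop` length mismatch")
  sizes <- table(pop)
  if (length(sizes) < 2L && is.null(group))
    stop_input("need at least 2 strata")
  if (any(sizes < 2L))
    stop_input("stratum of size 1 at the lowest level: ",
               names(sizes)[which(sizes < 2L)[1]])

  if (is.null(group)) {
    comp <- amova_components_2level(d2, pop)
    phi <- c(phi_ST = unname(comp["among"] / sum(comp)))
    df <- c(among = length(sizes) - 1L, within = nrow(d2) - length(sizes))
    p <- NULL
    if (n_perm > 0L) {
      p_obs <- phi["phi_ST"]
      with_seed(seed, {
        perm <- replicate(n_perm, {
          f <- sample(pop)
          cp <- amova_components_2level(d2, f)
          cp["among"] / sum(cp)
        })
        p <- c(phi_ST = perm_pvalue(perm, p_obs))
      })
    }
  } else {
    group <- as.character(group)
    if (length(group) != nrow(d2)) stop_input("`group` length mismatch")
    comp <- amova_components_3level(d2, pop, group)
    tot <- sum(comp)
    phi <- c(
      phi_CT = unname(comp["among_groups"] / tot),
      phi_SC = unname(comp["among_pops"] /
                        (comp["among_pops"] + comp["within"])),
      phi_ST = unname((comp["among_groups"] + comp["among_pops"]) / tot))
    df <- c(among_groups = length(unique(group)) - 1L,
            among_pops = length(unique(pop)) - length(unique(group)),
            within = nrow(d2) - length(unique(pop)))
    p <- NULL
    if (n_perm > 0L) {
      with_seed(seed, {
        pops <- unique(pop)
        pop_group <- vapply(pops, function(q) group[match(q, pop)],
                            character(1))
        perm_st <- perm_sc <- perm_ct <- numeric(n_perm)
        for (b in seq_len(n_perm)) {
          # phi_ST: individuals anywhere
          f <- sample(pop)
          cs <- amova_components_3level(d2, f, group[match(f, pop)])
          perm_st[b] <- (cs["among_groups"] + cs["among_pops"]) / sum(cs)
          # phi_SC: individuals among pops within their group
          f2 <- pop
          for (g in unique(group)) {
            idx <- which(group == g)
            f2[idx] <- sample(pop[idx])
          }
          cs2 <- amova_components_3level(d2, f2, group)
          perm_sc[b] <- cs2["among_pops"] / (cs2["among_pops"] + cs2["within"])
          # phi_CT: whole pops among groups
          pg <- sample(pop_group)
          g3 <- pg[match(pop, pops)]
          cs3 <- amova_components_3level(d2, pop, g3)
          perm_ct[b] <- cs3["among_groups"] / sum(cs3)
        }
        p <- c(phi_CT = perm_pvalue(perm_ct, phi["phi_CT"]),
               phi_SC = perm_pvalue(perm_sc, phi["phi_SC"]),
               phi_ST = perm_pvalue(perm_st, phi["phi_ST"]))
      })
    }
  }
  structure(list(components = comp,
                 percent = 100 * comp / sum(comp),
                 phi = phi, p_values = p, df = df,
                 n_perm = as.integer(n_perm)),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA\n")
  tab <- data.frame(df = x$df, sigma2 = round(x$components, 5),
                    percent = round(x$percent, 2))
  print(tab)
  cat("Fixation indices:\n")
  for (k in names(x$phi)) {
    cat(sprintf("  %s = %.4f", k, x$phi[[k]]))
    if (!is.null(x$p_values) && k %in% names(x$p_values))
      cat(sprintf("  (p = %.4g, %d permutations)", x$p_values[[k]], x$n_perm))
    cat("\n")
  }
  invisible(x)
}

#' AMOVA on a microsatellite genotype table
#'
#' Runs [amova_dist()] on the squared codominant genotype distance
#' ([genotype_dist()]). `strata = "pop"` or `"group"` gives a two-level
#' analysis; `strata = "group/pop"` the three-level nested analysis.
#'
#' @param x an [msat_table()].
#' @param strata `"pop"`, `"group"`, `"group/pop"`, or a vector/list of
#'   labels (a single vector for two levels; a list `list(group=, pop=)`
#'   for three).
#' @param n_perm,seed permutation settings passed on.
#' @return an `amova_result`.
#' @export
amova <- function(x, strata = "pop", n_perm = 999L, seed = NULL) {
  d2 <- genotype_dist(x)
  if (is.character(strata) && length(strata) == 1L) {
    if (strata == "group/pop")
      return(amova_dist(d2, pop = x$pop, group = strata_labels(x, "group"),
                        n_perm = n_perm, seed = seed))
    return(amova_dist(d2, pop = strata_labels(x, strata),
                      n_perm = n_perm, seed = seed))
  }
  if (is.list(strata) && all(c("group", "pop") %in% names(strata)))
    return(amova_dist(d2, pop = strata$pop, group = strata$group,
                      n_perm = n_perm, seed = seed))
  amova_dist(d2, pop = strata, n_perm = n_perm, seed = seed)
}
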