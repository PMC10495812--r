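test_that("summary statistics match hand computation", {
  # monomorphic 3-locus table
  x <- toy_table(lapply(1:3, function(l) cbind(rep(10L, 4), rep(10L, 4))))
  s <- summarize_msat(x, "single")
  expect_equal(unname(s[c("K_mean", "K_sd", "He_mean", "R_mean")]),
               c(1, 0, 0, 0))
  # hand-built 2-locus table
  g1 <- cbind(c(10L, 12L), c(12L, 12L))   # alleles 10,12,12,12
  g2 <- cbind(c(20L, 24L), c(20L, 24L))   # alleles 20,20,24,24
  x2 <- toy_table(list(g1, g2))
  s2 <- summarize_msat(x2, "single")
  he1 <- 1 - (0.25^2 + 0.75^2); he2 <- 0.5
  expect_equal(unname(s2["K_mean"]), 2)
  expect_equal(unname(s2["He_mean"]), mean(c(he1, he2)), tolerance = 1e-12)
  expect_equal(unname(s2["R_mean"]), mean(c(2, 4)))
  # identical groups in pair mode: GST near zero
  x3 <- balding_nichols_table(c(40, 40), n_loci = 5, target_fst = 0,
                              seed = 3)
  s3 <- summarize_msat(x3, "pair")
  expect_lt(s3[["GST"]], 0.02)
  expect_error(summarize_msat(toy_table(list(g1)), "pair"), "2 groups")
})

test_that("reference tables allocate, retry and reproduce deterministically", {
  models <- list(M1 = "SNM", M2 = "SNM", M3 = "SNM")
  ref <- build_reference_table(models, n_sims = 6, sample_sizes = 5,
                               n_loci = 2, seed = 41)
  expect_equal(as.vector(table(ref$model)), c(2L, 2L, 2L))
  ref2 <- build_reference_table(models, n_sims = 6, sample_sizes = 5,
                                n_loci = 2, seed = 41)
  expect_identical(ref, ref2)
  expect_error(build_reference_table(models, n_sims = 2, sample_sizes = 5,
                                     n_loci = 2), "at least")
  # rows simulated at a fixed N cluster near the SMM equilibrium He
  refN <- build_reference_table(
    list(S = "SNM"),
    priors = list(S = default_priors("SNM", fixed = list(
      N = 2000, p_gsm = 0, gsm_shape = 1e6))),
    n_sims = 60, sample_sizes = 30, n_loci = 8, seed = 42)
  he <- ref[["stat_He_mean"]]
  he_eq <- 1 - 1 / sqrt(1 + 8 * 2000 * 5e-4)
  expect_lt(abs(mean(refN[["stat_He_mean"]]) - he_eq), 0.1)
})

test_that("model choice separates separable models and not identical ones", {
  obs_tab <- simulate_msat_dataset(snm_model(6000), mutation_model(), 8, 25,
                                   seed = 5)
  obs <- summarize_msat(obs_tab, "single")
  disj <- build_reference_table(
    list(small = "SNM", large = "SNM"),
    priors = list(small = default_priors("SNM", fixed = list(N = 150)),
                  large = default_priors("SNM", fixed = list(N = 6000))),
    n_sims = 300, sample_sizes = 25, n_loci = 8, seed = 51)
  mc <- rf_model_choice(disj, obs, n_trees = 300, seed = 52)
  expect_lt(mc$oob_error, 0.05)
  expect_equal(mc$selected, "large")
  expect_gt(mc$posterior_prob, 0.85)
  expect_equal(sum(mc$votes), 300)
  same <- build_reference_table(
    list(A = "SNM", B = "SNM"),
    priors = list(A = default_priors("SNM", fixed = list(N = 1000)),
                  B = default_priors("SNM", fixed = list(N = 1000))),
    n_sims = 300, sample_sizes = 25, n_loci = 8, seed = 53)
  mc2 <- rf_model_choice(same, obs, n_trees = 300, seed = 54)
  expect_gt(mc2$oob_error, 0.35)
  expect_lt(mc2$oob_error, 0.65)
  expect_gt(mc2$posterior_prob, 0.25)
  expect_lt(mc2$posterior_prob, 0.75)
  one <- disj[disj$model == "small", ]
  attr(one, "stat_names") <- attr(disj, "stat_names")
  expect_error(rf_model_choice(one, obs), "at least 2")
})

test_that("rejection posterior retains exactly the tolerance fraction", {
  ref <- build_reference_table(list(S = "SNM"), n_sims = 400,
                               sample_sizes = 10, n_loci = 4, seed = 61)
  obs <- ref_stats_row <- as.numeric(ref[1, paste0("stat_",
                                                   attr(ref, "stat_names"))])
  for (tol in c(0.2, 0.33, 1)) {
    post <- estimate_posterior(ref, obs, tolerance = tol,
                               method = "rejection")
    expect_equal(post$n_retained, ceiling(tol * 400))
  }
  # tolerance = 1, rejection: posterior is the prior
  post1 <- estimate_posterior(ref, obs, tolerance = 1, method = "rejection")
  expect_equal(sort(post1$draws[, "N"]), sort(ref$N), tolerance = 1e-12)
  expect_error(estimate_posterior(ref, obs, tolerance = 0.05),
               "increase n_sims")
})

test_that("degenerate constant statistics warn and skip adjustment", {
  ref <- build_reference_table(list(S = "SNM"), n_sims = 60,
                               sample_sizes = 8, n_loci = 3, seed = 71)
  sn <- paste0("stat_", attr(ref, "stat_names"))
  for (s in sn) ref[[s]] <- 1
  obs <- rep(1, length(sn))
  expect_warning(post <- estimate_posterior(ref, obs, tolerance = 1,
                                            method = "loclinear"),
                 "constant")
  expect_equal(sort(post$draws[, "N"]), sort(ref$N), tolerance = 1e-12)
})

test_that("HPD and mode behave on known samples", {
  set.seed(81)
  x <- rnorm(20000)
  hp <- hpd_interval(x, 0.95)
  expect_lt(abs(hp[1] + 1.96), 0.12)
  expect_lt(abs(hp[2] - 1.96), 0.12)
  expect_lt(abs(posterior_mode(x)), 0.15)
  expect_true(hp[1] <= posterior_mode(x) && posterior_mode(x) <= hp[2])
  # HPD mass: narrowest window contains ceiling(0.95 n) draws
  u <- runif(1000)
  hpu <- hpd_interval(u, 0.9)
  expect_gte(mean(u >= hpu[1] & u <= hpu[2]), 0.9)
})

test_that("neural-network and local-linear adjustments agree on recovery", {
  ref <- build_reference_table(list(S = "SNM"), n_sims = 800,
                               sample_sizes = 20, n_loci = 8, seed = 95)
  obs_tab <- simulate_msat_dataset(snm_model(1200),
                                   mutation_model(p_gsm = 0.3,
                                                  gamma_shape = 2),
                                   8, 20, seed = 96)
  obs <- summarize_msat(obs_tab, "single")
  p_ll <- estimate_posterior(ref, obs, tolerance = 0.2,
                             method = "loclinear")
  p_nn <- estimate_posterior(ref, obs, tolerance = 0.2,
                             method = "neuralnet", seed = 97)
  s_ll <- p_ll$summary[p_ll$summary$parameter == "N", ]
  s_nn <- p_nn$summary[p_nn$summary$parameter == "N", ]
  width <- max(s_ll$hpd_upper - s_ll$hpd_lower,
               s_nn$hpd_upper - s_nn$hpd_lower)
  expect_lt(abs(s_ll$mode - s_nn$mode), width)
})

test_that("true-model selection improves with the number of loci", {
  pick_rate <- function(n_loci, n_rep = 12) {
    ref <- build_reference_table(
      list(small = "SNM", large = "SNM"),
      priors = list(small = default_priors("SNM", fixed = list(N = 500)),
                    large = default_priors("SNM", fixed = list(N = 2500))),
      n_sims = 400, sample_sizes = 20, n_loci = n_loci,
      seed = 100 + n_loci)
    mean(sapply(seq_len(n_rep), function(r) {
      obs <- summarize_msat(simulate_msat_dataset(
        snm_model(2500), mutation_model(p_gsm = 0.2, gamma_shape = 2),
        n_loci, 20, seed = 200 * n_loci + r), "single")
      rf_model_choice(ref, obs, n_trees = 200,
                      seed = 300 + r)$selected == "large"
    }))
  }
  # information endpoints: 2 loci vs 32 loci
  expect_gte(pick_rate(32), pick_rate(2))
})

test_that("posterior-predictive checks pass for self-generated data", {
  priors <- list(S = default_priors("SNM"))
  ref <- build_reference_table(list(S = "SNM"), priors, n_sims = 600,
                               sample_sizes = 15, n_loci = 8, seed = 91)
  obs_tab <- simulate_msat_dataset(snm_model(1500),
                                   mutation_model(p_gsm = 0.2,
                                                  gamma_shape = 2),
                                   8, 15, seed = 92)
  obs <- summarize_msat(obs_tab, "single")
  post <- estimate_posterior(ref, obs, tolerance = 0.2, method = "rejection")
  gof <- goodness_of_fit("SNM", post, obs, sample_sizes = 15, n_loci = 8,
                         n_ppc = 60, seed = 93)
  expect_lte(sum(gof$flagged), 1)
  expect_true(all(gof$p > 0 & gof$p <= 1))
  expect_error(goodness_of_fit("SNM", post, obs, sample_sizes = 15,
                               n_ppc = 0), "count")
})
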