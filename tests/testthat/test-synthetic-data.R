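test_that("F-model generator hits its differentiation target in the limits", {
  x0 <- balding_nichols_table(c(40, 40), n_loci = 6, target_fst = 0,
                              seed = 1)
  expect_lt(abs(wright_fst(x0)), 0.03)
  # near-fixation limit with 2 alleles
  fs <- sapply(1:10, function(s) {
    x1 <- balding_nichols_table(c(30, 30), n_loci = 4, target_fst = 0.95,
                                n_alleles = 2, ancestral_freqs = "uniform-k",
                                seed = 10 + s)
    wright_fst(x1)
  })
  expect_gt(mean(fs), 0.8)
})

test_that("F-model generator is calibrated in expectation at F = 0.11", {
  # scaled-down version of the 500-replicate calibration (full version in
  # the acceptance suite)
  f <- sapply(1:60, function(s) {
    wright_fst(balding_nichols_table(c(80, 80), n_loci = 8,
                                     target_fst = 0.11, seed = 900 + s))
  })
  se <- sd(f) / sqrt(length(f))
  expect_lt(abs(mean(f) - 0.11), 3 * se + 0.01)
})

test_that("generators are bit-identical under a fixed seed", {
  a <- balding_nichols_table(c(10, 10), n_loci = 3, seed = 5)
  b <- balding_nichols_table(c(10, 10), n_loci = 3, seed = 5)
  expect_identical(a$alleles, b$alleles)
  c1 <- two_clade_cpdna(n_seq = 20, seq_len = 200, seed = 6)
  c2 <- two_clade_cpdna(n_seq = 20, seq_len = 200, seed = 6)
  expect_identical(c1$matrix, c2$matrix)
  expect_identical(c1$pop, c2$pop)
  d1 <- coalescent_table(snm_model(500), mutation_model(), 10, 4, seed = 7)
  d2 <- coalescent_table(snm_model(500), mutation_model(), 10, 4, seed = 7)
  expect_identical(d1$alleles, d2$alleles)
})

test_that("two-clade alignment has the designed haplotype structure", {
  # no within-clade mutation: exactly 2 haplotypes, pi known in closed form
  a <- two_clade_cpdna(n_seq = 40, seq_len = 100, n_mut_within = 0,
                       n_mut_between = 5, clade_fraction = 0.5, seed = 11)
  s <- seq_diversity(a)
  expect_equal(s$H, 2L)
  n1 <- sum(a$clade == "cladeA"); n2 <- sum(a$clade == "cladeB")
  expect_equal(s$pi, 5 * n1 * n2 / choose(40, 2) / 100, tolerance = 1e-12)
  # two sequences, one per clade: h = 1
  b <- two_clade_cpdna(n_seq = 2, seq_len = 50, n_mut_within = 0,
                       n_mut_between = 2, clade_fraction = 0.5, seed = 2)
  expect_equal(seq_diversity(b)$h, 1)
  expect_error(two_clade_cpdna(n_seq = 10, seq_len = 3, n_mut_within = 5,
                               n_mut_between = 2),
               "too small")
  expect_error(two_clade_cpdna(n_mut_between = 0), ">= 1")
})

test_that("spatial labels of the two-clade alignment carry no signal", {
  a <- two_clade_cpdna(n_seq = 60, seq_len = 300, n_mut_within = 6,
                       n_mut_between = 4, seed = 23)
  ph <- phi_st(a, "pop", n_perm = 99, seed = 1)
  expect_lt(abs(ph$phi_st), 0.2)
  # clade labels, in contrast, explain most variance
  ph2 <- phi_st(a, "clade", n_perm = 99, seed = 2)
  expect_gt(ph2$phi_st, 0.5)
  expect_lt(ph2$p, 0.05)
})

test_that("divergence simulation at the published posterior modes brackets the observed FST", {
  mut <- mutation_model(5e-4, p_gsm = 0.98, gamma_shape = 1.594)
  dvm <- dvm_model(1327, 588, 1975, 783, m12 = 0.0013, m21 = 0.0013)
  fs <- sapply(1:8, function(s) {
    x <- simulate_msat_dataset(dvm, mut, 8, c(60, 60), seed = 1300 + s)
    fst_amova(x)
  })
  expect_lt(min(fs), 0.112)
  expect_gt(max(fs), 0.112)
})

test_that("coalescent-backed table reflects the demographic model", {
  # zero mutation: monomorphic
  x <- coalescent_table(snm_model(100), mutation_model(mu_mean = 0), 10, 2,
                        seed = 3)
  expect_equal(length(unique(c(x$alleles))), 1L)
  # long isolation: strong allele-size divergence between groups
  y <- coalescent_table(dvm_model(500, 500, 1000, 5e4, 0, 0),
                        mutation_model(5e-4), c(15, 15), 8, seed = 4)
  r <- rst_permutation_test(y, n_perm = 99, seed = 5)
  expect_gt(r$rst, 0.5)
})
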