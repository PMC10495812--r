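test_that("diversity matches hand-computed Nei statistics", {
  # monomorphic locus
  x <- toy_table(list(cbind(c(100L, 100L), c(100L, 100L))))
  d <- diversity(x, by = "total")
  row <- d[d$locus == "locus1", ]
  expect_equal(row$Na, 1); expect_equal(row$Ne, 1)
  expect_equal(row$He, 0); expect_equal(row$Ho, 0)
  expect_true(is.na(row$Fis))
  # all heterozygous 100/102
  x2 <- toy_table(list(cbind(rep(100L, 4), rep(102L, 4))))
  r2 <- diversity(x2, by = "total")[1, ]
  expect_equal(r2$Ho, 1); expect_equal(r2$He, 0.5); expect_equal(r2$Fis, -1)
  # 2 individuals (100/102, 100/100): p100 = 0.75
  x3 <- toy_table(list(cbind(c(100L, 100L), c(102L, 100L))))
  r3 <- diversity(x3, by = "total")[1, ]
  expect_equal(r3$He, 0.375); expect_equal(r3$Ho, 0.5)
  expect_equal(r3$Ne, 1.6); expect_equal(r3$Fis, -1 / 3)
})

test_that("He equals 1 - sum(p^2) on random tables (property)", {
  for (s in 1:8) {
    x <- random_table(n = 15, L = 6, seed = 200 + s)
    d <- diversity(x, by = "total")
    for (l in seq_len(n_loci(x))) {
      o <- oracle_locus_stats(x$alleles[, l, 1], x$alleles[, l, 2])
      row <- d[d$locus == x$loci[l], ]
      expect_equal(row$He, o$He, tolerance = 1e-12)
      expect_equal(row$Ne, o$Ne, tolerance = 1e-12)
      expect_equal(row$Ho, o$Ho, tolerance = 1e-12)
      expect_true(row$Na >= row$Ne)
      expect_true(row$He >= 0 && row$He <= 1)
    }
  }
})

test_that("all-missing stratum yields flagged entries, not silent zeros", {
  al <- array(10L, dim = c(4, 2, 2))
  al[3:4, 2, ] <- NA_integer_
  x <- msat_table(al, pop = c("a", "a", "b", "b"))
  d <- diversity(x, by = "pop")
  row <- d[d$stratum == "b" & d$locus == "locus2", ]
  expect_true(is.na(row$He))
  expect_equal(row$n_typed, 0)
})

test_that("Hardy-Weinberg Monte-Carlo test behaves at the extremes", {
  # perfect HW proportions: null datasets rarely give small p
  ps <- sapply(1:40, function(s) {
    x <- balding_nichols_table(c(50), n_loci = 1, target_fst = 0,
                               n_alleles = 2, ancestral_freqs = "uniform-k",
                               seed = 300 + s)
    hwe_test(x, 1, n_perm = 199, seed = s)$p
  })
  expect_gte(mean(ps > 0.05), 0.80)
  # complete heterozygote deficit: decisive rejection
  al <- array(rep(c(rep(10L, 25), rep(12L, 25)), 2), dim = c(50, 1, 2))
  expect_lte(hwe_test(msat_table(al), 1, n_perm = 4999, seed = 1)$p, 0.001)
  expect_error(hwe_test(msat_table(al), 1, n_perm = 0), "count")
  # monomorphic: flagged p = 1
  mono <- toy_table(list(cbind(rep(10L, 5), rep(10L, 5))))
  res <- hwe_test(mono, 1, n_perm = 99)
  expect_equal(res$p, 1)
  expect_true(res$monomorphic)
})

test_that("AMOVA recovers maximal and null differentiation", {
  # two pops fixed for different alleles at every locus
  g <- lapply(1:3, function(l) cbind(c(rep(10L, 5), rep(20L, 5)),
                                     c(rep(10L, 5), rep(20L, 5))))
  x <- toy_table(g, pop = rep(c("a", "b"), each = 5))
  res <- amova(x, n_perm = 99, seed = 1)
  expect_equal(unname(res$phi["phi_ST"]), 1)
  expect_equal(unname(res$percent["among"]), 100)
  expect_equal(fst_amova(x, by = "pop"), 1)
  # random labels: among-component near zero
  y <- random_table(n = 20, L = 5, n_pop = 2, missing_rate = 0, seed = 9)
  resr <- amova(y, n_perm = 199, seed = 2)
  expect_lt(abs(unname(resr$phi["phi_ST"])), 0.15)
  expect_gt(unname(resr$p_values["phi_ST"]), 0.01)
})

test_that("three-level AMOVA equals the brute-force decomposition", {
  set.seed(77)
  al <- array(sample(10:14, 16 * 2 * 2, TRUE), dim = c(16, 2, 2))
  x <- msat_table(al, pop = rep(paste0("p", 1:4), each = 4),
                  group = rep(c("g1", "g2"), each = 8))
  res <- amova(x, strata = "group/pop", n_perm = 0)
  d2 <- oracle_genotype_dist(x)
  # oracle: nested sums of squares with equal sizes (n per pop = 4)
  n <- 16
  ss_tot <- sum(d2[upper.tri(d2)]) / n
  ssw <- function(f) sum(sapply(unique(f), function(s) {
    i <- which(f == s)
    sum(d2[i, i][upper.tri(d2[i, i])]) / length(i)
  }))
  ss_wp <- ssw(x$pop); ss_wg <- ssw(x$group)
  msw <- ss_wp / (16 - 4)
  msap <- (ss_wg - ss_wp) / (4 - 2)
  msag <- (ss_tot - ss_wg) / (2 - 1)
  sc <- msw; sb <- (msap - sc) / 4; sa <- (msag - sc - 4 * sb) / 8
  expect_equal(unname(res$components),
               unname(c(sa, sb, sc)), tolerance = 1e-9)
  expect_equal(sum(res$percent), 100, tolerance = 1e-9)
  # degenerate stratum detected
  expect_error(amova_dist(d2, pop = c("solo", rep("rest", 15))),
               "size 1.*solo")
})

test_that("standardized F'ST dominates FST and hits its bounds", {
  # groups sharing no alleles: recoding is the identity, F'ST = 1
  g <- lapply(1:2, function(l) cbind(c(10L, 11L, 20L, 21L),
                                     c(11L, 10L, 21L, 20L)))
  x <- toy_table(g, pop = rep(c("a", "b"), each = 2),
                 group = rep(c("a", "b"), each = 2))
  fp <- fst_prime(x)
  expect_equal(fp$fst_prime, 1, tolerance = 1e-9)
  # identical groups: both near zero
  x0 <- balding_nichols_table(c(60, 60), n_loci = 6, target_fst = 0,
                              seed = 13)
  fp0 <- fst_prime(x0)
  expect_lt(abs(fp0$fst), 0.05)
  expect_lt(abs(fp0$fst_prime), 0.12)
  # inequality on random differentiated tables
  for (s in 1:5) {
    xb <- balding_nichols_table(c(25, 25), n_loci = 5, target_fst = 0.2,
                                seed = 400 + s)
    f <- fst_prime(xb)
    expect_gte(f$fst_prime, f$fst - 1e-9)
  }
  # all-monomorphic: undefined flag
  mono <- toy_table(list(cbind(rep(10L, 4), rep(10L, 4))),
                    pop = rep(c("a", "b"), 2), group = rep(c("a", "b"), 2))
  expect_true(is.na(fst_prime(mono)$fst_prime))
})

test_that("RST permutation test flags stepwise structure only", {
  # fixed sizes 100 vs 120: RST = 1
  al <- array(rep(c(rep(100L, 10), rep(120L, 10)), 2), dim = c(20, 1, 2))
  x <- msat_table(al, pop = rep(c("a", "b"), each = 10),
                  group = rep(c("a", "b"), each = 10))
  r <- rst_permutation_test(x, n_perm = 99, seed = 1)
  expect_equal(r$rst, 1, tolerance = 1e-9)
  # repeat-scale requirement and monomorphic exclusion
  xb <- x; xb$repeat_unit <- 2L
  expect_error(rst_permutation_test(xb), "repeat scale")
  al2 <- array(10L, dim = c(6, 2, 2))
  al2[, 1, ] <- rep(c(10L, 12L, 14L), 4)
  xm <- msat_table(al2, pop = rep(c("a", "b"), 3))
  expect_warning(rst_permutation_test(xm, by = "pop", n_perm = 49, seed = 2),
                 "monomorphic")
  # divergence simulated under stepwise mutation: RST >> pRST mostly
  hits <- sapply(1:8, function(s) {
    y <- coalescent_table(dvm_model(800, 800, 1600, 4000, 1e-4, 1e-4),
                          mutation_model(5e-4), c(12, 12), 6,
                          seed = 500 + s)
    rr <- rst_permutation_test(y, n_perm = 199, seed = s)
    (rr$rst > rr$p_rst) && (rr$p < 0.05)
  })
  expect_gte(mean(hits), 0.5)
})

test_that("PCoA reproduces known geometry", {
  # three points with mutual distance 1: equilateral triangle
  d <- matrix(1, 3, 3); diag(d) <- 0
  fit <- pcoa(d)
  got <- as.matrix(dist(fit$points))
  expect_equal(unname(got), unname(d), tolerance = 1e-9)
  # round-trip from known 2-D configuration
  set.seed(5)
  pts <- matrix(rnorm(20), 10, 2)
  d2 <- as.matrix(dist(pts))
  fit2 <- pcoa(d2, k = 2)
  expect_equal(unname(as.matrix(dist(fit2$points))), unname(d2),
               tolerance = 1e-9)
  expect_true(all(diff(fit2$eig) <= 1e-9))
  # degenerate and invalid inputs
  z <- pcoa(matrix(0, 4, 4))
  expect_true(all(z$points == 0))
  expect_error(pcoa(matrix(1:9, 3, 3)), "symmetric")
})

test_that("sequential Bonferroni matches the Holm ordering", {
  p <- c(0.01, 0.04, 0.03, 0.6)
  expect_equal(sequential_bonferroni(p), p.adjust(p, "holm"))
})
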