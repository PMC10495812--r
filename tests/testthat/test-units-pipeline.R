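test_that("unit delimitation follows the MU and ESU rules", {
  # strong nuclear divergence, low dispersal, admixed plastid clades:
  # one ESU, two MUs (the configuration reported for the study system)
  d <- delimit_units(nuclear_p = 0.001, migration_rates = c(0.0077, 0.0085),
                     plastid_clades_monophyletic = TRUE,
                     plastid_spatially_segregated = FALSE)
  expect_equal(d$n_ESU, 1L)
  expect_equal(d$n_MU, 2L)
  # high dispersal overrides significance
  d2 <- delimit_units(0.0001, c(0.5, 0.5))
  expect_equal(d2$n_MU, 1L)
  # non-significant divergence
  d3 <- delimit_units(0.4, c(0.001, 0.001))
  expect_equal(d3$n_MU, 1L)
  # full ESU case
  d4 <- delimit_units(0.001, c(0.01), TRUE, TRUE)
  expect_equal(d4$n_ESU, 2L)
  expect_equal(d4$n_MU, 2L)
  # missing plastid evidence: ESU stays 1, flagged indeterminate
  d5 <- delimit_units(0.001, c(0.01), NA, NA)
  expect_equal(d5$n_ESU, 1L)
  expect_true(d5$esu_indeterminate)
  expect_error(delimit_units(0.01, 0.01, alpha = 1.2), "alpha")
})

test_that("the decision rule is monotone in p and m", {
  ps <- c(0.2, 0.04, 0.001)
  ms <- c(0.5, 0.09, 0.001)
  last <- 0L
  for (p in ps) for (m in rev(ms)) {
    n_mu <- delimit_units(p, m)$n_MU
    expect_true(n_mu %in% c(1L, 2L))
  }
  # lowering m (or p) never decreases the MU count
  grid <- expand.grid(p = ps, m = ms)
  val <- mapply(function(p, m) delimit_units(p, m)$n_MU, grid$p, grid$m)
  for (i in seq_len(nrow(grid))) for (j in seq_len(nrow(grid))) {
    if (grid$p[j] <= grid$p[i] && grid$m[j] <= grid$m[i])
      expect_gte(val[j], val[i])
  }
})

test_that("unit conversions are exact", {
  expect_equal(generations_to_years(100, 25), 2500)
  expect_equal(migration_fraction(2, 1000), 0.002)
  expect_error(migration_fraction(1, 0))
})

test_that("pipeline runs end-to-end on synthetic data and is deterministic", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  cfg <- list(seed = 11L, n_perm = 49L,
              msat = list(synthetic = TRUE,
                          n_ind_per_group = c(40L, 40L), n_loci = 6L,
                          target_fst = 0.25),
              cpdna = list(synthetic = TRUE, n_seq = 40L, seq_len = 300L,
                           n_mut_within = 5L, n_mut_between = 4L),
              migration_rates = c(0.005, 0.008))
  rep1 <- run_pipeline(c(cfg, list(out_dir = out1)))
  rep2 <- run_pipeline(c(cfg, list(out_dir = out2)))
  # strong divergence settings: two MUs
  expect_equal(rep1$units$n_MU, 2L)
  expect_lt(rep1$nuclear$amova_p, 0.05)
  # same config + seed: byte-identical JSON report
  expect_identical(readLines(file.path(out1, "report.json")),
                   readLines(file.path(out2, "report.json")))
  expect_true(file.exists(file.path(out1, "diversity.tsv")))
  expect_true(file.exists(file.path(out1, "log.txt")))
  expect_true(validate_report(rep1))
  expect_true(validate_report(file.path(out1, "report.json")))
})

test_that("pipeline validates its configuration before computing", {
  expect_error(run_pipeline(list(msat = list(synthetic = FALSE,
                                             path = NULL))),
               "config error")
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("t", "locA", "Pop", "i1 , 001001"), f)
  expect_error(run_pipeline(list(msat = list(synthetic = FALSE, path = f))),
               "grouping")
})

test_that("report schema violations are caught", {
  bad <- list(config = list(seed = 1, n_perm = 9, alpha = 0.05),
              nuclear = list(fst = 0.1, fst_prime = 0.2, rst = 0.1,
                             amova_pct_among = 10),
              units = list(n_ESU = 2, n_MU = 1))
  expect_error(validate_report(bad), "n_MU >= n_ESU")
  bad2 <- bad
  bad2$nuclear$fst <- NULL
  expect_error(validate_report(bad2), "fst")
})

test_that("spatial plastid structure test distinguishes the two regimes", {
  # admixed (generator default): not segregated
  a <- two_clade_cpdna(n_seq = 60, seq_len = 300, n_mut_within = 4,
                       n_mut_between = 4, seed = 31)
  s <- plastid_spatial_structure(a, n_perm = 99, seed = 1)
  expect_false(s$segregated)
  # clades perfectly tracking geography: segregated
  b <- a
  b$pop <- ifelse(b$clade == "cladeA", "siteW", "siteE")
  s2 <- plastid_spatial_structure(b, n_perm = 99, seed = 2)
  expect_true(s2$segregated)
})
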