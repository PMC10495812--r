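# End-to-end orchestration: statistics -> (optional) ABC -> delimitation,
# with a JSON report, TSV tables and a plain-text log.

#' Spatial segregation of plastid clades
#'
#' Operationalizes "clades structured in space" as a permutation test:
#' phiST of clade membership (0/1 mismatch distance) across spatial
#' labels. Segregated clades give a large, significant statistic; admixed
#' clades give a value near 0.
#'
#' @param aln a [seq_alignment()] with `clade` and `pop` labels.
#' @param threshold phiST above which clades count as segregated.
#' @param alpha significance level.
#' @param n_perm,seed permutation settings.
#' @return list with `phi_spatial`, `p`, `segregated` (logical).
#' @export
plastid_spatial_structure <- function(aln, threshold = 0.2, alpha = 0.05,
                                      n_perm = 999L, seed = NULL) {
  if (is.null(aln$clade) || is.null(aln$pop))
    stop_input("alignment needs both `clade` and `pop` labels")
  keep <- aln$pop %in% names(which(table(aln$pop) >= 2L))
  d2 <- 1 * outer(aln$clade[keep], aln$clade[keep], "!=")
  res <- amova_dist(d2, pop = aln$pop[keep], n_perm = n_perm, seed = seed)
  phi <- unname(res$phi["phi_ST"])
  p <- unname(res$p_values["phi_ST"])
  list(phi_spatial = phi, p = p,
       segregated = is.finite(phi) && phi > threshold && p < alpha)
}

#' Re-run the reference nuclear analysis on a genotype file
#'
#' Computes the headline nuclear statistics (overall allele count and
#' heterozygosities, between-group FST and F'ST, among-group variance
#' percent, RST and pRST) from a GenePop file and a population-to-group
#' mapping. Intended for re-analysis of the published microsatellite
#' dataset when it is available locally.
#'
#' @param genepop_path GenePop file.
#' @param mapping pop -> group named vector (or YAML path via
#'   [read_grouping()]).
#' @param n_perm,seed permutation settings.
#' @param repeat_unit allele-size scale of the file.
#' @return named list of statistics.
#' @export
reference_reanalysis <- function(genepop_path, mapping, n_perm = 999L,
                                 seed = NULL, repeat_unit = 1L) {
  x <- read_genepop(genepop_path, repeat_unit = repeat_unit)
  if (is.character(mapping) && length(mapping) == 1L)
    mapping <- read_grouping(mapping)$mapping
  x <- assign_groups(x, mapping)
  div <- diversity(x, by = "total")
  tot <- div[div$locus != "mean", ]
  fp <- fst_prime(x, by = "group")
  am <- amova(x, strata = "group", n_perm = n_perm, seed = seed)
  rst <- rst_permutation_test(to_repeat_scale(x), by = "group",
                              n_perm = n_perm, seed = seed)
  list(n_alleles_total = sum(tot$Na), ho_overall = mean(tot$Ho),
       he_overall = mean(tot$He), fst = fp$fst, fst_prime = fp$fst_prime,
       amova_pct_among = unname(am$percent["among"]),
       amova_p = unname(am$p_values["phi_ST"]),
       rst = rst$rst, p_rst = rst$p_rst, rst_p = rst$p)
}

default_config <- function() {
  list(
    seed = 1L,
    n_perm = 999L,
    alpha = 0.05,
    generation_length = 25,
    msat = list(synthetic = TRUE),
    cpdna = list(synthetic = TRUE),
    migration_rates = NULL,
    abc = list(enabled = FALSE, n_sims = 600L, n_trees = 500L,
               tolerance = 0.1, n_loci = 8L,
               sample_sizes = c(25L, 25L)),
    out_dir = NULL)
}

load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  if (is.null(cfg$msat$synthetic) || !isTRUE(cfg$msat$synthetic)) {
    if (is.null(cfg$msat$path))
      stop_input("config error: msat input needs `path` or `synthetic: true`")
    if (is.null(cfg$msat$grouping))
      stop_input("config error: msat input needs a `grouping` mapping")
  }
  cfg
}

#' Run the full conservation-unit pipeline
#'
#' Executes the nuclear statistics stage, the chloroplast stage, the
#' optional ABC stage, and the unit-delimitation rule; writes a JSON
#' report (deterministic for a fixed config and seed), TSV statistic
#' tables and a plain-text log when `out_dir` is set.
#'
#' @param config a list or YAML file path. Keys (all optional except the
#'   inputs): `seed`, `n_perm`, `alpha`, `generation_length`;
#'   `msat = list(path=, grouping=)` or `list(synthetic = TRUE, ...)`
#'   (extra entries passed to [balding_nichols_table()]);
#'   `cpdna = list(path=, clades=)` or `list(synthetic = TRUE, ...)`;
#'   `migration_rates` (per-direction per-generation rates supplied from
#'   an external analysis); `abc = list(enabled=, n_sims=, n_trees=,
#'   tolerance=, n_loci=, sample_sizes=)`; `out_dir`.
#' @return the report, an object of class `pipeline_report` (a nested
#'   list mirroring the JSON).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- load_pipeline_config(config)
  log_lines <- c(sprintf("coalunits pipeline; seed = %d", cfg$seed),
                 sprintf("R %s.%s", R.version$major, R.version$minor))
  set.seed(cfg$seed)

  # --- nuclear stage -------------------------------------------------
  if (isTRUE(cfg$msat$synthetic)) {
    args <- cfg$msat[setdiff(names(cfg$msat), c("synthetic", "path",
                                                "grouping"))]
    x <- do.call(balding_nichols_table,
                 c(args, list(seed = cfg$seed + 101L)))
    log_lines <- c(log_lines, "msat: synthetic Balding-Nichols table")
  } else {
    x <- read_genepop(cfg$msat$path)
    mp <- cfg$msat$grouping
    if (is.character(mp) && length(mp) == 1L) mp <- read_grouping(mp)$mapping
    x <- assign_groups(x, unlist(mp))
    log_lines <- c(log_lines, paste("msat:", cfg$msat$path))
  }
  div <- diversity(x, by = "group")
  fp <- fst_prime(x, by = "group")
  am <- amova(x, strata = "group", n_perm = cfg$n_perm,
              seed = cfg$seed + 1L)
  rst <- rst_permutation_test(to_repeat_scale(x), by = "group",
                              n_perm = cfg$n_perm, seed = cfg$seed + 2L)
  ord <- pcoa(sqrt(genotype_dist(x)), k = 2L)
  nuclear <- list(
    n_ind = n_ind(x), n_loci = n_loci(x),
    fst = fp$fst, fst_max = fp$fst_max, fst_prime = fp$fst_prime,
    amova_pct_among = unname(am$percent["among"]),
    amova_p = unname(am$p_values["phi_ST"]),
    rst = rst$rst, p_rst = rst$p_rst, rst_p = rst$p,
    pcoa_var_explained = ord$var_explained)

  # --- plastid stage -------------------------------------------------
  plastid <- NULL
  if (isTRUE(cfg$cpdna$synthetic) || !is.null(cfg$cpdna$path)) {
    if (isTRUE(cfg$cpdna$synthetic)) {
      args <- cfg$cpdna[setdiff(names(cfg$cpdna), c("synthetic", "path",
                                                    "clades"))]
      aln <- do.call(two_clade_cpdna,
                     c(args, list(seed = cfg$seed + 202L)))
      log_lines <- c(log_lines, "cpdna: synthetic two-clade alignment")
    } else {
      aln <- read_fasta_alignment(cfg$cpdna$path)
      if (!is.null(cfg$cpdna$clades))
        aln$clade <- as.character(unlist(cfg$cpdna$clades))
      log_lines <- c(log_lines, paste("cpdna:", cfg$cpdna$path))
    }
    sdiv <- seq_diversity(aln)
    neut <- neutrality_tests(aln)
    ph <- phi_st(aln, "clade", n_perm = cfg$n_perm, seed = cfg$seed + 3L)
    spatial <- plastid_spatial_structure(aln, alpha = cfg$alpha,
                                         n_perm = cfg$n_perm,
                                         seed = cfg$seed + 4L)
    plastid <- list(
      n_seq = sdiv$n, H = sdiv$H, hap_diversity = sdiv$h,
      nucleotide_diversity = sdiv$pi, S = sdiv$S,
      tajima_D = neut$tajima_D, fu_li_D_star = neut$fu_li_D_star,
      fu_li_F_star = neut$fu_li_F_star,
      phi_st = ph$phi_st, phi_st_prime = ph$phi_st_prime, phi_p = ph$p,
      spatial_phi = spatial$phi_spatial, spatial_p = spatial$p,
      spatially_segregated = spatial$segregated)
  }

  # --- ABC stage (optional) ------------------------------------------
  abc_out <- NULL
  if (isTRUE(cfg$abc$enabled)) {
    ss <- as.integer(cfg$abc$sample_sizes)
    ref <- build_reference_table(
      models = list(DVM1 = "DVM"),
      priors = list(DVM1 = default_priors("DVM")),
      n_sims = cfg$abc$n_sims, sample_sizes = ss,
      n_loci = cfg$abc$n_loci, mode = "pair",
      seed = cfg$seed + 5L)
    sub <- if (n_ind(x) > sum(ss)) {
      idx <- unlist(lapply(seq_along(ss), function(g) {
        rows <- which(x$group == unique(x$group)[g])
        sample(rows, min(ss[g], length(rows)))
      }))
      subset_ind(x, sort(idx))
    } else x
    obs <- summarize_msat(to_repeat_scale(sub), mode = "pair")
    post <- estimate_posterior(ref, obs, tolerance = cfg$abc$tolerance,
                               method = "loclinear")
    abc_out <- list(
      n_sims = cfg$abc$n_sims,
      posterior = lapply(seq_len(nrow(post$summary)), function(i) {
        s <- post$summary[i, ]
        list(parameter = s$parameter, mode = s$mode,
             hpd_lower = s$hpd_lower, hpd_upper = s$hpd_upper)
      }))
    log_lines <- c(log_lines,
                   sprintf("abc: %d simulations, tolerance %.3g",
                           cfg$abc$n_sims, cfg$abc$tolerance))
  }

  # --- delimitation ---------------------------------------------------
  m_rates <- cfg$migration_rates
  if (is.null(m_rates)) {
    m_rates <- 1  # unknown dispersal: fails the <10% rule conservatively
    log_lines <- c(log_lines,
                   "migration rates not supplied; MU rule cannot pass")
  }
  decision <- delimit_units(
    nuclear_p = nuclear$amova_p,
    migration_rates = as.numeric(m_rates),
    plastid_clades_monophyletic = if (!is.null(plastid)) TRUE else NA,
    plastid_spatially_segregated = if (!is.null(plastid))
      plastid$spatially_segregated else NA,
    alpha = cfg$alpha)

  report <- list(
    config = list(seed = cfg$seed, n_perm = cfg$n_perm, alpha = cfg$alpha,
                  generation_length = cfg$generation_length),
    nuclear = nuclear,
    plastid = plastid,
    abc = abc_out,
    units = list(n_ESU = decision$n_ESU, n_MU = decision$n_MU,
                 nuclear_divergence_significant =
                   decision$nuclear_divergence_significant,
                 migration_below_threshold =
                   decision$migration_below_threshold,
                 max_migration = decision$max_migration,
                 rationale = decision$rationale))
  class(report) <- c("pipeline_report", "list")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    write.table(as.data.frame(div),
                file.path(cfg$out_dir, "diversity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(log_lines, file.path(cfg$out_dir, "log.txt"))
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("coalunits pipeline report\n")
  cat(sprintf("  nuclear: FST = %.4f, F'ST = %.4f, RST = %.4f (p = %.3g)\n",
              x$nuclear$fst, x$nuclear$fst_prime, x$nuclear$rst,
              x$nuclear$rst_p))
  if (!is.null(x$plastid))
    cat(sprintf("  plastid: H = %d, h = %.3f, pi = %.3g\n",
                x$plastid$H, x$plastid$hap_diversity,
                x$plastid$nucleotide_diversity))
  cat(sprintf("  units: %d ESU, %d MU\n", x$units$n_ESU, x$units$n_MU))
  invisible(x)
}

#' Validate a pipeline report against the package's report schema
#'
#' Structural validation (required fields and types) against the JSON
#' schema shipped at `inst/schema/report-schema.json`.
#'
#' @param report a `pipeline_report` or path to a report JSON file.
#' @return TRUE invisibly; errors describing the first violation.
#' @export
validate_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  need <- function(obj, keys, where) {
    miss <- setdiff(keys, names(obj))
    if (length(miss))
      stop_input("report invalid: missing ", where, " field(s): ",
                 paste(miss, collapse = ", "))
  }
  need(report, c("config", "nuclear", "units"), "top-level")
  need(report$config, c("seed", "n_perm", "alpha"), "config")
  need(report$nuclear, c("fst", "fst_prime", "rst", "amova_pct_among"),
       "nuclear")
  need(report$units, c("n_ESU", "n_MU"), "units")
  if (!is.numeric(report$units$n_ESU) || !is.numeric(report$units$n_MU) ||
      report$units$n_MU < report$units$n_ESU || report$units$n_ESU < 1)
    stop_input("report invalid: unit counts must satisfy n_MU >= n_ESU >= 1")
  invisible(TRUE)
}
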