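#' Diploid microsatellite genotype table
#'
#' The central container for nuclear SSR data: an `n x L x 2` integer array
#' of allele sizes (repeat counts or base pairs, declared via `repeat_unit`),
#' a population label per individual, optional group labels (e.g. the
#' east/west clusters a Bayesian assignment produced) and optional
#' coordinates. Missing genotypes are `NA` in both slots of a locus.
#'
#' @param alleles integer array `n x L x 2` of allele sizes; `NA` marks a
#'   missing genotype and must cover both gene copies of a genotype.
#' @param ids character vector of individual identifiers (length `n`).
#' @param loci character vector of locus names (length `L`).
#' @param pop character vector of population labels, one per individual.
#' @param group optional character vector of group labels; when present each
#'   population must map to exactly one group.
#' @param coords optional two-column numeric matrix of coordinates.
#' @param repeat_unit positive integer: number of base pairs per repeat unit
#'   on the stored scale (1 means sizes are already repeat counts).
#' @return an object of class `msat_table`.
#' @export
msat_table <- function(alleles, ids = NULL, loci = NULL, pop = NULL,
                       group = NULL, coords = NULL, repeat_unit = 1L) {
  if (length(dim(alleles)) != 3L || dim(alleles)[3] != 2L)
    stop_input("`alleles` must be an n x L x 2 array")
  n <- dim(alleles)[1]; L <- dim(alleles)[2]
  if (n < 1L || L < 1L) stop_input("empty genotype table")
  storage.mode(alleles) <- "integer"
  ids  <- as.character(ids  %||% paste0("ind", seq_len(n)))
  loci <- as.character(loci %||% paste0("locus", seq_len(L)))
  pop  <- as.character(pop  %||% rep("pop1", n))
  if (length(ids) != n)  stop_input("`ids` length does not match rows")
  if (length(loci) != L) stop_input("`loci` length does not match loci")
  if (length(pop) != n)  stop_input("`pop` length does not match rows")
  half_missing <- xor(is.na(alleles[, , 1, drop = FALSE]),
                      is.na(alleles[, , 2, drop = FALSE]))
  if (any(half_missing))
    stop_input("missing mask must cover both or neither allele of a genotype")
  if (any(alleles <= 0L, na.rm = TRUE))
    stop_input("allele sizes must be positive integers")
  if (!is.null(group)) {
    group <- as.character(group)
    if (length(group) != n) stop_input("`group` length does not match rows")
    map <- unique(data.frame(pop = pop, group = group))
    if (anyDuplicated(map$pop))
      stop_input("group labels must partition populations: a population maps",
                 " to more than one group")
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 2L)
      stop_input("`coords` must be an n x 2 matrix")
  }
  if (!is_count(repeat_unit)) stop_input("`repeat_unit` must be a count")
  dimnames(alleles) <- list(ids, loci, c("a1", "a2"))
  structure(
    list(alleles = alleles, ids = ids, loci = loci, pop = pop,
         group = group, coords = coords, repeat_unit = as.integer(repeat_unit)),
    class = "msat_table")
}

#' @export
print.msat_table <- function(x, ...) {
  cat("msat_table:", n_ind(x), "individuals x", n_loci(x), "loci\n")
  cat("  populations:", length(unique(x$pop)),
      if (!is.null(x$group)) paste0("; groups: ",
                                    paste(unique(x$group), collapse = ", ")),
      "\n", sep = "")
  miss <- mean(is.na(x$alleles[, , 1]))
  cat(sprintf("  missing genotypes: %.1f%%; repeat_unit: %d\n",
              100 * miss, x$repeat_unit))
  invisible(x)
}

#' @rdname msat_table
#' @param x an `msat_table`.
#' @export
n_ind <- function(x) dim(x$alleles)[1]

#' @rdname msat_table
#' @export
n_loci <- function(x) dim(x$alleles)[2]

#' Subset a genotype table by individuals
#' @param x an `msat_table`.
#' @param i integer or logical index over individuals.
#' @return an `msat_table` with the selected individuals.
#' @export
subset_ind <- function(x, i) {
  msat_table(x$alleles[i, , , drop = FALSE], ids = x$ids[i], loci = x$loci,
             pop = x$pop[i], group = x$group[i],
             coords = if (!is.null(x$coords)) x$coords[i, , drop = FALSE],
             repeat_unit = x$repeat_unit)
}

#' Convert stored allele sizes to the repeat scale
#'
#' Divides base-pair sizes by `repeat_unit`; a no-op when sizes are stored
#' as repeat counts already. Allele-size based statistics (RST, GSM work)
#' require the repeat scale.
#' @param x an `msat_table`.
#' @return an `msat_table` with `repeat_unit = 1`.
#' @export
to_repeat_scale <- function(x) {
  if (x$repeat_unit == 1L) return(x)
  a <- x$alleles
  if (any(a %% x$repeat_unit != 0L, na.rm = TRUE))
    stop_input("allele sizes are not multiples of `repeat_unit`")
  x$alleles <- a %/% x$repeat_unit
  x$repeat_unit <- 1L
  x
}

# stratum labels for an msat_table: "pop", "group" or "total"
strata_labels <- function(x, by = c("pop", "group", "total")) {
  by <- match.arg(by)
  switch(by,
    pop = x$pop,
    group = {
      if (is.null(x$group)) stop_input("table has no group labels")
      x$group
    },
    total = rep("total", n_ind(x)))
}

#' Attach group labels from a population-to-group mapping
#'
#' @param x an `msat_table`.
#' @param mapping named character vector or list: `mapping[[pop]] = group`.
#' @return the table with `group` filled in.
#' @export
assign_groups <- function(x, mapping) {
  mapping <- unlist(mapping)
  missing_pops <- setdiff(unique(x$pop), names(mapping))
  if (length(missing_pops))
    stop_input("no group assignment for population(s): ",
               paste(missing_pops, collapse = ", "))
  x$group <- unname(mapping[x$pop])
  # revalidate
  msat_table(x$alleles, ids = x$ids, loci = x$loci, pop = x$pop,
             group = x$group, coords = x$coords, repeat_unit = x$repeat_unit)
}

#' Read a population-to-group sidecar file
#'
#' YAML with a top-level `groups` mapping (`group name -> vector of pops`)
#' and optionally `coordinates` (`pop -> [x, y]`).
#' @param path YAML file path.
#' @return list with elements `mapping` (pop -> group named vector) and
#'   `coordinates` (pop-named matrix or NULL).
#' @export
read_grouping <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$groups)) stop_input("grouping YAML lacks a `groups` mapping")
  mapping <- unlist(lapply(names(y$groups), function(g) {
    pops <- as.character(y$groups[[g]])
    setNames(rep(g, length(pops)), pops)
  }))
  if (anyDuplicated(names(mapping)))
    stop_input("a population appears in more than one group")
  coords <- NULL
  if (!is.null(y$coordinates)) {
    coords <- do.call(rbind, lapply(y$coordinates, as.numeric))
    rownames(coords) <- names(y$coordinates)
  }
  list(mapping = mapping, coordinates = coords)
}
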