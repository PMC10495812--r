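#' Read a STRUCTURE genotype file (two-row-per-individual layout)
#'
#' Expected columns: individual id, population index, then one column per
#' locus; each individual occupies two consecutive rows (one gene copy per
#' row). `-9` encodes missing data. An optional header row of locus names is
#' auto-detected (non-numeric first row).
#'
#' @param path STRUCTURE file.
#' @param repeat_unit passed to [msat_table()].
#' @return an [msat_table()].
#' @export
read_structure <- function(path, repeat_unit = 1L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_input("STRUCTURE parse error: empty file")
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  loci <- NULL
  if (!grepl("^-?[0-9]+$", toks[[1]][2] %||% "")) {
    loci <- toks[[1]]
    toks <- toks[-1]
  }
  if (length(toks) %% 2L != 0L)
    stop_input("STRUCTURE parse error: odd number of genotype rows ",
               "(two rows per individual expected)")
  ncols <- lengths(toks)
  if (length(unique(ncols)) != 1L)
    stop_input("STRUCTURE parse error: ragged rows")
  L <- ncols[1] - 2L
  if (L < 1L) stop_input("STRUCTURE parse error: no locus columns")
  if (!is.null(loci) && length(loci) != L) loci <- NULL
  n <- length(toks) %/% 2L
  alleles <- array(NA_integer_, dim = c(n, L, 2L))
  ids <- character(n); pops <- character(n)
  for (i in seq_len(n)) {
    r1 <- toks[[2L * i - 1L]]; r2 <- toks[[2L * i]]
    if (r1[1] != r2[1])
      stop_input("STRUCTURE parse error: row pair ", i,
                 " has mismatched ids (", r1[1], " vs ", r2[1], ")")
    ids[i] <- r1[1]
    pops[i] <- paste0("pop", r1[2])
    a1 <- suppressWarnings(as.integer(r1[-(1:2)]))
    a2 <- suppressWarnings(as.integer(r2[-(1:2)]))
    if (anyNA(a1) || anyNA(a2))
      stop_input("STRUCTURE parse error: non-integer allele in pair ", i)
    a1[a1 == -9L] <- NA_integer_; a2[a2 == -9L] <- NA_integer_
    miss <- is.na(a1) | is.na(a2)
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    alleles[i, , 1L] <- a1; alleles[i, , 2L] <- a2
  }
  msat_table(alleles, ids = ids, loci = loci, pop = pops,
             repeat_unit = repeat_unit)
}

#' Write a STRUCTURE genotype file (two-row-per-individual layout)
#'
#' @param x an [msat_table()].
#' @param path output file.
#' @param header write a locus-name header row.
#' @export
write_structure <- function(x, path, header = TRUE) {
  if (!inherits(x, "msat_table")) stop_input("`x` must be an msat_table")
  pop_idx <- match(x$pop, unique(x$pop))
  out <- character(0)
  if (header) out <- paste(x$loci, collapse = "\t")
  enc <- function(a) ifelse(is.na(a), "-9", as.character(a))
  for (i in seq_len(n_ind(x))) {
    out <- c(out,
      paste(c(x$ids[i], pop_idx[i], enc(x$alleles[i, , 1L])), collapse = "\t"),
      paste(c(x$ids[i], pop_idx[i], enc(x$alleles[i, , 2L])), collapse = "\t"))
  }
  writeLines(out, path)
  invisible(path)
}
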