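#' Read a GenePop genotype file
#'
#' Supports the common dialect: a title line, locus names (one per line or
#' comma-separated), `Pop` separators, and per-individual lines
#' `id , 001002 003004 ...` with 2- or 3-digit diploid allele codes.
#' All-zero codes (`0000` / `000000`, or a zero half) are mapped to missing
#' genotypes. Populations are named `pop1..popK` in file order unless the
#' last individual id of a population is usable as a label (GenePop
#' convention); here file order naming is used for determinism.
#'
#' @param path GenePop file.
#' @param repeat_unit declared repeat-unit scale passed to [msat_table()].
#' @return an [msat_table()].
#' @export
read_genepop <- function(path, repeat_unit = 1L) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (length(lines) < 3L) stop_input("GenePop parse error: file too short")
  pop_re <- "^[[:space:]]*pop[[:space:]]*$"
  first_pop <- grep(pop_re, tolower(lines))[1]
  if (is.na(first_pop) || first_pop < 3L)
    stop_input("GenePop parse error: no `Pop` separator found")
  locus_lines <- lines[2:(first_pop - 1L)]
  loci <- unlist(strsplit(locus_lines, "[,[:space:]]+"))
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop_input("GenePop parse error: no locus names")
  L <- length(loci)

  ids <- character(); pops <- character(); rows <- list()
  cur_pop <- 0L; width <- NA_integer_
  for (k in seq(first_pop, length(lines))) {
    line <- lines[k]
    if (!nzchar(trimws(line))) next
    if (grepl(pop_re, tolower(line))) { cur_pop <- cur_pop + 1L; next }
    parts <- strsplit(line, ",", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop_input("GenePop parse error at line ", k,
                 ": expected `id , genotypes`")
    id <- trimws(parts[1])
    codes <- strsplit(trimws(parts[2]), "[[:space:]]+")[[1]]
    codes <- codes[nzchar(codes)]
    if (length(codes) != L)
      stop_input("GenePop parse error at line ", k, ": ", length(codes),
                 " genotypes for ", L, " loci")
    if (any(grepl("[^0-9]", codes)))
      stop_input("GenePop parse error at line ", k, ": non-numeric code")
    w <- unique(nchar(codes))
    if (length(w) != 1L || !(w %in% c(4L, 6L)))
      stop_input("GenePop parse error at line ", k,
                 ": genotype codes must be uniformly 4 or 6 digits")
    if (is.na(width)) width <- w
    if (w != width)
      stop_input("GenePop parse error at line ", k,
                 ": mixed 2- and 3-digit dialects")
    half <- width %/% 2L
    a1 <- as.integer(substr(codes, 1L, half))
    a2 <- as.integer(substr(codes, half + 1L, width))
    miss <- a1 == 0L | a2 == 0L
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    ids <- c(ids, id)
    pops <- c(pops, paste0("pop", max(cur_pop, 1L)))
    rows[[length(rows) + 1L]] <- rbind(a1, a2)
  }
  if (!length(rows)) stop_input("GenePop parse error: no individuals")
  n <- length(rows)
  alleles <- array(NA_integer_, dim = c(n, L, 2L))
  for (i in seq_len(n)) {
    alleles[i, , 1L] <- rows[[i]][1L, ]
    alleles[i, , 2L] <- rows[[i]][2L, ]
  }
  msat_table(alleles, ids = ids, loci = loci, pop = pops,
             repeat_unit = repeat_unit)
}

#' Write a GenePop genotype file
#'
#' @param x an [msat_table()].
#' @param path output file.
#' @param digits allele code width, 2 or 3 (the two GenePop dialects).
#' @param title title line content.
#' @return `path`, invisibly. Errors if any allele size does not fit the
#'   chosen code width.
#' @export
write_genepop <- function(x, path, digits = 3L, title = "coalunits export") {
  if (!inherits(x, "msat_table")) stop_input("`x` must be an msat_table")
  if (!digits %in% c(2L, 3L)) stop_input("`digits` must be 2 or 3")
  maxcode <- 10^digits - 1L
  if (any(x$alleles > maxcode, na.rm = TRUE))
    stop_input("allele size exceeds ", digits, "-digit GenePop code; ",
               "rescale or use digits = 3")
  fmt <- paste0("%0", digits, "d")
  code <- function(a) ifelse(is.na(a), paste0(strrep("0", digits)),
                             sprintf(fmt, a))
  out <- c(title, x$loci)
  pops <- unique(x$pop)
  for (p in pops) {
    out <- c(out, "Pop")
    for (i in which(x$pop == p)) {
      g <- paste0(code(x$alleles[i, , 1L]), code(x$alleles[i, , 2L]))
      out <- c(out, paste0(x$ids[i], " , ", paste(g, collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}
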