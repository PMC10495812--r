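#' Aligned haploid sequence set
#'
#' Holds equal-length haploid sequences (chloroplast fragments concatenated
#' and aligned upstream) together with optional clade and spatial labels.
#'
#' @param seqs character vector of equal-length strings over
#'   `A,C,G,T,-,N` (case-insensitive), or a character matrix with one row
#'   per sequence.
#' @param ids sequence identifiers.
#' @param clade optional character vector of clade labels.
#' @param pop optional character vector of spatial/population labels.
#' @return an object of class `seq_alignment` wrapping an `n x L` character
#'   matrix in upper case.
#' @export
seq_alignment <- function(seqs, ids = NULL, clade = NULL, pop = NULL) {
  if (is.matrix(seqs)) {
    m <- toupper(seqs)
  } else {
    seqs <- toupper(as.character(seqs))
    if (!length(seqs)) stop_input("empty alignment")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      ids0 <- ids %||% paste0("seq", seq_along(seqs))
      bad <- ids0[lens != lens[1]]
      stop_input("ragged alignment: sequence length differs for ",
                 paste(bad, collapse = ", "))
    }
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  }
  if (ncol(m) < 1L) stop_input("alignment length must be positive")
  bad_chr <- setdiff(unique(as.vector(m)), c("A", "C", "G", "T", "-", "N"))
  if (length(bad_chr))
    stop_input("invalid alignment characters: ", paste(bad_chr, collapse = " "))
  n <- nrow(m)
  ids <- as.character(ids %||% paste0("seq", seq_len(n)))
  if (length(ids) != n) stop_input("`ids` length mismatch")
  if (!is.null(clade) && length(clade) != n) stop_input("`clade` length mismatch")
  if (!is.null(pop) && length(pop) != n) stop_input("`pop` length mismatch")
  rownames(m) <- ids
  structure(list(matrix = m, ids = ids,
                 clade = if (!is.null(clade)) as.character(clade),
                 pop = if (!is.null(pop)) as.character(pop)),
            class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat("seq_alignment:", nrow(x$matrix), "sequences x", ncol(x$matrix),
      "sites\n")
  if (!is.null(x$clade))
    cat("  clades:", paste(names(table(x$clade)), table(x$clade),
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' All records must have identical length; ragged input is an error listing
#' the offending identifiers.
#' @param path FASTA file.
#' @return a [seq_alignment()].
#' @export
read_fasta_alignment <- function(path) {
  recs <- ape::read.FASTA(path)
  if (!length(recs)) stop_input("no FASTA records in ", path)
  seqs <- vapply(as.character(recs), paste, character(1), collapse = "")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop_input("ragged alignment in ", path, ": ",
               paste(names(recs)[lens != lens[1]], collapse = ", "))
  seq_alignment(seqs, ids = names(recs))
}

#' Write an alignment as FASTA
#' @param aln a [seq_alignment()].
#' @param path output file.
#' @export
write_fasta_alignment <- function(aln, path) {
  seqs <- apply(aln$matrix, 1, paste, collapse = "")
  dna <- ape::as.DNAbin(strsplit(tolower(seqs), "", fixed = TRUE))
  names(dna) <- aln$ids
  ape::write.FASTA(dna, path)
  invisible(path)
}
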