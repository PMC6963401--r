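# Shared low-level helpers: DNA strings, alignment containers, table output.
# Coordinates are 0-based half-open everywhere inside the package; conversion
# to/from 1-based happens only at GenBank/BED boundaries.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x A single character string over the DNA alphabet (IUPAC codes and
#'   `N`/`-` allowed).
#' @return The reverse-complemented string, uppercase.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# complement of a character vector of single bases (A/C/G/T/N only)
complement_chars <- function(v) {
  chartr("ACGTN", "TGCAN", v)
}

# rotate a string so that 0-based position `at` becomes position 0
rotate_string <- function(x, at) {
  n <- nchar(x)
  at <- ((at %% n) + n) %% n
  if (at == 0) return(x)
  paste0(substr(x, at + 1L, n), substr(x, 1L, at))
}

# circular substring, 0-based half-open [start, start + len)
circ_substr <- function(x, start, len) {
  n <- nchar(x)
  start <- ((start %% n) + n) %% n
  if (len <= 0) return("")
  if (start + len <= n) return(substr(x, start + 1L, start + len))
  paste0(substr(x, start + 1L, n), substr(x, 1L, start + len - n))
}

#' Build an alignment matrix
#'
#' Alignments are stored as character matrices: one row per taxon (rownames
#' are taxon ids), one column per alignment column, each cell a single
#' uppercase character.
#'
#' @param x A named character vector of equal-length sequence strings, or an
#'   existing character matrix.
#' @return A character matrix of class `dna_alignment` (the class name
#'   avoids clashing with seqinr/ape's own "alignment" S3 class).
#' @export
as_alignment <- function(x) {
  if (is.matrix(x)) {
    mat <- x
  } else {
    stopifnot(is.character(x))
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    lens <- nchar(x)
    if (length(unique(lens)) != 1L) {
      abort("All sequences in an alignment must have equal length.")
    }
    mat <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(mat) <- names(x)
  }
  if (is.null(rownames(mat))) rownames(mat) <- paste0("seq", seq_len(nrow(mat)))
  mat[] <- toupper(mat)
  class(mat) <- unique(c("dna_alignment", class(mat)))
  mat
}

#' Read a FASTA alignment into an alignment matrix
#'
#' @param path Path to a (possibly gapped) FASTA file.
#' @return An alignment matrix (see [as_alignment()]).
#' @export
read_fasta_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  as_alignment(setNames(toupper(as.character(ss)), names(ss)))
}

#' Write an alignment matrix (or named sequences) to FASTA
#'
#' @param aln An alignment matrix or named character vector of sequences.
#' @param path Output file path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path, width = 70L) {
  if (is.matrix(aln)) {
    seqs <- apply(aln, 1L, paste0, collapse = "")
  } else {
    seqs <- aln
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# Write a tibble as TSV with '# key=value' header lines recording the
# configuration used (the determinism / provenance contract for pipeline
# outputs).
write_tsv_with_header <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(params)) {
    writeLines(paste0("# ", names(params), "=",
                      vapply(params, function(p) paste(format(p), collapse = ","),
                             character(1))), con)
  }
  df <- as.data.frame(lapply(df, function(col) {
    if (is.list(col)) vapply(col, function(x) paste(x, collapse = ","), character(1))
    else col
  }), check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# derive a child seed from a base seed, kept inside 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1103L + 7919L * k) %% 2147483647)
}
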