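#' Reverse complement of DNA/RNA strings
#'
#' Accepts plain character vectors over the IUPAC alphabet. RNA input (with
#' `U`) is reverse-complemented in the RNA alphabet; otherwise DNA is assumed.
#'
#' @param x character vector of sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (grepl("U", s, fixed = TRUE)) {
      as.character(Biostrings::reverseComplement(Biostrings::RNAString(s)))
    } else {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
  }, character(1), USE.NAMES = FALSE)
}

#' Convert between DNA and RNA alphabets
#'
#' `as_rna()` maps T to U, `as_dna()` maps U to T; both uppercase the input.
#'
#' @param x character vector of sequences.
#' @return character vector.
#' @export
as_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' @rdname as_rna
#' @export
as_dna <- function(x) chartr("Uu", "Tt", toupper(x))

#' Round half away from zero
#'
#' Decimal rounding with ties going up (2.5 -> 3), the convention used when
#' reporting prevalence percentages such as 7/9 = 77.8%. Base R's `round()`
#' rounds ties to even, which would disagree at some boundaries.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.check_alphabet <- function(x, extra = "", what = "sequence") {
  ok <- paste0("ACGTU", extra)
  bad <- grepl(sprintf("[^%s]", ok), toupper(x))
  if (any(bad)) {
    stop(sprintf("non-IUPAC character in %s (allowed: %s)", what, ok),
         call. = FALSE)
  }
  invisible(TRUE)
}

.iupac_check <- function(x, what = "pattern") {
  bad <- grepl("[^ACGTURYSWKMBDHVN]", toupper(x))
  if (any(bad)) stop(sprintf("non-IUPAC character in %s", what), call. = FALSE)
  invisible(TRUE)
}

#' Read and write FASTA files
#'
#' Thin wrappers around Biostrings that keep sequences as a named character
#' vector, the representation used throughout the package. `write_fasta()`
#' wraps lines at 70 columns.
#'
#' @param path file path.
#' @param seqs named character vector of sequences.
#' @return `read_fasta()` returns a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read and write tab-separated tables
#'
#' @param path file path.
#' @param df a data.frame.
#' @return `read_tsv_file()` returns a data.frame.
#' @export
read_tsv_file <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' @rdname read_tsv_file
#' @export
write_tsv_file <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# random DNA of given length from the i.i.d. uniform background model
.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
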