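#' @useDynLib cretrace, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

VALID_BASES <- c("A", "C", "G", "T")

#' Validate a DNA sequence
#'
#' Sequences are plain uppercase character strings over the alphabet
#' \{A, C, G, T\}. Sequences containing undetermined bases (N) or any other
#' character are rejected with an error: ortholog retrieval pipelines discard
#' such sequences, and every downstream operation (alignment, motif scoring)
#' assumes a fully determined sequence.
#'
#' @param x character string (or named character vector of length 1).
#' @param what label used in error messages.
#' @return the validated sequence, invisibly usable as input elsewhere.
#' @export
validate_sequence <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string", call. = FALSE)
  if (nchar(x) == 0L)
    stop(what, " is empty", call. = FALSE)
  bad <- setdiff(unique(strsplit(x, "")[[1]]), VALID_BASES)
  if (length(bad) > 0L) {
    if ("N" %in% bad)
      stop(what, " contains undetermined bases (N); such sequences are discarded upstream",
           call. = FALSE)
    stop(what, " contains invalid characters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Reverse complement
#' @param x DNA string.
#' @return reverse-complemented string.
#' @export
revcomp <- function(x) {
  validate_sequence(x)
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

#' Read sequences from a FASTA file
#'
#' Reads a (multi-)FASTA file into a named character vector. By default any
#' record whose sequence contains characters outside \{A, C, G, T\} (notably
#' undetermined bases, N) triggers an error; with `drop_invalid = TRUE` such
#' records are dropped with a message, reproducing the discard behaviour of
#' ortholog retrieval pipelines.
#'
#' @param path FASTA file.
#' @param drop_invalid drop offending records instead of erroring.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path, drop_invalid = FALSE) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  ok <- !grepl(paste0("[^", paste(VALID_BASES, collapse = ""), "]"), seqs)
  if (!all(ok)) {
    if (!drop_invalid)
      stop("FASTA records with invalid characters (e.g. N): ",
           paste(names(seqs)[!ok], collapse = ", "),
           "; use drop_invalid = TRUE to discard them", call. = FALSE)
    message("dropping ", sum(!ok), " record(s) with invalid characters")
    seqs <- seqs[ok]
  }
  seqs
}

#' Write sequences to a FASTA file
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read an aligned FASTA (MSA)
#'
#' Like [read_fasta()] but allows the gap character `-` and requires all rows
#' to have equal length.
#' @param path aligned FASTA file.
#' @return named character vector of gapped rows.
#' @export
read_msa <- function(path) {
  set <- Biostrings::readBStringSet(path)
  rows <- toupper(as.character(set))
  names(rows) <- sub("\\s.*$", "", names(set))
  if (length(unique(nchar(rows))) != 1L)
    stop("MSA rows have unequal lengths", call. = FALSE)
  bad <- grepl("[^ACGT-]", rows)
  if (any(bad))
    stop("MSA rows with invalid characters: ",
         paste(names(rows)[bad], collapse = ", "), call. = FALSE)
  rows
}

#' Length-ratio filter for retrieved ortholog intervals
#'
#' Orthologous intervals whose length falls outside 0.5-1.5x the query
#' interval length are discarded before any sequence-level analysis.
#'
#' @param lengths integer vector of retrieved interval lengths.
#' @param reference_length query interval length.
#' @param min,max allowed ratio bounds (inclusive).
#' @return logical vector: TRUE where the interval passes.
#' @export
length_ratio_filter <- function(lengths, reference_length, min = 0.5, max = 1.5) {
  stopifnot(reference_length > 0)
  ratio <- lengths / reference_length
  ratio >= min & ratio <= max
}
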