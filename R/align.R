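#' Alignment scoring parameters
#'
#' Bundles match/mismatch scores and gap penalties. A gap run of length L
#' costs `gap_open + (L - 1) * gap_extend`, so in linear mode
#' (`gap_open == gap_extend`) each gap base costs `gap_extend`.
#'
#' @param match,mismatch per-column scores; `match` must exceed `mismatch`.
#' @param gap_open cost of the first base of a gap run (negative).
#' @param gap_extend cost of each further gap base (negative).
#' @param mode `"linear"` (requires `gap_open == gap_extend`) or `"affine"`.
#' @return an object of class `scoring_params`.
#' @seealso [preset_params()] for the two standard parameterizations.
#' @export
scoring_params <- function(match = 1, mismatch = -1,
                           gap_open = -1, gap_extend = gap_open,
                           mode = c("linear", "affine")) {
  mode <- match.arg(mode)
  if (mode == "linear" && gap_open != gap_extend)
    stop("linear mode requires gap_open == gap_extend", call. = FALSE)
  if (match <= mismatch)
    stop("match score must exceed mismatch score", call. = FALSE)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend, mode = mode),
            class = "scoring_params")
}

#' Standard alignment parameter presets
#'
#' `"reconstitution"`: match 1, mismatch -1, linear gap -1 per base — used to
#' enumerate mutation events between an ancestral and an extant ortholog.
#' `"orientation"`: match 1, mismatch -1, affine gaps (open -2, extend -8) —
#' used to orient retrieved orthologs against the reference.
#'
#' @param name preset name.
#' @return a `scoring_params` object.
#' @export
preset_params <- function(name = c("reconstitution", "orientation")) {
  name <- match.arg(name)
  switch(name,
    reconstitution = scoring_params(1, -1, -1, -1, mode = "linear"),
    orientation    = scoring_params(1, -1, -2, -8, mode = "affine"))
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch/Gotoh global alignment with a deterministic traceback:
#' ties are broken preferring diagonal (match/mismatch) over deletion (gap in
#' `b`) over insertion (gap in `a`), so the same input always yields the same
#' alignment.
#'
#' @param a,b DNA strings; by convention `a` is the ancestor and `b` the
#'   extant target when the alignment feeds mutation enumeration.
#' @param params a [scoring_params()] object.
#' @param id_a,id_b optional sequence labels carried into downstream tables.
#' @return an object of class `alignment_pair` with elements `aligned_a`,
#'   `aligned_b` (gapped strings), `score`, and 0-based per-column coordinate
#'   maps `column_to_a`, `column_to_b` (NA at gap columns).
#' @export
align_global <- function(a, b, params = preset_params("reconstitution"),
                         id_a = "a", id_b = "b") {
  validate_sequence(a, "sequence a")
  validate_sequence(b, "sequence b")
  stopifnot(inherits(params, "scoring_params"))
  res <- .align_global_cpp(a, b, params$match, params$mismatch,
                           params$gap_open, params$gap_extend)
  ca <- strsplit(res$aligned_a, "")[[1]]
  cb <- strsplit(res$aligned_b, "")[[1]]
  structure(list(
    aligned_a = res$aligned_a, aligned_b = res$aligned_b,
    score = res$score,
    column_to_a = ifelse(ca == "-", NA_integer_, cumsum(ca != "-") - 1L),
    column_to_b = ifelse(cb == "-", NA_integer_, cumsum(cb != "-") - 1L),
    id_a = id_a, id_b = id_b, params = params), class = "alignment_pair")
}

#' @export
print.alignment_pair <- function(x, ...) {
  cat("Global alignment", x$id_a, "vs", x$id_b,
      sprintf("(score %g, %d columns)\n", x$score, nchar(x$aligned_a)))
  cat(substr(x$aligned_a, 1, 60), if (nchar(x$aligned_a) > 60) "..." else "", "\n")
  cat(substr(x$aligned_b, 1, 60), if (nchar(x$aligned_b) > 60) "..." else "", "\n")
  invisible(x)
}

#' Percent identity of an alignment
#'
#' @param aln an `alignment_pair`.
#' @param denominator `"columns"` (default): matched columns over all
#'   alignment columns, gaps included; `"aligned"`: matched columns over
#'   columns where both rows have a residue.
#' @return percent identity in `[0, 100]`.
#' @export
sequence_identity <- function(aln, denominator = c("columns", "aligned")) {
  denominator <- match.arg(denominator)
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  matched <- sum(ca == cb & ca != "-")
  den <- if (denominator == "columns") length(ca) else sum(ca != "-" & cb != "-")
  100 * matched / den
}

#' Orient a query sequence against a reference
#'
#' Aligns the query and its reverse complement globally to the reference and
#' keeps the orientation with the higher score; ties resolve to forward.
#'
#' @param query,reference DNA strings.
#' @param params scoring parameters (default: the affine orientation preset).
#' @return list with `sequence` (possibly reverse-complemented), `strand`
#'   (`"+"` or `"-"`), and the two scores.
#' @export
orient_sequence <- function(query, reference,
                            params = preset_params("orientation")) {
  fwd <- align_global(query, reference, params)
  rc <- revcomp(query)
  rev <- align_global(rc, reference, params)
  if (rev$score > fwd$score)
    list(sequence = rc, strand = "-", score_fwd = fwd$score, score_rev = rev$score)
  else
    list(sequence = query, strand = "+", score_fwd = fwd$score, score_rev = rev$score)
}
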