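aln_columns <- function(aln) {
  list(a = strsplit(aln$aligned_a, "")[[1]],
       b = strsplit(aln$aligned_b, "")[[1]])
}

#' Enumerate mutation events between aligned ancestor and target
#'
#' Walks the alignment columns of an ancestor (row a) / target (row b)
#' alignment and returns every difference as a mutation event: mismatch
#' columns become single-base substitutions, and maximal runs of adjacent
#' same-orientation gap columns are merged into one insertion (gap in the
#' ancestor row) or deletion (gap in the target row). Event ids are assigned
#' after sorting by alignment column, so they are deterministic.
#'
#' @param aln an [align_global()] result with row a = ancestor, row b = target.
#' @return an object of class `mutation_set`: a data.frame with columns `id`,
#'   `kind` (substitution/insertion/deletion), `column_start` (0-based
#'   alignment column), `n_columns`, `ref_pos` (0-based position on the
#'   target), `from`, `to`; the source alignment is attached as an attribute.
#' @export
enumerate_mutations <- function(aln) {
  cols <- aln_columns(aln)
  a <- cols$a; b <- cols$b
  n <- length(a)
  # classify each column: 0 match, 1 substitution, 2 insertion (gap in a),
  # 3 deletion (gap in b)
  cls <- integer(n)
  cls[a != b] <- 1L
  cls[a == "-"] <- 2L
  cls[b == "-"] <- 3L
  # target-coordinate offset before each column
  b_before <- c(0L, cumsum(b != "-"))[seq_len(n)]

  events <- list()
  i <- 1L
  while (i <= n) {
    if (cls[i] == 0L) { i <- i + 1L; next }
    if (cls[i] == 1L) {
      events[[length(events) + 1L]] <- data.frame(
        kind = "substitution", column_start = i - 1L, n_columns = 1L,
        ref_pos = b_before[i], from = a[i], to = b[i],
        stringsAsFactors = FALSE)
      i <- i + 1L
    } else {
      j <- i
      while (j < n && cls[j + 1L] == cls[i]) j <- j + 1L
      if (cls[i] == 2L) {
        events[[length(events) + 1L]] <- data.frame(
          kind = "insertion", column_start = i - 1L, n_columns = j - i + 1L,
          ref_pos = b_before[i], from = "",
          to = paste(b[i:j], collapse = ""), stringsAsFactors = FALSE)
      } else {
        events[[length(events) + 1L]] <- data.frame(
          kind = "deletion", column_start = i - 1L, n_columns = j - i + 1L,
          ref_pos = b_before[i], from = paste(a[i:j], collapse = ""),
          to = "", stringsAsFactors = FALSE)
      }
      i <- j + 1L
    }
  }
  ms <- if (length(events) == 0L)
    data.frame(kind = character(), column_start = integer(),
               n_columns = integer(), ref_pos = integer(),
               from = character(), to = character(), stringsAsFactors = FALSE)
  else do.call(rbind, events)
  ms <- ms[order(ms$column_start), , drop = FALSE]
  ms <- cbind(id = sprintf("m%03d", seq_len(nrow(ms))), ms,
              stringsAsFactors = FALSE)
  rownames(ms) <- NULL
  attr(ms, "ancestor_id") <- aln$id_a
  attr(ms, "target_id") <- aln$id_b
  attr(ms, "aln_key") <- paste(aln$aligned_a, aln$aligned_b, sep = "|")
  class(ms) <- c("mutation_set", "data.frame")
  ms
}

#' Apply a subset of mutation events to the ancestor
#'
#' Edits are applied in alignment-column space: each selected event replaces
#' its ancestor-row columns with the target-row columns, so the result is
#' independent of the order in which events are listed and coordinates never
#' shift. The empty subset returns the ancestor; the full set returns the
#' target exactly.
#'
#' @param aln the alignment the events were enumerated on.
#' @param subset a `mutation_set` or a subset of its rows (or event ids).
#' @return the edited sequence (character string).
#' @export
apply_mutations <- function(aln, subset) {
  full <- enumerate_mutations(aln)
  if (is.character(subset)) {
    missing <- setdiff(subset, full$id)
    if (length(missing) > 0L)
      stop("unknown event id(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    subset <- full[match(subset, full$id), , drop = FALSE]
  }
  if (nrow(subset) > 0L) {
    key_cols <- c("id", "kind", "column_start", "n_columns", "from", "to")
    mk <- function(d) do.call(paste, c(d[key_cols], sep = "\r"))
    if (!all(mk(subset) %in% mk(full)))
      stop("event(s) not enumerated on this alignment", call. = FALSE)
  }
  cols <- aln_columns(aln)
  use_b <- rep(FALSE, length(cols$a))
  for (r in seq_len(nrow(subset))) {
    idx <- subset$column_start[r] + seq_len(subset$n_columns[r])
    use_b[idx] <- TRUE
  }
  out <- ifelse(use_b, cols$b, cols$a)
  paste(out[out != "-"], collapse = "")
}

#' Write / read mutation sets as TSV
#' @param ms a `mutation_set`.
#' @param path TSV file.
#' @export
write_mutations <- function(ms, path) {
  utils::write.table(as.data.frame(ms), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_mutations
#' @export
read_mutations <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(from = "character", to = "character"))
}

#' Map MSA columns to reference positions
#'
#' Builds the bidirectional partial map between 0-based MSA columns and
#' 0-based positions on a chosen ungapped reference row. Gap columns in the
#' reference row map to no reference position.
#'
#' @param msa named character vector of equal-length gapped rows.
#' @param reference_id name of the reference row.
#' @return list with `col_to_pos` (length = number of columns; NA at
#'   reference-gap columns) and `pos_to_col` (length = reference length),
#'   both holding 0-based values.
#' @export
msa_column_map <- function(msa, reference_id) {
  if (!reference_id %in% names(msa))
    stop("reference row '", reference_id, "' not found in MSA", call. = FALSE)
  ref <- strsplit(msa[[reference_id]], "")[[1]]
  col_to_pos <- ifelse(ref == "-", NA_integer_, cumsum(ref != "-") - 1L)
  pos_to_col <- which(ref != "-") - 1L
  list(col_to_pos = as.integer(col_to_pos), pos_to_col = as.integer(pos_to_col))
}

#' Map a reference interval into another MSA row's local coordinates
#'
#' Takes a 0-based half-open interval on the reference row and returns the
#' corresponding 0-based half-open interval of residues in `row_id`'s own
#' ungapped coordinates, or NULL when the interval is fully deleted in that
#' row.
#'
#' @param msa named gapped rows.
#' @param reference_id,row_id row names.
#' @param start,end 0-based half-open interval on the reference.
#' @return list(start, end) in `row_id` coordinates, or NULL.
#' @export
map_interval <- function(msa, reference_id, row_id, start, end) {
  m <- msa_column_map(msa, reference_id)
  cols <- m$pos_to_col[(start + 1L):end]           # 0-based columns
  row <- strsplit(msa[[row_id]], "")[[1]]
  row_pos <- ifelse(row == "-", NA_integer_, cumsum(row != "-") - 1L)
  hit <- row_pos[cols + 1L]
  hit <- hit[!is.na(hit)]
  if (length(hit) == 0L) return(NULL)
  list(start = min(hit), end = max(hit) + 1L)
}
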