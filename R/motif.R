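#' Construct a PSAM motif model
#'
#' A position-specific affinity matrix (PSAM) holds per-position, per-base
#' relative binding affinities whose product scores a k-mer. On construction
#' each row is divided by its maximum, so the consensus k-mer scores 1 before
#' normalization against random k-mers.
#'
#' @param tf_name transcription factor label.
#' @param weights k x 4 nonnegative matrix, columns A, C, G, T (any order of
#'   named columns accepted).
#' @param paralog_group optional label shared by redundant paralogs (e.g.
#'   Gata4 and Gata6 under "Gata4/6").
#' @param normalize divide each row by its max (default TRUE).
#' @return an object of class `psam`.
#' @export
psam <- function(tf_name, weights, paralog_group = NULL, normalize = TRUE) {
  weights <- as.matrix(weights)
  if (ncol(weights) != 4L)
    stop("PSAM weights must have 4 columns (A, C, G, T)", call. = FALSE)
  if (!is.null(colnames(weights))) {
    if (!setequal(colnames(weights), VALID_BASES))
      stop("PSAM columns must be named A, C, G, T", call. = FALSE)
    weights <- weights[, VALID_BASES, drop = FALSE]
  } else colnames(weights) <- VALID_BASES
  if (any(weights < 0) || any(is.na(weights)))
    stop("PSAM weights must be nonnegative and finite", call. = FALSE)
  rmax <- apply(weights, 1, max)
  if (any(rmax == 0))
    stop("every PSAM position needs at least one positive weight", call. = FALSE)
  if (normalize) weights <- weights / rmax
  rownames(weights) <- NULL
  structure(list(tf_name = tf_name, width = nrow(weights), weights = weights,
                 paralog_group = paralog_group), class = "psam")
}

#' @export
print.psam <- function(x, ...) {
  cat("PSAM", x$tf_name, sprintf("(width %d%s)\n", x$width,
      if (!is.null(x$paralog_group)) paste0(", group ", x$paralog_group) else ""))
  print(round(x$weights, 3))
  invisible(x)
}

#' Read / write PSAM models as TSV
#'
#' Format: header `tf  position  A  C  G  T`, one row per motif position
#' (0-based positions), several motifs per file allowed.
#'
#' @param path TSV file.
#' @param paralog_groups optional named character: tf_name -> group label.
#' @return named list of `psam` objects.
#' @export
read_psams <- function(path, paralog_groups = NULL) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  stopifnot(all(c("tf", "position", "A", "C", "G", "T") %in% names(d)))
  out <- lapply(split(d, d$tf), function(g) {
    g <- g[order(g$position), , drop = FALSE]
    psam(g$tf[1], as.matrix(g[, VALID_BASES]),
         paralog_group = if (g$tf[1] %in% names(paralog_groups))
           paralog_groups[[g$tf[1]]] else NULL)
  })
  out[order(names(out))]
}

#' @rdname read_psams
#' @param motifs named list of `psam` objects.
#' @export
write_psams <- function(motifs, path) {
  rows <- lapply(motifs, function(m) {
    data.frame(tf = m$tf_name, position = seq_len(m$width) - 1L,
               m$weights, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Raw affinity of a single k-mer
#'
#' Plain product of per-position weights; the reference slow path against
#' which the vectorized scanner is checked.
#'
#' @param motif a `psam`.
#' @param kmer string of length equal to the motif width.
#' @return raw affinity (consensus scores 1).
#' @export
score_kmer <- function(motif, kmer) {
  if (nchar(kmer) != motif$width)
    stop("k-mer length ", nchar(kmer), " does not match motif width ",
         motif$width, call. = FALSE)
  bases <- strsplit(kmer, "")[[1]]
  idx <- match(bases, VALID_BASES)
  if (anyNA(idx)) stop("invalid base in k-mer", call. = FALSE)
  prod(motif$weights[cbind(seq_len(motif$width), idx)])
}

#' Sliding-window affinity scan
#'
#' Scores every window of the sequence with the PSAM in both orientations:
#' `fwd[i]` is the affinity of the window starting at 0-based position i - 1,
#' `rev[i]` the affinity of that window's reverse complement.
#'
#' @param seq DNA string.
#' @param motif a `psam`.
#' @param seq_id label carried into hit tables.
#' @return object of class `affinity_profile` with `fwd` and `rev` vectors of
#'   length `nchar(seq) - width + 1` (empty, with a warning, if the sequence
#'   is shorter than the motif).
#' @export
scan_sequence <- function(seq, motif, seq_id = "seq") {
  validate_sequence(seq)
  if (nchar(seq) < motif$width) {
    warning("sequence shorter than motif width; empty profile")
    prof <- list(fwd = numeric(0), rev = numeric(0))
  } else {
    prof <- .psam_scan_cpp(seq, motif$weights)
  }
  structure(list(sequence_id = seq_id, tf_name = motif$tf_name,
                 width = motif$width, fwd = prof$fwd, rev = prof$rev),
            class = "affinity_profile")
}

#' Random-k-mer normalization reference
#'
#' Computes the normalizer that places raw affinities on a common scale: the
#' q-quantile (default 0.9999) of raw affinities over n (default 1e6)
#' uniformly random k-mers. `method = "max"` uses the maximum of the sample
#' instead, and `method = "exact"` enumerates all 4^k k-mers and takes the
#' exact population quantile (practical for k <= ~10).
#'
#' @param motif a `psam`.
#' @param n number of random k-mers.
#' @param quantile quantile level in (0, 1).
#' @param seed RNG seed (sampling is reproducible under a fixed seed).
#' @param method "quantile" (default), "max", or "exact".
#' @return object of class `normalization_ref` with the normalizer and the
#'   parameters that produced it.
#' @export
compute_normalizer <- function(motif, n = 1e6, quantile = 0.9999, seed = 1,
                               method = c("quantile", "max", "exact")) {
  method <- match.arg(method)
  stopifnot(n >= 1, quantile > 0, quantile < 1)
  k <- motif$width
  if (method == "exact") {
    grid <- as.matrix(expand.grid(rep(list(0:3), k)))[, k:1, drop = FALSE]
    aff <- .psam_score_kmers_cpp(grid, motif$weights)
    norm <- stats::quantile(aff, quantile, names = FALSE, type = 7)
  } else {
    aff <- local_seed(seed, {
      km <- matrix(sample.int(4L, n * k, replace = TRUE) - 1L, nrow = n)
      .psam_score_kmers_cpp(km, motif$weights)
    })
    norm <- if (method == "max") max(aff)
            else stats::quantile(aff, quantile, names = FALSE, type = 7)
  }
  if (norm <= 0)
    stop("degenerate motif: normalizer is not positive", call. = FALSE)
  structure(list(tf_name = motif$tf_name, normalizer = norm, n_samples = n,
                 quantile = quantile, seed = seed, method = method),
            class = "normalization_ref")
}

#' Call TFBS hits from an affinity profile
#'
#' At each start position the strand is forward iff the forward affinity is
#' greater than or equal to the reverse affinity; the candidate's normalized
#' affinity is the larger of the two raw affinities divided by the
#' normalizer, and it is retained only if strictly greater than the
#' threshold.
#'
#' @param profile an `affinity_profile`.
#' @param normref matching `normalization_ref`.
#' @param threshold call threshold on the normalized affinity (default 0.05,
#'   strict inequality).
#' @return data.frame with columns `seq_id`, `tf`, `start` (0-based),
#'   `width`, `strand`, `norm_affinity`.
#' @export
call_hits <- function(profile, normref, threshold = 0.05) {
  if (profile$tf_name != normref$tf_name)
    stop("profile and normalization reference are for different TFs",
         call. = FALSE)
  if (normref$normalizer <= 0) stop("normalizer must be positive", call. = FALSE)
  if (length(profile$fwd) == 0L)
    return(data.frame(seq_id = character(), tf = character(),
                      start = integer(), width = integer(),
                      strand = character(), norm_affinity = numeric(),
                      stringsAsFactors = FALSE))
  norm <- pmax(profile$fwd, profile$rev) / normref$normalizer
  strand <- ifelse(profile$fwd >= profile$rev, "+", "-")
  keep <- which(norm > threshold)
  data.frame(seq_id = rep(profile$sequence_id, length(keep)),
             tf = rep(profile$tf_name, length(keep)),
             start = keep - 1L, width = rep(profile$width, length(keep)),
             strand = strand[keep], norm_affinity = norm[keep],
             stringsAsFactors = FALSE)
}

#' Scan a sequence with several motifs and call hits
#'
#' Convenience wrapper: scan + call per motif, optional paralog merge.
#'
#' @param seq DNA string.
#' @param motifs named list of `psam` objects.
#' @param normrefs named list of `normalization_ref`, same names.
#' @param threshold call threshold.
#' @param merge merge paralog groups (default TRUE).
#' @param seq_id label.
#' @return hit data.frame as in [call_hits()].
#' @export
call_all_hits <- function(seq, motifs, normrefs, threshold = 0.05,
                          merge = TRUE, seq_id = "seq") {
  hits <- lapply(names(motifs), function(tf) {
    call_hits(scan_sequence(seq, motifs[[tf]], seq_id), normrefs[[tf]],
              threshold)
  })
  hits <- do.call(rbind, hits)
  if (merge) {
    groups <- vapply(motifs, function(m)
      if (is.null(m$paralog_group)) m$tf_name else m$paralog_group, "")
    hits <- merge_paralogs(hits, groups)
  }
  hits
}

#' Merge hits of redundant paralogs
#'
#' Relabels each hit with its paralog group and keeps, at every (sequence,
#' start) position, the single hit with the maximal normalized affinity.
#'
#' @param hits hit data.frame from [call_hits()] (possibly several TFs
#'   row-bound).
#' @param groups named character: tf_name -> group label (TFs absent from the
#'   map keep their own name).
#' @return merged hit data.frame; the contributing TF is kept in `tf_source`.
#' @export
merge_paralogs <- function(hits, groups = NULL) {
  if (nrow(hits) == 0L) {
    hits$tf_source <- character(0)
    return(hits)
  }
  hits$tf_source <- hits$tf
  if (!is.null(groups)) {
    mapped <- groups[hits$tf]
    hits$tf <- ifelse(is.na(mapped), hits$tf, unname(mapped))
  }
  key <- paste(hits$seq_id, hits$tf, hits$start, sep = "\r")
  hits <- hits[order(key, -hits$norm_affinity), , drop = FALSE]
  hits <- hits[!duplicated(paste(hits$seq_id, hits$tf, hits$start, sep = "\r")), ,
               drop = FALSE]
  hits <- hits[order(hits$seq_id, hits$start, hits$tf), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Assign hits to reference functional sites by interval overlap
#'
#' Both hits and reference sites must be expressed in a common coordinate
#' system (typically MSA columns). A hit is assigned to a reference site iff
#' their intervals share at least one position; hits overlapping no site are
#' labeled "novel". When a hit overlaps several sites the one with the
#' largest overlap (then the first in table order) wins.
#'
#' @param hits data.frame with `start` and `width` (0-based half-open
#'   `[start, start + width)`).
#' @param reference_sites data.frame with `site_id`, `start`, `end` (0-based
#'   half-open).
#' @return `hits` with an added `site_id` column.
#' @export
overlap_with_reference <- function(hits, reference_sites) {
  hits$site_id <- rep("novel", nrow(hits))
  if (nrow(hits) == 0L || nrow(reference_sites) == 0L) return(hits)
  q <- IRanges::IRanges(start = hits$start + 1L, width = hits$width)
  s <- IRanges::IRanges(start = reference_sites$start + 1L,
                        end = reference_sites$end)
  ov <- IRanges::findOverlaps(q, s)
  if (length(ov) > 0L) {
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    w <- IRanges::width(IRanges::pintersect(q[qh], s[sh]))
    ord <- order(qh, -w, sh)
    first <- !duplicated(qh[ord])
    hits$site_id[qh[ord][first]] <- reference_sites$site_id[sh[ord][first]]
  }
  hits
}

max_affinity_in_window <- function(seq, motif, normref, start, end) {
  # max normalized affinity over windows overlapping [start, end) (0-based)
  prof <- suppressWarnings(scan_sequence(seq, motif))
  if (length(prof$fwd) == 0L) return(0)
  k <- motif$width
  lo <- max(0L, start - k + 1L)
  hi <- min(length(prof$fwd) - 1L, end - 1L)
  if (lo > hi) return(0)
  idx <- (lo:hi) + 1L
  max(pmax(prof$fwd[idx], prof$rev[idx])) / normref$normalizer
}

#' Binding-affinity fold change of a site between two orthologs
#'
#' Maps a functional site interval (given on the reference row of a shared
#' MSA) into both sequences and reports the ratio of the maximal normalized
#' affinities over the mapped windows (b over a): > 1 is a fold gain, < 1 a
#' fold loss. A site whose columns are entirely deleted in one sequence is
#' reported with status "lost" instead of a ratio.
#'
#' @param msa shared gapped rows including both sequences and the reference.
#' @param id_a,id_b row names of the two orthologs.
#' @param reference_id reference row name.
#' @param site list/row with `start`, `end` on the reference (0-based
#'   half-open).
#' @param motif,normref scoring model for the site's TF.
#' @return list with `fold`, `status` ("ok" or "lost"), `aff_a`, `aff_b`.
#' @export
affinity_fold_change <- function(msa, id_a, id_b, reference_id, site,
                                 motif, normref) {
  seq_a <- gsub("-", "", msa[[id_a]], fixed = TRUE)
  seq_b <- gsub("-", "", msa[[id_b]], fixed = TRUE)
  wa <- map_interval(msa, reference_id, id_a, site$start, site$end)
  wb <- map_interval(msa, reference_id, id_b, site$start, site$end)
  if (is.null(wa) || is.null(wb))
    return(list(fold = NA_real_, status = "lost",
                aff_a = NA_real_, aff_b = NA_real_))
  aff_a <- max_affinity_in_window(seq_a, motif, normref, wa$start, wa$end)
  aff_b <- max_affinity_in_window(seq_b, motif, normref, wb$start, wb$end)
  fold <- if (aff_a == 0 && aff_b == 0) 1 else if (aff_a == 0) Inf
          else aff_b / aff_a
  list(fold = fold, status = "ok", aff_a = aff_a, aff_b = aff_b)
}

#' Write TFBS hits as BED-like TSV
#' @param hits hit data.frame.
#' @param path TSV file.
#' @export
write_hits <- function(hits, path) {
  bed <- data.frame(seq_id = hits$seq_id, start = hits$start,
                    end = hits$start + hits$width, tf = hits$tf,
                    norm_affinity = hits$norm_affinity, strand = hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
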