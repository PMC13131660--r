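#' Validate / read / write barcode UMI count tables
#'
#' Long format: one row per (barcode, replicate, molecule) with an integral
#' nonnegative UMI count; molecule is "DNA" or "RNA".
#'
#' @param table data.frame with columns `barcode`, `replicate`, `molecule`,
#'   `count`.
#' @return the validated table.
#' @export
count_table <- function(table) {
  need <- c("barcode", "replicate", "molecule", "count")
  if (!all(need %in% names(table)))
    stop("count table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(table$count < 0) || any(table$count != round(table$count)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (!all(table$molecule %in% c("DNA", "RNA")))
    stop("molecule must be DNA or RNA", call. = FALSE)
  key <- paste(table$barcode, table$replicate, table$molecule)
  if (anyDuplicated(key))
    stop("duplicated (barcode, replicate, molecule) rows", call. = FALSE)
  table
}

#' @rdname count_table
#' @param path TSV file.
#' @export
read_count_table <- function(path) {
  count_table(utils::read.table(path, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE))
}

#' @rdname count_table
#' @export
write_count_table <- function(table, path) {
  utils::write.table(count_table(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Filter a barcode-to-element map by association read support
#'
#' @param map data.frame with `barcode`, `element`, `reads`.
#' @param min_reads minimum association reads (default 2); barcodes below are
#'   removed.
#' @return filtered map; the number removed is reported with a message (a
#'   warning if nothing survives).
#' @export
filter_barcodes <- function(map, min_reads = 2) {
  stopifnot(min_reads >= 0)
  if (anyDuplicated(map$barcode))
    stop("each barcode must map to at most one element", call. = FALSE)
  keep <- map$reads >= min_reads
  if (sum(!keep) > 0)
    message("removed ", sum(!keep), " low-abundance barcode(s)")
  out <- map[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("no barcodes survive the read filter")
  rownames(out) <- NULL
  out
}

#' Per-barcode normalized RNA/DNA expression for one replicate
#'
#' Each barcode's UMI count is normalized by the summed counts of its sample
#' type (DNA or RNA totals within the replicate); expression is the
#' normalized RNA count divided by the normalized DNA count. Barcodes with
#' zero DNA (and zero pseudocount) get NA.
#'
#' @param table a [count_table()].
#' @param replicate replicate label.
#' @param pseudocount added to every count before normalization (default 0).
#' @return data.frame `barcode`, `dna`, `rna`, `dna_norm`, `rna_norm`,
#'   `ratio`.
#' @export
barcode_expression <- function(table, replicate, pseudocount = 0) {
  t <- table[table$replicate == replicate, , drop = FALSE]
  if (nrow(t) == 0L) stop("no rows for replicate ", replicate, call. = FALSE)
  dna <- t[t$molecule == "DNA", ]
  rna <- t[t$molecule == "RNA", ]
  bcs <- sort(unique(t$barcode))
  d <- stats::setNames(rep(0, length(bcs)), bcs)
  r <- d
  d[dna$barcode] <- dna$count
  r[rna$barcode] <- rna$count
  d <- d + pseudocount; r <- r + pseudocount
  if (sum(d) == 0 || sum(r) == 0)
    stop("zero total counts in replicate ", replicate, call. = FALSE)
  dn <- d / sum(d); rn <- r / sum(r)
  data.frame(barcode = bcs, dna = unname(d), rna = unname(r),
             dna_norm = unname(dn), rna_norm = unname(rn),
             ratio = ifelse(d > 0, rn / dn, NA_real_),
             stringsAsFactors = FALSE)
}

#' Winsorize a numeric vector at symmetric quantiles
#'
#' Values below the `f` quantile or above the `1 - f` quantile are replaced
#' by those quantiles (type-7 linear-interpolation quantiles, so results are
#' bit-reproducible).
#'
#' @param x numeric vector.
#' @param f winsorization fraction in `[0, 0.5)`.
#' @return winsorized vector.
#' @export
winsorize <- function(x, f = 0.01) {
  stopifnot(f >= 0, f < 0.5)
  if (f == 0 || length(x) < 2L) return(x)
  q <- stats::quantile(x, c(f, 1 - f), names = FALSE, type = 7, na.rm = TRUE)
  pmin(pmax(x, q[1]), q[2])
}

#' Per-element winsorized RNA/DNA activity for one replicate
#'
#' Default estimator (`mode = "counts"`): within each element, the barcodes'
#' normalized RNA and normalized DNA values are winsorized at
#' `[winsor_frac, 1 - winsor_frac]`, summed, and the ratio of sums reported
#' (the winsorized summed RNA over DNA estimator). `mode = "ratios"`
#' winsorizes per-barcode RNA/DNA ratios and averages them instead. With
#' `winsor_frac = 0` the default mode reduces exactly to the plain
#' summed-ratio estimator.
#'
#' @param table a [count_table()].
#' @param map barcode-to-element map (post [filter_barcodes()]).
#' @param replicate replicate label.
#' @param winsor_frac winsorization fraction (default 0.01).
#' @param mode `"counts"` (default) or `"ratios"`.
#' @param pseudocount passed to [barcode_expression()].
#' @return data.frame `element`, `activity`, `n_barcodes` (activity NA when
#'   an element has zero summed DNA).
#' @export
element_activity <- function(table, map, replicate, winsor_frac = 0.01,
                             mode = c("counts", "ratios"), pseudocount = 0) {
  mode <- match.arg(mode)
  be <- barcode_expression(table, replicate, pseudocount)
  be$element <- map$element[match(be$barcode, map$barcode)]
  be <- be[!is.na(be$element), , drop = FALSE]
  rows <- lapply(split(be, be$element), function(g) {
    if (mode == "counts") {
      rs <- sum(winsorize(g$rna_norm, winsor_frac))
      ds <- sum(winsorize(g$dna_norm, winsor_frac))
      act <- if (ds > 0) rs / ds else NA_real_
    } else {
      ratios <- g$ratio[!is.na(g$ratio)]
      act <- if (length(ratios) > 0)
        mean(winsorize(ratios, winsor_frac)) else NA_real_
    }
    data.frame(activity = act, n_barcodes = nrow(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(element = names(rows), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Mean and standard error across replicates
#'
#' @param x numeric vector of per-replicate activities.
#' @return list with `mu` (mean), `sigma` (standard error of the mean; NA
#'   with a single replicate), `n`.
#' @export
replicate_stats <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  list(mu = mean(x),
       sigma = if (n >= 2) stats::sd(x) / sqrt(n) else NA_real_,
       n = n)
}

#' Quantify element activities across replicates
#'
#' Runs [element_activity()] per replicate and summarizes with
#' [replicate_stats()].
#'
#' @inheritParams element_activity
#' @param replicates replicate labels (default: all in the table).
#' @return list with `summary` (element, mu, sigma, n_replicates,
#'   n_barcodes) and `per_replicate` (element, replicate, activity).
#' @export
quantify_mpra <- function(table, map, replicates = NULL, winsor_frac = 0.01,
                          mode = c("counts", "ratios"), pseudocount = 0) {
  mode <- match.arg(mode)
  replicates <- replicates %||% sort(unique(table$replicate))
  per <- lapply(replicates, function(r) {
    ea <- element_activity(table, map, r, winsor_frac, mode, pseudocount)
    ea$replicate <- r
    ea
  })
  per <- do.call(rbind, per)
  rows <- lapply(split(per, per$element), function(g) {
    st <- replicate_stats(g$activity)
    data.frame(mu = st$mu, sigma = st$sigma, n_replicates = st$n,
               n_barcodes = max(g$n_barcodes), stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  summary <- cbind(element = names(rows), summary, stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(summary = summary,
       per_replicate = per[, c("element", "replicate", "activity",
                               "n_barcodes")])
}

#' Fold-change of element activities over negative controls
#'
#' @param summary element summary from [quantify_mpra()].
#' @param negatives element ids of the negative controls.
#' @return `summary` with added `fold_vs_neg` and `log2_fold_vs_neg`.
#' @export
fold_vs_controls <- function(summary, negatives) {
  neg <- summary$mu[summary$element %in% negatives]
  if (length(neg) == 0L) stop("no negative controls found", call. = FALSE)
  base <- mean(neg, na.rm = TRUE)
  if (is.na(base) || base == 0)
    stop("negative-control mean is zero or undefined", call. = FALSE)
  summary$fold_vs_neg <- summary$mu / base
  summary$log2_fold_vs_neg <- log2(summary$fold_vs_neg)
  summary
}

#' Bootstrap confidence interval over barcodes (convenience)
#'
#' Resamples an element's barcodes with replacement and recomputes the
#' winsorized activity. This is a descriptive interval only; it is not a
#' substitute for a calibrated differential-activity test.
#'
#' @inheritParams element_activity
#' @param element element id.
#' @param n_boot bootstrap draws.
#' @param level confidence level.
#' @param seed RNG seed.
#' @return list with `estimate`, `lower`, `upper`.
#' @export
bootstrap_activity_ci <- function(table, map, replicate, element,
                                  winsor_frac = 0.01, n_boot = 200,
                                  level = 0.95, seed = 1) {
  be <- barcode_expression(table, replicate)
  be$element <- map$element[match(be$barcode, map$barcode)]
  g <- be[!is.na(be$element) & be$element == element, , drop = FALSE]
  if (nrow(g) == 0L) stop("element has no mapped barcodes", call. = FALSE)
  est <- sum(winsorize(g$rna_norm, winsor_frac)) /
         sum(winsorize(g$dna_norm, winsor_frac))
  boots <- local_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(nrow(g), replace = TRUE)
      ds <- sum(winsorize(g$dna_norm[idx], winsor_frac))
      if (ds == 0) return(NA_real_)
      sum(winsorize(g$rna_norm[idx], winsor_frac)) / ds
    }, numeric(1))
  })
  qs <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, names = FALSE)
  list(estimate = est, lower = qs[1], upper = qs[2])
}
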