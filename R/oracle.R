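#' Construct a sequence-scoring oracle
#'
#' A scoring oracle is the pluggable contract for predicted accessibility:
#' a pure function mapping DNA sequences to nonnegative scalars, plus
#' metadata. A trained accessibility model can be attached through
#' [oracle_external()]; the built-in motif-gated surrogate
#' ([surrogate_oracle()]) is used for testing and simulation.
#'
#' @param score_fn function(character vector of sequences) -> numeric vector.
#' @param name oracle name.
#' @param config optional configuration (hashed into metadata).
#' @return object of class `scoring_oracle`.
#' @export
scoring_oracle <- function(score_fn, name = "oracle", config = NULL) {
  stopifnot(is.function(score_fn))
  structure(list(score_fn = score_fn, name = name,
                 config_hash = config_hash(config %||% name)),
            class = "scoring_oracle")
}

#' Score sequences with an oracle
#' @param oracle a `scoring_oracle`.
#' @param seqs character vector of DNA sequences.
#' @return numeric vector of scores.
#' @export
oracle_score <- function(oracle, seqs) {
  stopifnot(inherits(oracle, "scoring_oracle"))
  out <- oracle$score_fn(seqs)
  if (length(out) != length(seqs))
    stop("oracle returned ", length(out), " scores for ", length(seqs),
         " sequences", call. = FALSE)
  as.numeric(out)
}

#' Motif-gated surrogate oracle configuration
#'
#' The surrogate encodes the empirical logic of a developmental enhancer: a
#' required heterotypic module that must be complete for any activity above
#' baseline (AND gate over its member TFBSs), plus saturating booster
#' contributions from additional binding sites. The score of a sequence is
#' `b0` if any required module is incomplete, and otherwise
#' `min(c_max, b0 + sum(booster_weight[tf] * norm_affinity))` over all called
#' hits.
#'
#' Defaults mirror a reporter-assay activity scale where the minimal-promoter
#' background sits near 0.14 and an active enhancer reaches roughly 7-fold
#' above it.
#'
#' @param motifs named list of [psam()] models.
#' @param booster_weights named numeric, per TF; TFs without a weight
#'   contribute 0.
#' @param required_modules list of named numeric vectors; each vector is one
#'   heterotypic module, names = TF labels (post paralog merge), values =
#'   minimal normalized affinity that must be met by at least one hit. All
#'   modules must be satisfied.
#' @param b0 baseline score (>= 0).
#' @param c_max ceiling (> b0).
#' @param threshold hit-call threshold.
#' @param seed seed for the normalization references.
#' @param norm_n random k-mers per normalization reference.
#' @return object of class `surrogate_config` (normalization references are
#'   computed once here).
#' @export
surrogate_config <- function(motifs, booster_weights = NULL,
                             required_modules = list(),
                             b0 = 0.14, c_max = 1.4, threshold = 0.05,
                             seed = 1, norm_n = 1e5) {
  stopifnot(b0 >= 0, c_max > b0)
  if (is.null(booster_weights))
    booster_weights <- stats::setNames(rep(0.3, length(motifs)), names(motifs))
  normrefs <- lapply(motifs, compute_normalizer, n = norm_n, seed = seed)
  structure(list(motifs = motifs, normrefs = normrefs,
                 booster_weights = booster_weights,
                 required_modules = required_modules,
                 b0 = b0, c_max = c_max, threshold = threshold, seed = seed),
            class = "surrogate_config")
}

# Per-(group, start) merged normalized affinities, without data.frame
# overhead; thresholding before or after the paralog max is equivalent
# because the max passes iff any member passes.
surrogate_group_profiles <- function(cfg, seq) {
  groups <- vapply(cfg$motifs, function(m)
    m$paralog_group %||% m$tf_name, "")
  out <- list()
  for (tf in names(cfg$motifs)) {
    m <- cfg$motifs[[tf]]
    if (nchar(seq) < m$width) next
    p <- .psam_scan_cpp(seq, m$weights)
    norm <- pmax(p$fwd, p$rev) / cfg$normrefs[[tf]]$normalizer
    g <- groups[[tf]]
    prev <- out[[g]]
    if (is.null(prev)) out[[g]] <- norm
    else {
      n <- max(length(prev), length(norm))
      a <- c(prev, rep(0, n - length(prev)))
      b <- c(norm, rep(0, n - length(norm)))
      out[[g]] <- pmax(a, b)
    }
  }
  out
}

surrogate_score_one <- function(cfg, seq) {
  prof <- surrogate_group_profiles(cfg, seq)
  for (module in cfg$required_modules) {
    for (tf in names(module)) {
      p <- prof[[tf]]
      if (is.null(p) || max(p) < module[[tf]] || max(p) <= cfg$threshold)
        return(cfg$b0)
    }
  }
  total <- 0
  for (g in names(prof)) {
    w <- unname(cfg$booster_weights[g])
    if (is.na(w) || w == 0) next
    called <- prof[[g]][prof[[g]] > cfg$threshold]
    total <- total + w * sum(called)
  }
  min(cfg$c_max, cfg$b0 + total)
}

#' Build the surrogate scoring oracle
#' @param cfg a [surrogate_config()].
#' @return a `scoring_oracle`.
#' @export
surrogate_oracle <- function(cfg) {
  stopifnot(inherits(cfg, "surrogate_config"))
  scoring_oracle(function(seqs)
    vapply(seqs, function(s) surrogate_score_one(cfg, s), numeric(1),
           USE.NAMES = FALSE),
    name = "surrogate", config = cfg[c("b0", "c_max", "threshold", "seed",
                                       "booster_weights")])
}

#' External oracle via a file-based subprocess contract
#'
#' Attaches any external accessibility predictor that can be driven as
#' `command [args] input.fasta output.tsv`, where the output TSV has columns
#' `id` and `score`. This is how a trained deployment plugs in without being
#' a build dependency.
#'
#' @param command executable name/path.
#' @param args extra arguments placed before the input/output paths.
#' @param name oracle name.
#' @return a `scoring_oracle`.
#' @export
oracle_external <- function(command, args = character(), name = command) {
  scoring_oracle(function(seqs) {
    fin <- tempfile(fileext = ".fasta"); fout <- tempfile(fileext = ".tsv")
    on.exit(unlink(c(fin, fout)))
    ids <- sprintf("s%06d", seq_along(seqs))
    write_fasta(stats::setNames(seqs, ids), fin)
    status <- system2(command, c(args, fin, fout))
    if (status != 0)
      stop("external oracle '", command, "' exited with status ", status,
           call. = FALSE)
    d <- utils::read.table(fout, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
    d$score[match(ids, d$id)]
  }, name = name, config = list(command = command, args = args))
}

#' Random background sequences
#' @param n number of sequences.
#' @param length length of each sequence (bp).
#' @param seed RNG seed.
#' @return character vector.
#' @export
random_backgrounds <- function(n, length, seed = 1) {
  local_seed(seed, {
    vapply(seq_len(n), function(i)
      paste(sample(VALID_BASES, length, replace = TRUE), collapse = ""),
      character(1))
  })
}

embed_centered <- function(candidate, background) {
  L <- nchar(background); l <- nchar(candidate)
  if (l > L)
    stop("candidate (", l, " bp) does not fit in background (", L, " bp)",
         call. = FALSE)
  off <- (L - l) %/% 2
  paste0(substr(background, 1, off), candidate,
         substr(background, off + l + 1, L))
}

#' Marginal footprint of a candidate sequence
#'
#' Embeds the candidate at the center of each background sequence (replacing
#' the central `nchar(candidate)` bases so the oracle always sees the same
#' length), scores all embedded sequences, and normalizes by the null score
#' of the backgrounds alone. The default is the ratio of means
#' (mean embedded score / mean background score); `method = "mean_of_ratios"`
#' averages per-background ratios instead.
#'
#' @param oracle a `scoring_oracle`.
#' @param candidate DNA string.
#' @param backgrounds character vector of background sequences.
#' @param method "ratio_of_means" (default) or "mean_of_ratios".
#' @return list with `mean_embedded`, `null`, `ratio`.
#' @export
marginal_footprint <- function(oracle, candidate, backgrounds,
                               method = c("ratio_of_means", "mean_of_ratios")) {
  method <- match.arg(method)
  if (length(backgrounds) == 0L)
    stop("at least one background sequence is required", call. = FALSE)
  embedded <- vapply(backgrounds, embed_centered, character(1),
                     candidate = candidate, USE.NAMES = FALSE)
  se <- oracle_score(oracle, embedded)
  sn <- oracle_score(oracle, backgrounds)
  if (method == "ratio_of_means") {
    null <- mean(sn)
    if (null == 0) stop("null footprint score is zero", call. = FALSE)
    list(mean_embedded = mean(se), null = null, ratio = mean(se) / null)
  } else {
    if (any(sn == 0)) stop("null footprint score is zero", call. = FALSE)
    list(mean_embedded = mean(se), null = mean(sn), ratio = mean(se / sn))
  }
}
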