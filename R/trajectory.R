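new_trajectory <- function(kind, start_id, target_id, steps, seed = NA,
                           events = NULL, audit = NULL) {
  structure(list(kind = kind, start_id = start_id, target_id = target_id,
                 steps = steps, seed = seed, events = events, audit = audit),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  n <- nrow(x$steps) - 1L
  cat(sprintf("%s trajectory %s -> %s: %d step(s)\n", x$kind,
              x$start_id, x$target_id %||% "(de novo)", n))
  cols <- intersect(c("step", "mutation_id", "predicted", "measured",
                      "divergence"), names(x$steps))
  print(utils::head(x$steps[, cols], 12), row.names = FALSE)
  if (n > 11) cat("...\n")
  invisible(x)
}

score_candidates <- function(oracle, seqs, scoring, backgrounds) {
  if (scoring == "raw") return(oracle_score(oracle, seqs))
  vapply(seqs, function(s)
    marginal_footprint(oracle, s, backgrounds)$ratio, numeric(1),
    USE.NAMES = FALSE)
}

traj_divergence <- function(seqs, target, params) {
  vapply(seqs, function(s)
    100 - sequence_identity(align_global(s, target, params)), numeric(1),
    USE.NAMES = FALSE)
}

#' Greedy model-guided reconstitution trajectory
#'
#' Enumerates the mutation events separating an ancestral from an extant
#' ortholog, then introduces them one at a time: at every step each remaining
#' event is applied singly on top of the committed set, all candidates are
#' scored by the oracle, and the event with the greatest predicted gain is
#' committed. Ties break deterministically by lowest alignment column, then
#' lexicographic derived allele, so a trajectory needs no seed. The
#' trajectory terminates exactly at the extant sequence.
#'
#' @param ancestor,extant DNA strings.
#' @param oracle a `scoring_oracle`.
#' @param params alignment scoring parameters (default reconstitution
#'   preset).
#' @param scoring `"footprint"` (default; candidates scored by
#'   [marginal_footprint()]) or `"raw"` (direct oracle scores).
#' @param backgrounds background sequences for footprint scoring; generated
#'   automatically (n = 50, 3x the extant length, seeded) when NULL.
#' @param id_ancestor,id_extant labels.
#' @param audit keep the full per-step candidate score tables (attribute
#'   `audit`), enabling exhaustive local-optimality checks.
#' @return a `trajectory`; `steps` has one row per intermediate (step 0 = the
#'   unmutated ancestor) with the committed mutation id, sequence, predicted
#'   score, and percent divergence from the extant target.
#' @export
greedy_reconstitution <- function(ancestor, extant, oracle,
                                  params = preset_params("reconstitution"),
                                  scoring = c("footprint", "raw"),
                                  backgrounds = NULL,
                                  id_ancestor = "ancestor",
                                  id_extant = "extant", audit = FALSE) {
  scoring <- match.arg(scoring)
  if (scoring == "footprint" && is.null(backgrounds))
    backgrounds <- random_backgrounds(50, 3 * nchar(extant), seed = 1)
  aln <- align_global(ancestor, extant, params,
                      id_a = id_ancestor, id_b = id_extant)
  ms <- enumerate_mutations(aln)
  committed <- character(0)
  remaining <- ms$id
  cur_seq <- ancestor
  cur_score <- score_candidates(oracle, cur_seq, scoring, backgrounds)
  steps <- list(data.frame(step = 0L, mutation_id = NA_character_,
                           sequence = ancestor, predicted = cur_score,
                           measured = NA_real_, stringsAsFactors = FALSE))
  audit_log <- list()
  k <- 0L
  while (length(remaining) > 0L) {
    cand_seqs <- vapply(remaining, function(e)
      apply_mutations(aln, c(committed, e)), character(1), USE.NAMES = FALSE)
    sc <- score_candidates(oracle, cand_seqs, scoring, backgrounds)
    if (anyNA(sc))
      stop("oracle failure on candidate after mutation ",
           remaining[which(is.na(sc))[1]], call. = FALSE)
    rows <- ms[match(remaining, ms$id), ]
    ord <- order(-sc, rows$column_start, rows$to)
    pick <- ord[1]
    if (audit)
      audit_log[[length(audit_log) + 1L]] <-
        data.frame(step = k + 1L, mutation_id = remaining,
                   score = sc, gain = sc - cur_score,
                   committed = seq_along(remaining) == pick,
                   stringsAsFactors = FALSE)
    committed <- c(committed, remaining[pick])
    cur_seq <- cand_seqs[pick]
    cur_score <- sc[pick]
    remaining <- remaining[-pick]
    k <- k + 1L
    steps[[length(steps) + 1L]] <-
      data.frame(step = k, mutation_id = committed[k], sequence = cur_seq,
                 predicted = cur_score, measured = NA_real_,
                 stringsAsFactors = FALSE)
  }
  steps <- do.call(rbind, steps)
  steps$divergence <- traj_divergence(steps$sequence, extant, params)
  new_trajectory("model_optimized", id_ancestor, id_extant, steps,
                 events = ms,
                 audit = if (audit) do.call(rbind, audit_log) else NULL)
}

#' Random-order reconstitution trajectories
#'
#' Generates n independent trajectories, each introducing the same mutation
#' set in a uniformly random order; all trajectories share the ancestor and
#' the extant endpoint.
#'
#' @inheritParams greedy_reconstitution
#' @param n number of random trajectories (default 10).
#' @param seed RNG seed; draws are reproducible.
#' @param oracle optional; when given, intermediates are scored.
#' @return list of `trajectory` objects (kind "random").
#' @export
random_reconstitutions <- function(ancestor, extant, n = 10, seed = 1,
                                   oracle = NULL,
                                   params = preset_params("reconstitution"),
                                   scoring = c("raw", "footprint"),
                                   backgrounds = NULL,
                                   id_ancestor = "ancestor",
                                   id_extant = "extant") {
  scoring <- match.arg(scoring)
  stopifnot(n >= 1)
  if (scoring == "footprint" && is.null(backgrounds) && !is.null(oracle))
    backgrounds <- random_backgrounds(50, 3 * nchar(extant), seed = 1)
  aln <- align_global(ancestor, extant, params,
                      id_a = id_ancestor, id_b = id_extant)
  ms <- enumerate_mutations(aln)
  orders <- local_seed(seed, {
    lapply(seq_len(n), function(i) sample(ms$id))
  })
  lapply(seq_len(n), function(i) {
    ids <- orders[[i]]
    seqs <- c(ancestor, vapply(seq_along(ids), function(j)
      apply_mutations(aln, ids[seq_len(j)]), character(1)))
    pred <- if (is.null(oracle)) rep(NA_real_, length(seqs))
            else score_candidates(oracle, seqs, scoring, backgrounds)
    steps <- data.frame(step = seq_along(seqs) - 1L,
                        mutation_id = c(NA_character_, ids),
                        sequence = seqs, predicted = pred,
                        measured = NA_real_, stringsAsFactors = FALSE)
    steps$divergence <- traj_divergence(seqs, extant, params)
    new_trajectory("random", id_ancestor, id_extant, steps,
                   seed = seed + 0, events = ms)
  })
}

#' Phylogeny-derived trajectory
#'
#' The intermediates are the ancestral orthologs themselves, in lineage-path
#' order; the divergence axis is the percent divergence of each node sequence
#' from the target ortholog (computed by global alignment).
#'
#' @param path lineage path (node labels).
#' @param sequences named character vector of per-node sequences.
#' @param target label of the target (extant) node.
#' @param oracle optional oracle to score intermediates.
#' @param params alignment parameters for the divergence axis.
#' @return a `trajectory` (kind "phylogeny"); nodes lacking sequences are
#'   skipped with a warning.
#' @export
phylogeny_trajectory <- function(path, sequences, target,
                                 oracle = NULL,
                                 params = preset_params("reconstitution")) {
  have <- path %in% names(sequences)
  if (!all(have))
    warning("skipping path nodes without sequences: ",
            paste(path[!have], collapse = ", "))
  path <- path[have]
  if (!target %in% names(sequences))
    stop("target sequence '", target, "' missing", call. = FALSE)
  seqs <- unname(sequences[path])
  pred <- if (is.null(oracle)) rep(NA_real_, length(seqs))
          else oracle_score(oracle, seqs)
  steps <- data.frame(step = seq_along(path) - 1L, mutation_id = NA_character_,
                      node = path, sequence = seqs, predicted = pred,
                      measured = NA_real_, stringsAsFactors = FALSE)
  steps$divergence <- traj_divergence(seqs, sequences[[target]], params)
  new_trajectory("phylogeny", path[1], target, steps)
}

#' De novo enhancement / ablation tuning
#'
#' Iterative in silico saturation mutagenesis: at each step every possible
#' single-base substitution (3L candidates) of the current sequence is scored
#' by the oracle and the candidate with the highest (enhance) or lowest
#' (ablate) predicted score is committed. A candidate identical to the
#' immediately preceding sequence is excluded (cycle guard). Positions may be
#' mutated repeatedly; only substitutions are considered.
#'
#' @param seq starting DNA string.
#' @param oracle a `scoring_oracle`.
#' @param objective `"enhance"` or `"ablate"`.
#' @param steps number of sequential mutations to accumulate (default 50).
#' @param scoring `"raw"` (default) or `"footprint"`.
#' @param backgrounds backgrounds for footprint scoring.
#' @param id label of the starting sequence.
#' @return a `trajectory` (kind = objective) with `steps + 1` rows.
#' @export
denovo_tune <- function(seq, oracle, objective = c("enhance", "ablate"),
                        steps = 50, scoring = c("raw", "footprint"),
                        backgrounds = NULL, id = "start") {
  objective <- match.arg(objective)
  scoring <- match.arg(scoring)
  stopifnot(steps >= 1)
  validate_sequence(seq)
  if (scoring == "footprint" && is.null(backgrounds))
    backgrounds <- random_backgrounds(50, 3 * nchar(seq), seed = 1)
  L <- nchar(seq)
  cur <- seq
  prev <- NA_character_
  out <- list(data.frame(
    step = 0L, mutation_id = NA_character_, sequence = cur,
    predicted = score_candidates(oracle, cur, scoring, backgrounds),
    measured = NA_real_, stringsAsFactors = FALSE))
  for (s in seq_len(steps)) {
    chars <- strsplit(cur, "")[[1]]
    pos <- rep(seq_len(L), each = 3)
    alt <- unlist(lapply(chars, function(b) setdiff(VALID_BASES, b)),
                  use.names = FALSE)
    cand <- vapply(seq_along(pos), function(i) {
      x <- chars; x[pos[i]] <- alt[i]; paste(x, collapse = "")
    }, character(1))
    ok <- is.na(prev) | cand != prev
    sc <- score_candidates(oracle, cand[ok], scoring, backgrounds)
    pos_ok <- pos[ok]; alt_ok <- alt[ok]
    ord <- if (objective == "enhance") order(-sc, pos_ok, alt_ok)
           else order(sc, pos_ok, alt_ok)
    pick <- ord[1]
    prev <- cur
    mut_id <- sprintf("t%03d_%d%s>%s", s, pos_ok[pick] - 1L,
                      chars[pos_ok[pick]], alt_ok[pick])
    cur <- cand[ok][pick]
    out[[length(out) + 1L]] <- data.frame(
      step = s, mutation_id = mut_id, sequence = cur,
      predicted = sc[pick], measured = NA_real_, stringsAsFactors = FALSE)
  }
  steps_df <- do.call(rbind, out)
  new_trajectory(objective, id, NULL, steps_df)
}

#' Earliest step reaching an activity level
#'
#' @param traj a `trajectory`.
#' @param level activity level to compare against.
#' @param direction `"ge"`: value >= level; `"le"`: value <= level.
#' @param use `"auto"` (measured when any present, else predicted),
#'   `"measured"`, or `"predicted"`.
#' @return smallest step index (0-based; 0 = the unmutated start) whose value
#'   satisfies the comparison, or NA if never.
#' @export
steps_to_level <- function(traj, level, direction = c("ge", "le"),
                           use = c("auto", "measured", "predicted")) {
  direction <- match.arg(direction)
  use <- match.arg(use)
  v <- switch(use,
    auto = if (any(!is.na(traj$steps$measured))) traj$steps$measured
           else traj$steps$predicted,
    measured = traj$steps$measured,
    predicted = traj$steps$predicted)
  hit <- if (direction == "ge") which(v >= level) else which(v <= level)
  if (length(hit) == 0L) NA_integer_ else traj$steps$step[min(hit)]
}

#' Count reconstituted reference TFBSs in a sequence
#'
#' A reference functional site counts as reconstituted when the best
#' normalized affinity of its TF over the site's window in `seq` (mapped via
#' global alignment to the reference) equals or exceeds the endogenous
#' normalized affinity. Sites whose window is deleted in `seq` are counted as
#' not reconstituted.
#'
#' @param seq DNA string to evaluate.
#' @param reference endogenous reference sequence the sites live on.
#' @param sites data.frame with `site_id`, `tf`, `start`, `end` (0-based
#'   half-open on the reference), `norm_affinity` (endogenous value).
#' @param motifs,normrefs named lists keyed by TF label.
#' @param params alignment parameters used to map windows.
#' @return integer count.
#' @export
reconstituted_tfbs_count <- function(seq, reference, sites, motifs, normrefs,
                                     params = preset_params("reconstitution")) {
  if (nrow(sites) == 0L) return(0L)
  aln <- align_global(seq, reference, params)
  msa <- c(qry = aln$aligned_a, ref = aln$aligned_b)
  n <- 0L
  for (r in seq_len(nrow(sites))) {
    tf <- sites$tf[r]
    if (!tf %in% names(motifs)) next
    w <- map_interval(msa, "ref", "qry", sites$start[r], sites$end[r])
    if (is.null(w)) next
    aff <- max_affinity_in_window(seq, motifs[[tf]], normrefs[[tf]],
                                  w$start, w$end)
    if (aff >= sites$norm_affinity[r]) n <- n + 1L
  }
  n
}

#' Attach measured activities to a trajectory
#'
#' @param traj a `trajectory`.
#' @param mu numeric vector of measured activities, one per step row.
#' @param sigma optional standard errors (same length).
#' @return the trajectory with `measured` (and `measured_sigma`) filled.
#' @export
set_measurements <- function(traj, mu, sigma = NULL) {
  stopifnot(length(mu) == nrow(traj$steps))
  traj$steps$measured <- as.numeric(mu)
  if (!is.null(sigma)) {
    stopifnot(length(sigma) == nrow(traj$steps))
    traj$steps$measured_sigma <- as.numeric(sigma)
  }
  traj
}

#' Write a trajectory as TSV (and optionally its intermediates as FASTA)
#' @param traj a `trajectory`.
#' @param path TSV file.
#' @param fasta optional FASTA path for the intermediate sequences.
#' @export
write_trajectory <- function(traj, path, fasta = NULL) {
  d <- traj$steps
  d$kind <- traj$kind
  cols <- intersect(c("kind", "step", "mutation_id", "node", "predicted",
                      "measured", "measured_sigma", "divergence", "sequence"),
                    names(d))
  utils::write.table(d[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(fasta))
    write_fasta(stats::setNames(d$sequence,
                                sprintf("%s_step%03d", traj$kind, d$step)),
                fasta)
  invisible(path)
}
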