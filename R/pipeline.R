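write_report <- function(d, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  for (line in meta) writeLines(paste0("# ", line), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

report_meta <- function(config, seed) {
  c(paste0("cretrace ", as.character(utils::packageVersion("cretrace"))),
    paste0("config_hash ", config_hash(config)),
    paste0("seed ", seed))
}

#' Run the retracing pipeline: lineages, step changes, TFBS integrity
#'
#' End-to-end orchestration of the phylogenetic analysis: per-leaf lineage
#' paths and activity step changes, derived mutations on the largest positive
#' steps, per-node TFBS hit tables, and (when a grouping is given) clade
#' summaries. All outputs are plain TSV with a replayable metadata header
#' (package version, config hash, seed); reruns with the same inputs and
#' seed are byte-identical.
#'
#' @param tree labeled `phylo` tree.
#' @param msa named gapped rows (all nodes of interest).
#' @param activities data.frame `node`, `mu` (and optionally `sigma`, `n`)
#'   or named numeric; if NULL, `counts` + `barcode_map` are quantified with
#'   [quantify_mpra()] and elements are taken as node labels.
#' @param counts,barcode_map raw MPRA inputs (used when `activities` NULL).
#' @param motifs,normrefs named lists for TFBS scanning (optional; skip hit
#'   tables when NULL).
#' @param leaves leaf labels to trace (default: all tips present in the
#'   MSA).
#' @param grouping optional data.frame `node`, `clade`.
#' @param reference_id MSA row used for identity computation in clade
#'   summaries (optional).
#' @param out_dir output directory (created).
#' @param top_k derived mutations are reported for the k largest positive
#'   steps per leaf (default 3).
#' @param floor activity floor for inactive classification.
#' @param threshold TFBS call threshold.
#' @param winsor_frac winsorization fraction for quantification.
#' @param seed seed recorded in metadata (and used for quantification where
#'   applicable).
#' @return invisible list of the tables written.
#' @export
run_retrace <- function(tree, msa, activities = NULL, counts = NULL,
                        barcode_map = NULL, motifs = NULL, normrefs = NULL,
                        leaves = NULL, grouping = NULL, reference_id = NULL,
                        out_dir = "retrace_out", top_k = 3, floor = 0,
                        threshold = 0.05, winsor_frac = 0.01, seed = 1) {
  validate_phylo(tree)
  if (is.null(activities)) {
    if (is.null(counts) || is.null(barcode_map))
      stop("either activities or counts + barcode_map must be given",
           call. = FALSE)
    q <- quantify_mpra(counts, barcode_map, winsor_frac = winsor_frac)
    activities <- data.frame(node = q$summary$element, mu = q$summary$mu,
                             sigma = q$summary$sigma,
                             stringsAsFactors = FALSE)
  }
  if (!is.data.frame(activities))
    activities <- data.frame(node = names(activities),
                             mu = unname(activities), stringsAsFactors = FALSE)
  if (nrow(activities) == 0L)
    stop("activity table is empty", call. = FALSE)
  mu <- stats::setNames(activities$mu, activities$node)
  leaves <- leaves %||% intersect(tree$tip.label, names(msa))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(top_k = top_k, floor = floor, threshold = threshold,
              winsor_frac = winsor_frac)
  meta <- report_meta(cfg, seed)

  steps_all <- list(); derived_all <- list()
  for (leaf in leaves) {
    path <- lineage_path(tree, leaf)
    st <- step_changes(path, mu, floor = floor)
    st$leaf <- leaf
    steps_all[[leaf]] <- st
    top <- top_step_changes(st, top_k)
    top <- top[top$log2_fc > 0, , drop = FALSE]
    for (child in top$child) {
      if (!all(c(child, leaf) %in% names(msa))) next
      dm <- derived_mutations(msa, path, child, leaf)
      if (nrow(dm) > 0) {
        dm$leaf <- leaf; dm$node <- child
        derived_all[[paste(leaf, child)]] <- dm
      }
    }
  }
  steps_all <- do.call(rbind, steps_all)
  rownames(steps_all) <- NULL
  write_report(steps_all, file.path(out_dir, "step_changes.tsv"), meta)

  derived_all <- if (length(derived_all) > 0) do.call(rbind, derived_all)
    else data.frame(id = character(), kind = character(),
                    column_start = integer(), n_columns = integer(),
                    ref_pos = integer(), from = character(),
                    to = character(), leaf = character(), node = character(),
                    stringsAsFactors = FALSE)
  rownames(derived_all) <- NULL
  write_report(derived_all, file.path(out_dir, "derived_mutations.tsv"), meta)

  out <- list(step_changes = steps_all, derived_mutations = derived_all)

  if (!is.null(motifs)) {
    if (is.null(normrefs))
      normrefs <- lapply(motifs, compute_normalizer, n = 1e5, seed = seed)
    hit_rows <- list()
    for (nd in intersect(names(msa), activities$node)) {
      s <- gsub("-", "", msa[[nd]], fixed = TRUE)
      if (nchar(s) == 0) next
      h <- call_all_hits(s, motifs, normrefs, threshold, seq_id = nd)
      if (nrow(h) > 0) hit_rows[[nd]] <- h
    }
    hits <- if (length(hit_rows)) do.call(rbind, hit_rows)
      else data.frame()
    rownames(hits) <- NULL
    write_report(hits, file.path(out_dir, "tfbs_hits.tsv"), meta)
    out$tfbs_hits <- hits
  }

  if (!is.null(grouping)) {
    if (is.null(reference_id))
      stop("clade summaries need reference_id for identities", call. = FALSE)
    ids <- vapply(grouping$node, function(nd) {
      if (!nd %in% names(msa)) return(NA_real_)
      s <- gsub("-", "", msa[[nd]], fixed = TRUE)
      r <- gsub("-", "", msa[[reference_id]], fixed = TRUE)
      sequence_identity(align_global(s, r))
    }, numeric(1))
    cs <- clade_summary(tree, mu,
                        stats::setNames(ids, grouping$node), grouping)
    write_report(cs, file.path(out_dir, "clade_summary.tsv"), meta)
    out$clade_summary <- cs
  }
  invisible(out)
}

#' Run the rewriting pipeline: reconstitution, tuning, epistasis
#'
#' Designs the full trajectory panel between an ancestral and an extant
#' ortholog — the greedy model-optimized trajectory, n random-order
#' controls, and optional phylogeny-derived intermediates — plus de novo
#' enhancement and ablation tuning from the extant sequence, and writes
#' per-trajectory TSVs, intermediates FASTA, and a summary of
#' steps-to-level. Deterministic given config + seed.
#'
#' @param ancestor,extant DNA strings.
#' @param oracle a `scoring_oracle`.
#' @param out_dir output directory.
#' @param n_random number of random reconstitution trajectories (default
#'   10).
#' @param tune_steps de novo tuning steps (default 50).
#' @param scoring candidate scoring, `"raw"` or `"footprint"`.
#' @param phylo_path,node_sequences optional lineage path + per-node
#'   sequences for the phylogeny trajectory.
#' @param level activity level for steps-to-level (default: the oracle score
#'   of the extant sequence).
#' @param seed RNG seed for the random trajectories.
#' @return invisible list with all trajectories and the summary table.
#' @export
run_rewrite <- function(ancestor, extant, oracle, out_dir = "rewrite_out",
                        n_random = 10, tune_steps = 50,
                        scoring = c("raw", "footprint"),
                        phylo_path = NULL, node_sequences = NULL,
                        level = NULL, seed = 1) {
  scoring <- match.arg(scoring)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(n_random = n_random, tune_steps = tune_steps, scoring = scoring)
  meta <- report_meta(cfg, seed)
  level <- level %||% oracle_score(oracle, extant)

  greedy <- greedy_reconstitution(ancestor, extant, oracle, scoring = scoring)
  randoms <- random_reconstitutions(ancestor, extant, n = n_random,
                                    seed = seed, oracle = oracle,
                                    scoring = scoring)
  trajs <- c(list(greedy = greedy),
             stats::setNames(randoms, sprintf("random%02d",
                                              seq_along(randoms))))
  if (!is.null(phylo_path)) {
    trajs$phylogeny <- phylogeny_trajectory(phylo_path, node_sequences,
                                            target = phylo_path[length(phylo_path)],
                                            oracle = oracle)
  }
  trajs$enhance <- denovo_tune(extant, oracle, "enhance", steps = tune_steps,
                               scoring = scoring)
  trajs$ablate <- denovo_tune(extant, oracle, "ablate", steps = tune_steps,
                              scoring = scoring)

  for (nm in names(trajs)) {
    write_trajectory(trajs[[nm]],
                     file.path(out_dir, paste0("trajectory_", nm, ".tsv")),
                     fasta = file.path(out_dir,
                                       paste0("intermediates_", nm, ".fasta")))
  }
  summary <- data.frame(
    trajectory = names(trajs),
    kind = vapply(trajs, function(t) t$kind, ""),
    n_steps = vapply(trajs, function(t) nrow(t$steps) - 1L, 0L),
    end_predicted = vapply(trajs, function(t)
      utils::tail(t$steps$predicted, 1), numeric(1)),
    steps_to_level = vapply(trajs, function(t)
      as.integer(steps_to_level(t, level,
                                direction = if (t$kind == "ablate") "le"
                                            else "ge",
                                use = "predicted")), integer(1)),
    stringsAsFactors = FALSE)
  write_report(summary, file.path(out_dir, "summary.tsv"), meta)
  invisible(c(trajs, list(summary = summary)))
}
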