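#' Built-in toy PSAM models for simulation and testing
#'
#' Five sharp binding models for the parietal-endoderm TF vocabulary (Foxa2,
#' Sox17, Gata4, Gata6 — the latter two sharing the paralog group "Gata4/6" —
#' and Jun): consensus weight 1, off-consensus weight `off` at every
#' position. These are synthetic stand-ins with realistic widths, not fitted
#' binding models.
#'
#' @param off off-consensus weight (default 0.1).
#' @return named list of [psam()] objects.
#' @export
default_motifs <- function(off = 0.1) {
  mk <- function(tf, consensus, group = NULL) {
    bases <- strsplit(consensus, "")[[1]]
    w <- matrix(off, nrow = length(bases), ncol = 4,
                dimnames = list(NULL, VALID_BASES))
    w[cbind(seq_along(bases), match(bases, VALID_BASES))] <- 1
    psam(tf, w, paralog_group = group)
  }
  list(Foxa2 = mk("Foxa2", "TGTTTAC"),
       Sox17 = mk("Sox17", "AACAATG"),
       Gata4 = mk("Gata4", "AGATAAG", "Gata4/6"),
       Gata6 = mk("Gata6", "AGATAAC", "Gata4/6"),
       Jun   = mk("Jun",   "TGACTCA"))
}

motif_consensus <- function(motif) {
  paste(VALID_BASES[apply(motif$weights, 1, which.max)], collapse = "")
}

# --- token-tracked sequence evolution ---------------------------------------
# Every residue carries a unique token id; substitutions keep the token,
# insertions mint new tokens with fractional column keys, deletions drop
# them. Token identity gives exact residue homology across the whole tree,
# hence an exact MSA and exact retained-in-leaf bookkeeping, with no
# re-alignment step.

new_registry <- function(root_len) {
  env <- new.env(parent = emptyenv())
  env$key <- as.numeric(seq_len(root_len))
  env
}

mint_tokens <- function(reg, n, key_lo, key_hi) {
  keys <- key_lo + (key_hi - key_lo) * seq_len(n) / (n + 1)
  ids <- length(reg$key) + seq_len(n)
  reg$key <- c(reg$key, keys)
  ids
}

#' Simulate sequence evolution along a labeled phylogeny
#'
#' Root-to-tip recursion: on each branch the number of substitutions is
#' Poisson(L x sub_rate x branch length) with uniform positions and uniform
#' alternative bases; indels are Poisson(L x indel_rate x branch length)
#' with geometric lengths (mean `indel_mean`) and are never placed inside
#' protected (planted motif) windows. Planted events are applied last on
#' their branch and logged like all other events. Residues are tracked by
#' identity tokens, so the returned ground truth includes an exact MSA and
#' enough bookkeeping to decide whether any event is retained in any leaf.
#'
#' @param tree labeled `phylo` tree.
#' @param root_sequence DNA string for the root, or an integer length (a
#'   random root of that length is drawn under `seed`).
#' @param sub_rate substitutions per site per branch-length unit.
#' @param indel_rate indels per site per branch-length unit.
#' @param indel_mean mean indel length (geometric, >= 1).
#' @param planted list of planted events; each a list with `branch` (child
#'   node label), `type` (`"motif_gain"` or `"motif_loss"`), `name` (window
#'   label), and for gains `consensus` + `at` (1-based position in the child
#'   sequence) — gains substitute the window to the consensus and protect it
#'   from indels in all descendants; losses scramble a previously named
#'   window (each base replaced by the next base cyclically).
#' @param protect_root optional list of list(at, width, name) windows on the
#'   root sequence to protect from indels (used when the root itself carries
#'   a motif module).
#' @param oracle optional `scoring_oracle`; when given, per-node true
#'   activities are computed on the final sequences.
#' @param seed RNG seed.
#' @return object of class `ground_truth`: list with `tree`, `sequences`
#'   (named, all nodes), `msa` (named gapped rows, exact), `event_log`
#'   (data.frame), `tokens` (per-node list(ids, bases)), `activity` (named
#'   numeric or NULL).
#' @export
simulate_evolution <- function(tree, root_sequence, sub_rate = 0.02,
                               indel_rate = 0.002, indel_mean = 1.5,
                               planted = list(), protect_root = list(),
                               oracle = NULL, seed = 1) {
  validate_phylo(tree)
  stopifnot(sub_rate >= 0, indel_rate >= 0, indel_mean >= 1)
  labs <- c(tree$tip.label, tree$node.label)
  for (pe in planted)
    if (!pe$branch %in% labs)
      stop("planted event references unknown branch '", pe$branch, "'",
           call. = FALSE)

  local_seed(seed, {
    root_seq <- if (is.numeric(root_sequence))
      paste(sample(VALID_BASES, root_sequence, replace = TRUE), collapse = "")
    else validate_sequence(root_sequence)
    L0 <- nchar(root_seq)
    reg <- new_registry(L0)

    states <- list()   # per node label: list(ids, bases)
    protected <- list() # per node label: named list of token-id vectors
    logs <- list()

    root_label <- node_label(tree, length(tree$tip.label) + 1L)
    states[[root_label]] <- list(ids = seq_len(L0),
                                 bases = strsplit(root_seq, "")[[1]])
    prot0 <- list()
    for (w in protect_root)
      prot0[[w$name]] <- seq.int(w$at, w$at + w$width - 1L)
    protected[[root_label]] <- prot0

    children_of <- split(tree$edge[, 2], tree$edge[, 1])
    edge_len <- stats::setNames(tree$edge.length, paste(tree$edge[, 1],
                                                        tree$edge[, 2]))

    evolve_edge <- function(parent_n, child_n) {
      plab <- node_label(tree, parent_n); clab <- node_label(tree, child_n)
      st <- states[[plab]]
      prot <- protected[[plab]]
      bl <- edge_len[[paste(parent_n, child_n)]]
      ev <- list()
      is_protected <- function(ids) ids %in% unlist(prot)

      # substitutions
      L <- length(st$bases)
      n_sub <- stats::rpois(1, L * sub_rate * bl)
      if (n_sub > 0) {
        pos <- sample.int(L, min(n_sub, L))
        for (p in pos) {
          old <- st$bases[p]
          new <- sample(setdiff(VALID_BASES, old), 1)
          st$bases[p] <- new
          ev[[length(ev) + 1L]] <- data.frame(
            branch = clab, planted = FALSE, kind = "substitution",
            pos = p, from = old, to = new, tokens = as.character(st$ids[p]),
            stringsAsFactors = FALSE)
        }
      }
      # indels
      n_ind <- stats::rpois(1, L * indel_rate * bl)
      for (z in seq_len(n_ind)) {
        len <- stats::rgeom(1, 1 / indel_mean) + 1L
        if (stats::runif(1) < 0.5) {   # deletion
          Lc <- length(st$bases)
          if (Lc <= len + 1L) next
          placed <- FALSE
          for (try in 1:20) {
            s <- sample.int(Lc - len + 1L, 1)
            span <- s:(s + len - 1L)
            if (!any(is_protected(st$ids[span]))) { placed <- TRUE; break }
          }
          if (!placed) next
          ev[[length(ev) + 1L]] <- data.frame(
            branch = clab, planted = FALSE, kind = "deletion", pos = s,
            from = paste(st$bases[span], collapse = ""), to = "",
            tokens = paste(st$ids[span], collapse = ","),
            stringsAsFactors = FALSE)
          st$ids <- st$ids[-span]; st$bases <- st$bases[-span]
        } else {                        # insertion
          Lc <- length(st$bases)
          placed <- FALSE
          for (try in 1:20) {
            p <- sample.int(Lc + 1L, 1) - 1L   # insert after position p
            inside <- p >= 1L && p < Lc &&
              is_protected(st$ids[p]) && is_protected(st$ids[p + 1L])
            if (!inside) { placed <- TRUE; break }
          }
          if (!placed) next
          key_lo <- if (p >= 1L) reg$key[st$ids[p]] else reg$key[st$ids[1]] - 1
          key_hi <- if (p < Lc) reg$key[st$ids[p + 1L]]
                    else reg$key[st$ids[Lc]] + 1
          ids <- mint_tokens(reg, len, key_lo, key_hi)
          bases <- sample(VALID_BASES, len, replace = TRUE)
          ev[[length(ev) + 1L]] <- data.frame(
            branch = clab, planted = FALSE, kind = "insertion", pos = p + 1L,
            from = "", to = paste(bases, collapse = ""),
            tokens = paste(ids, collapse = ","), stringsAsFactors = FALSE)
          st$ids <- append(st$ids, ids, after = p)
          st$bases <- append(st$bases, bases, after = p)
        }
      }
      # planted events, applied last on their branch
      for (pe in planted) {
        if (pe$branch != clab) next
        if (pe$type == "motif_gain") {
          bases <- strsplit(pe$consensus, "")[[1]]
          span <- pe$at:(pe$at + length(bases) - 1L)
          if (max(span) > length(st$bases))
            stop("planted gain on branch '", clab,
                 "' falls outside the sequence (deletion collision)",
                 call. = FALSE)
          for (j in seq_along(span)) {
            p <- span[j]
            if (st$bases[p] == bases[j]) next
            ev[[length(ev) + 1L]] <- data.frame(
              branch = clab, planted = TRUE, kind = "substitution", pos = p,
              from = st$bases[p], to = bases[j],
              tokens = as.character(st$ids[p]), stringsAsFactors = FALSE)
            st$bases[p] <- bases[j]
          }
          prot[[pe$name]] <- st$ids[span]
        } else if (pe$type == "motif_loss") {
          toks <- prot[[pe$window]]
          if (is.null(toks))
            stop("motif_loss on branch '", clab, "' references unknown window '",
                 pe$window, "'", call. = FALSE)
          idx <- match(toks, st$ids)
          idx <- idx[!is.na(idx)]
          cyc <- c(A = "C", C = "G", G = "T", T = "A")
          for (p in idx) {
            old <- st$bases[p]
            ev[[length(ev) + 1L]] <- data.frame(
              branch = clab, planted = TRUE, kind = "substitution", pos = p,
              from = old, to = unname(cyc[old]),
              tokens = as.character(st$ids[p]), stringsAsFactors = FALSE)
            st$bases[p] <- unname(cyc[old])
          }
        } else stop("unknown planted event type '", pe$type, "'",
                    call. = FALSE)
      }

      states[[clab]] <<- st
      protected[[clab]] <<- prot
      if (length(ev) > 0) logs[[length(logs) + 1L]] <<- do.call(rbind, ev)

      for (gc in children_of[[as.character(child_n)]] %||% integer(0))
        evolve_edge(child_n, gc)
    }

    root_n <- length(tree$tip.label) + 1L
    for (ch in children_of[[as.character(root_n)]])
      evolve_edge(root_n, ch)

    sequences <- vapply(states, function(s) paste(s$bases, collapse = ""),
                        character(1))
    event_log <- if (length(logs) > 0) do.call(rbind, logs)
      else data.frame(branch = character(), planted = logical(),
                      kind = character(), pos = integer(), from = character(),
                      to = character(), tokens = character(),
                      stringsAsFactors = FALSE)
    event_log$id <- sprintf("ev%04d", seq_len(nrow(event_log)))

    # exact MSA from the token registry
    ord <- order(reg$key, seq_along(reg$key))
    col_of <- integer(length(reg$key)); col_of[ord] <- seq_along(ord)
    msa <- vapply(states, function(s) {
      row <- rep("-", length(reg$key))
      row[col_of[s$ids]] <- s$bases
      paste(row, collapse = "")
    }, character(1))

    activity <- if (!is.null(oracle)) {
      stats::setNames(oracle_score(oracle, unname(sequences)),
                      names(sequences))
    } else NULL

    structure(list(tree = tree, sequences = sequences, msa = msa,
                   event_log = event_log, tokens = states,
                   protected = protected, activity = activity, seed = seed),
              class = "ground_truth")
  })
}

#' Is a logged event retained in a leaf?
#'
#' A substitution or insertion is retained iff the leaf still carries all its
#' tokens with the derived base(s); a deletion is retained iff the leaf
#' carries none of the deleted tokens.
#'
#' @param truth a `ground_truth`.
#' @param event_id id from `truth$event_log`.
#' @param leaf leaf label.
#' @return logical.
#' @export
event_retained <- function(truth, event_id, leaf) {
  e <- truth$event_log[truth$event_log$id == event_id, , drop = FALSE]
  if (nrow(e) != 1L) stop("unknown event id", call. = FALSE)
  st <- truth$tokens[[leaf]]
  toks <- as.integer(strsplit(e$tokens, ",")[[1]])
  if (e$kind == "deletion") return(!any(toks %in% st$ids))
  idx <- match(toks, st$ids)
  if (anyNA(idx)) return(FALSE)
  identical(paste(st$bases[idx], collapse = ""), e$to)
}

#' Simulate MPRA barcode counts from element activities
#'
#' Per element, barcodes receive lognormal DNA abundance shares (library
#' composition, fixed across replicates). Per replicate, DNA counts are
#' multinomial over all barcodes at the given depth; RNA counts are
#' multinomial with rates proportional to element activity x a per-replicate
#' lognormal jitter x the barcode's DNA share. Elements with activity 0 get
#' zero RNA.
#'
#' @param activities named numeric vector (element -> true activity, >= 0).
#' @param barcodes_per_element barcodes per element (default 30).
#' @param sigma_d lognormal sdlog of barcode DNA shares (default 0.6).
#' @param depth total UMIs per sample (per replicate, per molecule; default
#'   1e6).
#' @param replicates number of replicates (default 3).
#' @param sigma_rep lognormal sdlog of per-replicate activity jitter
#'   (default 0.05).
#' @param assoc_depth expected association reads across the map (default
#'   1e4 x number of barcodes / 100, i.e. ~100 reads per barcode).
#' @param seed RNG seed.
#' @return list with `counts` (long [count_table()]) and `map`
#'   (barcode-to-element with `reads`).
#' @export
simulate_mpra <- function(activities, barcodes_per_element = 30,
                          sigma_d = 0.6, depth = 1e6, replicates = 3,
                          sigma_rep = 0.05, assoc_depth = NULL, seed = 1) {
  stopifnot(all(activities >= 0), depth > 0, replicates >= 1)
  if (all(activities == 0))
    stop("all activities are zero: nothing to transcribe", call. = FALSE)
  elements <- names(activities)
  local_seed(seed, {
    bc <- data.frame(
      barcode = sprintf("bc_%s_%02d", rep(elements, each = barcodes_per_element),
                        rep(seq_len(barcodes_per_element), length(elements))),
      element = rep(elements, each = barcodes_per_element),
      stringsAsFactors = FALSE)
    share <- stats::rlnorm(nrow(bc), 0, sigma_d)
    share <- share / sum(share)
    assoc_depth <- assoc_depth %||% (100 * nrow(bc))
    bc$reads <- stats::rpois(nrow(bc), share * assoc_depth)

    rows <- list()
    for (r in seq_len(replicates)) {
      rep_name <- sprintf("rep%d", r)
      dna <- stats::rmultinom(1, depth, share)[, 1]
      jitter <- stats::setNames(stats::rlnorm(length(elements), 0, sigma_rep),
                                elements)
      rate <- activities[bc$element] * jitter[bc$element] * share
      rna <- if (sum(rate) == 0) rep(0L, nrow(bc))
             else stats::rmultinom(1, depth, rate / sum(rate))[, 1]
      rows[[length(rows) + 1L]] <- data.frame(
        barcode = rep(bc$barcode, 2),
        replicate = rep_name,
        molecule = rep(c("DNA", "RNA"), each = nrow(bc)),
        count = c(dna, rna), stringsAsFactors = FALSE)
    }
    list(counts = count_table(do.call(rbind, rows)),
         map = bc[, c("barcode", "element", "reads")])
  })
}

make_labeled_tree <- function(n_leaves, bl_range = c(0.05, 0.3)) {
  tree <- ape::rtree(n_leaves, rooted = TRUE)
  tree$tip.label <- sprintf("sp%02d", seq_len(n_leaves))
  tree$node.label <- sprintf("Anc%02d", seq_len(tree$Nnode))
  tree$edge.length <- stats::runif(nrow(tree$edge), bl_range[1], bl_range[2])
  tree
}

# smallest non-root internal node (by label order) whose clade has n tips in
# the given range; deterministic for a fixed tree
pick_terminal_clade <- function(tree, min_tips = 2, max_tips = 4) {
  root_n <- length(tree$tip.label) + 1L
  for (n in (root_n + 1L):(root_n + tree$Nnode - 1L)) {
    tips <- length(ape::extract.clade(tree, n)$tip.label)
    if (tips >= min_tips && tips <= max_tips) return(n)
  }
  stop("no internal clade with the requested tip count", call. = FALSE)
}

clade_leaves <- function(tree, node_label) {
  n <- node_number(tree, node_label)
  if (n <= length(tree$tip.label)) return(node_label)
  ape::extract.clade(tree, n)$tip.label
}

#' Build the two canonical synthetic scenarios
#'
#' Scenario "repurposed" (conserved-but-repurposed): low substitution rate;
#' three TFBS-creating planted gains (Foxa2 + Sox17 + Gata4 consensus, the
#' required heterotypic module) confined to the stem of one small terminal
#' clade, so activity above baseline is restricted to that clade. Scenario
#' "module" (module-dependent): the required module is present in the root
#' sequence; a higher substitution rate; two independent planted module
#' losses in distinct subclades (whose descendants fall to baseline) and two
#' independent Jun booster gains in other subclades.
#'
#' @param seed RNG seed (fixture regeneration is byte-identical under the
#'   same seed).
#' @param scenario `"repurposed"` or `"module"`.
#' @param n_leaves,root_len tree and sequence size (defaults 16 leaves /
#'   180 bp for "repurposed", 24 / 180 for "module").
#' @param dir optional directory; when given, writes sequences.fasta,
#'   tree.nwk, msa.fasta, psams.tsv, counts.tsv, barcode_map.tsv,
#'   truth.json.
#' @param mpra simulate barcode counts too (default TRUE when `dir` given).
#' @return list with `truth` (a `ground_truth` incl. per-node activities),
#'   `oracle`, `config` (the `surrogate_config`), `planted_branches`,
#'   `module_positions`, and (optionally) `counts`, `map`.
#' @export
make_fixture_suite <- function(seed = 1,
                               scenario = c("repurposed", "module"),
                               n_leaves = NULL, root_len = 180,
                               dir = NULL, mpra = !is.null(dir)) {
  scenario <- match.arg(scenario)
  n_leaves <- n_leaves %||% if (scenario == "repurposed") 16L else 24L
  motifs <- default_motifs()
  module_tfs <- c(Foxa2 = "TGTTTAC", Sox17 = "AACAATG", Gata4 = "AGATAAG")
  at <- c(Foxa2 = 40L, Sox17 = 65L, Gata4 = 90L)

  cfg <- surrogate_config(
    motifs,
    booster_weights = c(Foxa2 = 0.03, Sox17 = 0.03, "Gata4/6" = 0.03,
                        Jun = 0.05),
    required_modules = list(c(Foxa2 = 1.5, Sox17 = 1.5, "Gata4/6" = 1.5)),
    b0 = 0.14, c_max = 1.4, seed = 1)
  oracle <- surrogate_oracle(cfg)

  tree <- local_seed(seed, make_labeled_tree(n_leaves))

  if (scenario == "repurposed") {
    gain_node <- node_label(tree, pick_terminal_clade(tree))
    planted <- lapply(names(module_tfs), function(tf)
      list(branch = gain_node, type = "motif_gain", name = paste0("w_", tf),
           consensus = module_tfs[[tf]], at = at[[tf]]))
    truth <- simulate_evolution(tree, root_len, sub_rate = 0.02,
                                indel_rate = 0.002, planted = planted,
                                oracle = oracle, seed = seed + 1000L)
    planted_branches <- gain_node
  } else {
    # root carries the module: embed consensus in a random root sequence
    root_seq <- local_seed(seed + 500L, {
      s <- sample(VALID_BASES, root_len, replace = TRUE)
      for (tf in names(module_tfs)) {
        span <- at[[tf]]:(at[[tf]] + nchar(module_tfs[[tf]]) - 1L)
        s[span] <- strsplit(module_tfs[[tf]], "")[[1]]
      }
      paste(s, collapse = "")
    })
    protect_root <- lapply(names(module_tfs), function(tf)
      list(at = at[[tf]], width = nchar(module_tfs[[tf]]),
           name = paste0("w_", tf)))
    # choose four distinct internal branches for losses and booster gains
    root_n <- n_leaves + 1L
    internals <- (root_n + 1L):(root_n + tree$Nnode - 1L)
    sizes <- vapply(internals, function(n)
      length(ape::extract.clade(tree, n)$tip.label), integer(1))
    cand <- internals[sizes >= 2 & sizes <= 6]
    # spread picks across the candidate list, deterministic
    pick <- cand[unique(round(seq(1, length(cand), length.out = 4)))]
    if (length(pick) < 4)
      stop("tree too small for the module scenario", call. = FALSE)
    loss_nodes <- node_label(tree, pick[1:2])
    jun_nodes <- node_label(tree, pick[3:4])
    planted <- c(
      lapply(loss_nodes, function(nd)
        list(branch = nd, type = "motif_loss", window = "w_Foxa2")),
      lapply(seq_along(jun_nodes), function(i)
        list(branch = jun_nodes[i], type = "motif_gain",
             name = paste0("w_Jun", i), consensus = "TGACTCA", at = 130L)))
    truth <- simulate_evolution(tree, root_seq, sub_rate = 0.04,
                                indel_rate = 0.002, planted = planted,
                                protect_root = protect_root,
                                oracle = oracle, seed = seed + 1000L)
    planted_branches <- c(loss = loss_nodes, jun = jun_nodes)
  }

  out <- list(truth = truth, oracle = oracle, config = cfg,
              planted_branches = planted_branches,
              module_positions = at, scenario = scenario, seed = seed)

  if (mpra) {
    sim <- simulate_mpra(truth$activity, seed = seed + 2000L)
    out$counts <- sim$counts
    out$map <- sim$map
  }

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(truth$sequences, file.path(dir, "sequences.fasta"))
    ape::write.tree(truth$tree, file.path(dir, "tree.nwk"))
    write_fasta(truth$msa, file.path(dir, "msa.fasta"))
    write_psams(default_motifs(), file.path(dir, "psams.tsv"))
    if (mpra) {
      write_count_table(out$counts, file.path(dir, "counts.tsv"))
      utils::write.table(out$map, file.path(dir, "barcode_map.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(
      list(scenario = scenario, seed = seed,
           planted_branches = as.list(planted_branches),
           module_positions = as.list(at),
           activity = as.list(truth$activity)),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  out
}
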