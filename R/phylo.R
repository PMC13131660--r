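#' Read a labeled phylogeny from Newick
#'
#' Reads a rooted tree whose internal nodes all carry labels (named
#' reconstructed ancestors); trees with unlabeled internal nodes are rejected
#' because every downstream operation references ancestors by name.
#'
#' @param path Newick file, or a Newick string via `text`.
#' @param text Newick string (alternative to `path`).
#' @return an `ape::phylo` tree.
#' @export
read_phylo <- function(path = NULL, text = NULL) {
  tree <- if (!is.null(text)) ape::read.tree(text = text)
          else ape::read.tree(path)
  validate_phylo(tree)
}

validate_phylo <- function(tree) {
  if (is.null(tree$node.label) || any(tree$node.label == "") ||
      anyNA(tree$node.label))
    stop("all internal nodes must be labeled", call. = FALSE)
  labs <- c(tree$tip.label, tree$node.label)
  if (anyDuplicated(labs))
    stop("duplicated node labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "), call. = FALSE)
  tree
}

node_number <- function(tree, label) {
  labs <- c(tree$tip.label, tree$node.label)
  i <- match(label, labs)
  if (is.na(i)) stop("node '", label, "' not in tree", call. = FALSE)
  i
}

node_label <- function(tree, number) c(tree$tip.label, tree$node.label)[number]

#' Root-to-leaf lineage path
#'
#' Ordered list of node labels from the root (or a chosen ancestor) down to a
#' leaf, following parent-child edges.
#'
#' @param tree labeled `phylo` tree.
#' @param leaf tip label.
#' @param from_node optional ancestor label to start from (default: root);
#'   must lie on the root-to-leaf path.
#' @return character vector of node labels, first = starting ancestor,
#'   last = leaf.
#' @export
lineage_path <- function(tree, leaf, from_node = NULL) {
  validate_phylo(tree)
  leaf_n <- node_number(tree, leaf)
  if (leaf_n > length(tree$tip.label))
    stop("'", leaf, "' is not a leaf", call. = FALSE)
  root_n <- length(tree$tip.label) + 1L
  path <- ape::nodepath(tree, from = root_n, to = leaf_n)
  labels <- node_label(tree, path)
  if (!is.null(from_node)) {
    i <- match(from_node, labels)
    if (is.na(i))
      stop("'", from_node, "' is not an ancestor of '", leaf, "'",
           call. = FALSE)
    labels <- labels[i:length(labels)]
  }
  labels
}

#' Per-edge activity step changes along a lineage
#'
#' For each consecutive (parent, child) pair on a lineage path with defined
#' activities, reports the log2 fold-change of the child activity relative to
#' the immediately prior ancestor. Ratios involving a zero or missing
#' activity are left NA; summed over a contiguous run of defined steps the
#' log2 fold-changes telescope to log2(last/first).
#'
#' @param path character vector of node labels (see [lineage_path()]).
#' @param act data.frame with columns `node`, `mu` (and optionally `sigma`,
#'   `n`), or a named numeric vector of activity means.
#' @param floor activity floor below which a node is flagged inactive for
#'   classification (default 0; typically the negative-control mean).
#' @return data.frame with `parent`, `child`, `mu_parent`, `mu_child`,
#'   `log2_fc`, `active_parent`, `active_child`.
#' @export
step_changes <- function(path, act, floor = 0) {
  mu <- if (is.data.frame(act)) stats::setNames(act$mu, act$node) else act
  if (length(path) < 2L)
    stop("path must contain at least two nodes", call. = FALSE)
  parent <- path[-length(path)]
  child <- path[-1L]
  mp <- unname(mu[parent]); mc <- unname(mu[child])
  ok <- !is.na(mp) & !is.na(mc) & mp > 0 & mc > 0
  data.frame(parent = parent, child = child,
             mu_parent = mp, mu_child = mc,
             log2_fc = ifelse(ok, log2(mc / mp), NA_real_),
             active_parent = !is.na(mp) & mp > floor,
             active_child = !is.na(mc) & mc > floor,
             stringsAsFactors = FALSE)
}

#' Largest activity step changes
#'
#' Returns the k edges with the largest log2 fold-change, sorted by
#' decreasing magnitude with ties kept in path order (stable sort); NA steps
#' are dropped.
#'
#' @param steps output of [step_changes()].
#' @param k number of edges to return.
#' @return subset of `steps`.
#' @export
top_step_changes <- function(steps, k = 3) {
  stopifnot(k >= 1)
  steps <- steps[!is.na(steps$log2_fc), , drop = FALSE]
  ord <- order(-steps$log2_fc)        # radix/stable for ties
  out <- steps[ord, , drop = FALSE][seq_len(min(k, nrow(steps))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derived mutations at a node that are retained in an extant leaf
#'
#' Compares a node against its immediate predecessor on the lineage path,
#' column by column over a shared MSA, and returns the differences that are
#' newly present at the node AND still carried by the extant ortholog at the
#' same MSA columns (i.e. not subsequently reverted or overwritten).
#' Adjacent columns of the same kind merge into one event, mirroring
#' [enumerate_mutations()].
#'
#' @param msa named gapped rows containing all path nodes of interest.
#' @param path lineage path (character labels); `node_x` must not be first.
#' @param node_x node whose derived changes are sought.
#' @param extant leaf label (defaults to the last path entry).
#' @return data.frame with `id`, `kind`, `column_start`, `n_columns`,
#'   `ref_pos` (0-based position on the extant sequence), `from`, `to`.
#' @export
derived_mutations <- function(msa, path, node_x, extant = path[length(path)]) {
  i <- match(node_x, path)
  if (is.na(i) || i == 1L)
    stop("node_x must appear on the path after its predecessor", call. = FALSE)
  pred <- path[i - 1L]
  for (lab in c(pred, node_x, extant))
    if (!lab %in% names(msa))
      stop("sequence for node '", lab, "' missing from MSA", call. = FALSE)
  p <- strsplit(msa[[pred]], "")[[1]]
  x <- strsplit(msa[[node_x]], "")[[1]]
  e <- strsplit(msa[[extant]], "")[[1]]
  n <- length(p)
  keep <- p != x & x == e
  kind <- rep(NA_character_, n)
  kind[keep & p == "-"] <- "insertion"
  kind[keep & x == "-" & p != "-"] <- "deletion"
  kind[keep & p != "-" & x != "-"] <- "substitution"
  e_before <- c(0L, cumsum(e != "-"))[seq_len(n)]

  events <- list()
  j <- 1L
  while (j <= n) {
    if (is.na(kind[j])) { j <- j + 1L; next }
    if (kind[j] == "substitution") {
      events[[length(events) + 1L]] <- data.frame(
        kind = "substitution", column_start = j - 1L, n_columns = 1L,
        ref_pos = e_before[j], from = p[j], to = x[j],
        stringsAsFactors = FALSE)
      j <- j + 1L
    } else {
      k <- j
      while (k < n && !is.na(kind[k + 1L]) && kind[k + 1L] == kind[j])
        k <- k + 1L
      events[[length(events) + 1L]] <- data.frame(
        kind = kind[j], column_start = j - 1L, n_columns = k - j + 1L,
        ref_pos = e_before[j],
        from = if (kind[j] == "insertion") "" else
          paste(p[j:k], collapse = ""),
        to = if (kind[j] == "deletion") "" else
          paste(x[j:k], collapse = ""),
        stringsAsFactors = FALSE)
      j <- k + 1L
    }
  }
  out <- if (length(events) == 0L)
    data.frame(kind = character(), column_start = integer(),
               n_columns = integer(), ref_pos = integer(),
               from = character(), to = character(), stringsAsFactors = FALSE)
  else do.call(rbind, events)
  out <- out[order(out$column_start), , drop = FALSE]
  out <- cbind(id = sprintf("d%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-clade activity and identity summaries
#'
#' Groups nodes into clades and summarizes activity distributions and the
#' Spearman rank correlation between percent sequence identity and activity
#' (average ranks for ties; NA when a clade has fewer than 3 nodes with both
#' values, or when either variable is constant).
#'
#' @param tree labeled `phylo` tree (used to split leaves from ancestors).
#' @param act data.frame `node`, `mu` or named numeric vector.
#' @param identities data.frame `node`, `identity` or named numeric vector
#'   (percent identity to the reference ortholog).
#' @param grouping data.frame `node`, `clade`.
#' @return data.frame, one row per clade.
#' @export
clade_summary <- function(tree, act, identities, grouping) {
  mu <- if (is.data.frame(act)) stats::setNames(act$mu, act$node) else act
  idy <- if (is.data.frame(identities))
    stats::setNames(identities$identity, identities$node) else identities
  validate_phylo(tree)
  rows <- lapply(split(grouping$node, grouping$clade), function(nodes) {
    m <- unname(mu[nodes]); d <- unname(idy[nodes])
    both <- !is.na(m) & !is.na(d)
    rho <- if (sum(both) >= 3 && stats::sd(m[both]) > 0 && stats::sd(d[both]) > 0)
      stats::cor(d[both], m[both], method = "spearman") else NA_real_
    data.frame(n_extant = sum(nodes %in% tree$tip.label),
               n_ancestral = sum(!nodes %in% tree$tip.label),
               n_with_activity = sum(!is.na(m)),
               mean_mu = mean(m, na.rm = TRUE),
               median_mu = stats::median(m, na.rm = TRUE),
               sd_mu = stats::sd(m, na.rm = TRUE),
               spearman_rho = rho, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(clade = names(rows), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read / write node activity tables
#' @param path TSV with columns node, mu, sigma, n.
#' @export
read_node_activity <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname read_node_activity
#' @param act activity data.frame.
#' @export
write_node_activity <- function(act, path) {
  utils::write.table(act, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
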