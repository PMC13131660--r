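# Independent reference implementations used as oracles. These deliberately
# avoid the package's own code paths (recursion instead of iterative DP,
# string surgery instead of column-space editing).

# optimal global alignment score, linear gaps, by memoized recursion
bf_align_score <- function(a, b, match = 1, mis = -1, gap = -1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  memo <- matrix(NA_real_, n + 1, m + 1)
  rec <- function(i, j) {
    if (!is.na(memo[i + 1, j + 1])) return(memo[i + 1, j + 1])
    v <- if (i == 0 && j == 0) 0 else {
      best <- -Inf
      if (i > 0 && j > 0)
        best <- max(best, rec(i - 1, j - 1) +
                      if (A[i] == B[j]) match else mis)
      if (i > 0) best <- max(best, rec(i - 1, j) + gap)
      if (j > 0) best <- max(best, rec(i, j - 1) + gap)
      best
    }
    memo[i + 1, j + 1] <<- v
    v
  }
  rec(n, m)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# mutate a sequence with seeded substitutions/indels; returns the new string
mutate_seq <- function(x, n_sub = 3, n_ins = 1, n_del = 1) {
  ch <- strsplit(x, "")[[1]]
  for (i in seq_len(n_sub)) {
    p <- sample(length(ch), 1)
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  for (i in seq_len(n_ins)) {
    p <- sample(length(ch) + 1, 1) - 1
    ins <- sample(c("A", "C", "G", "T"), sample(1:2, 1), replace = TRUE)
    ch <- append(ch, ins, after = p)
  }
  for (i in seq_len(n_del)) {
    if (length(ch) < 4) break
    p <- sample(length(ch) - 1, 1)
    ch <- ch[-(p:(p + sample(0:1, 1)))]
  }
  paste(ch, collapse = "")
}

# apply a subset of mutation events by direct string surgery on the ancestor,
# using ancestor-side offsets computed from the alignment
string_edit_oracle <- function(aln, subset) {
  a <- strsplit(aln$aligned_a, "")[[1]]
  a_before <- c(0L, cumsum(a != "-"))
  anc <- strsplit(gsub("-", "", aln$aligned_a), "")[[1]]
  if (nrow(subset) == 0L) return(paste(anc, collapse = ""))
  subset$a_off <- a_before[subset$column_start + 1L]
  subset <- subset[order(-subset$a_off, -subset$column_start), , drop = FALSE]
  for (r in seq_len(nrow(subset))) {
    off <- subset$a_off[r]
    kind <- subset$kind[r]
    if (kind == "substitution") {
      anc[off + 1L] <- subset$to[r]
    } else if (kind == "deletion") {
      anc <- anc[-((off + 1L):(off + nchar(subset$from[r])))]
    } else {
      anc <- append(anc, strsplit(subset$to[r], "")[[1]], after = off)
    }
  }
  paste(anc, collapse = "")
}

# a strictly additive oracle over fixed positions: score = base + sum of
# weights at positions where the sequence carries the given target base
additive_position_oracle <- function(positions, target_bases, weights,
                                     base = 1) {
  scoring_oracle(function(seqs) {
    vapply(seqs, function(s) {
      ch <- strsplit(s, "")[[1]]
      base + sum(weights[ch[positions] == target_bases])
    }, numeric(1), USE.NAMES = FALSE)
  }, name = "additive_positions")
}

# small shared surrogate fixture (module + booster motifs)
test_surrogate <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) {
      cfg <- surrogate_config(
        default_motifs(),
        booster_weights = c(Foxa2 = 0.03, Sox17 = 0.03, "Gata4/6" = 0.03,
                            Jun = 0.05),
        required_modules = list(c(Foxa2 = 1.5, Sox17 = 1.5, "Gata4/6" = 1.5)),
        b0 = 0.14, c_max = 1.4, seed = 1)
      cached <<- list(cfg = cfg, oracle = surrogate_oracle(cfg))
    }
    cached
  }
})

# sequence with the full required module planted in an A/C background
module_sequence <- function(len = 120, at = c(20, 45, 70)) {
  set.seed(99)
  ch <- sample(c("A", "C"), len, replace = TRUE)
  plant <- c("TGTTTAC", "AACAATG", "AGATAAG")
  for (i in seq_along(at))
    ch[at[i]:(at[i] + 6)] <- strsplit(plant[i], "")[[1]]
  paste(ch, collapse = "")
}

# trajectory object with supplied measurements, for epistasis analytics
traj_from_measurements <- function(ids, measured, sigma = NULL, y0 = 1) {
  steps <- data.frame(step = 0:length(ids),
                      mutation_id = c(NA, ids),
                      sequence = "N/A", predicted = NA_real_,
                      measured = c(y0, measured),
                      stringsAsFactors = FALSE)
  if (!is.null(sigma)) steps$measured_sigma <- c(0, sigma)
  cretrace:::new_trajectory("model_optimized", "anc", "ext", steps)
}

# reconstitution instance with known per-position additive weights
make_additive_instance <- function(weights) {
  n <- length(weights)
  anc <- strrep("A", 6 * n)
  positions <- 6 * seq_len(n) - 3
  target_bases <- rep(c("G", "T", "C"), length.out = n)
  ch <- strsplit(anc, "")[[1]]
  ch[positions] <- target_bases
  list(ancestor = anc, extant = paste(ch, collapse = ""),
       oracle = additive_position_oracle(positions, target_bases, weights),
       positions = positions, weights = weights)
}
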