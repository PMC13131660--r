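flat_motif <- function(k = 4) {
  psam("flat", matrix(1, k, 4, dimnames = list(NULL, c("A", "C", "G", "T"))),
       normalize = FALSE)
}

test_that("k-mer scoring is the per-position product", {
  expect_equal(score_kmer(flat_motif(), "ACGT"), 1)
  m <- psam("hard", rbind(c(1, 0, 0, 0), c(1, 1, 1, 1)))
  expect_equal(score_kmer(m, "CA"), 0)
  expect_error(score_kmer(m, "ACA"), "width")
  # random motif vs an independent product recomputation
  set.seed(5)
  for (i in 1:10) {
    k <- sample(3:6, 1)
    w <- matrix(runif(4 * k, 0.01, 1), k, 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
    mm <- psam("rand", w)   # rows are re-scaled to max 1 at load
    km <- random_seq(k)
    idx <- match(strsplit(km, "")[[1]], c("A", "C", "G", "T"))
    manual <- prod((w / apply(w, 1, max))[cbind(1:k, idx)])
    expect_equal(score_kmer(mm, km), manual)
  }
})

test_that("scanning respects strand symmetry and finds planted consensus", {
  m <- default_motifs()$Foxa2
  set.seed(6)
  s <- random_seq(80)
  p <- scan_sequence(s, m)
  pr <- scan_sequence(revcomp(s), m)
  expect_equal(rev(pr$fwd), p$rev)
  expect_equal(rev(pr$rev), p$fwd)
  # flat motif gives a flat profile
  pf <- scan_sequence(s, flat_motif())
  expect_true(all(pf$fwd == 1) && all(pf$rev == 1))
  # planted consensus is the forward argmax
  s2 <- paste0(substr(s, 1, 30), "TGTTTAC", substr(s, 38, 80))
  p2 <- scan_sequence(s2, m)
  expect_equal(which.max(p2$fwd) - 1L, 30L)
  expect_warning(scan_sequence("ACG", m), "shorter")
})

test_that("normalizer is reproducible and close to the exhaustive quantile", {
  m <- default_motifs()$Foxa2
  n1 <- compute_normalizer(m, n = 2e5, seed = 7)
  n2 <- compute_normalizer(m, n = 2e5, seed = 7)
  expect_identical(n1$normalizer, n2$normalizer)
  # flat motif: every k-mer scores 1
  expect_equal(compute_normalizer(flat_motif(), n = 1000)$normalizer, 1)
  # sampled vs exhaustive population quantile for a small random motif
  set.seed(8)
  w <- matrix(runif(4 * 5, 0.05, 1), 5, 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  mm <- psam("rand5", w)
  ex <- compute_normalizer(mm, method = "exact")$normalizer
  sm <- compute_normalizer(mm, n = 2e5, seed = 9)$normalizer
  expect_lt(abs(sm - ex) / ex, 0.05)
})

test_that("hit calling uses strict threshold and the fwd>=rev strand rule", {
  # use a unit normalizer so threshold comparisons are exact
  nr1 <- compute_normalizer(flat_motif(7), n = 1000, seed = 1)
  expect_equal(nr1$normalizer, 1)
  prof <- structure(list(sequence_id = "s", tf_name = "flat", width = 7,
                         fwd = 0.05, rev = 0),
                    class = "affinity_profile")
  # exactly at threshold is not called (strict inequality)
  expect_equal(nrow(call_hits(prof, nr1, threshold = 0.05)), 0)
  prof$fwd <- 0.0501
  expect_equal(nrow(call_hits(prof, nr1, threshold = 0.05)), 1)
  # palindromic tie goes to the forward strand
  prof$rev <- prof$fwd
  expect_identical(call_hits(prof, nr1)$strand, "+")
  m <- default_motifs()$Foxa2
  nr <- compute_normalizer(m, n = 1e5, seed = 1)
  # planted consensus in a seeded low-affinity background: exactly one hit
  set.seed(12)
  bg <- paste(sample(c("A", "C"), 60, replace = TRUE), collapse = "")
  s <- paste0(substr(bg, 1, 25), "TGTTTAC", substr(bg, 33, 60))
  h <- call_hits(scan_sequence(s, m), nr, threshold = 0.5)
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 25)
  # raising the threshold never adds hits
  h1 <- call_hits(scan_sequence(s, m), nr, threshold = 0.05)
  h2 <- call_hits(scan_sequence(s, m), nr, threshold = 0.2)
  expect_true(all(h2$start %in% h1$start))
})

test_that("normalized affinities are invariant to per-position rescaling", {
  set.seed(13)
  w <- matrix(runif(4 * 6, 0.05, 1), 6, 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  m1 <- psam("m", w)
  w2 <- w; w2[3, ] <- w2[3, ] * 7   # row scaling is removed at load
  m2 <- psam("m", w2)
  expect_equal(m1$weights, m2$weights)
})

test_that("paralog merging takes the per-position maximum under the group label", {
  hits <- data.frame(
    seq_id = "s", tf = c("Gata4", "Gata6", "Foxa2"),
    start = c(10L, 10L, 30L), width = 7L, strand = "+",
    norm_affinity = c(0.3, 0.5, 0.8), stringsAsFactors = FALSE)
  groups <- c(Gata4 = "Gata4/6", Gata6 = "Gata4/6")
  merged <- merge_paralogs(hits, groups)
  g <- merged[merged$tf == "Gata4/6", ]
  expect_equal(nrow(g), 1)
  expect_equal(g$norm_affinity, 0.5)
  expect_identical(g$tf_source, "Gata6")
  expect_true("Foxa2" %in% merged$tf)
  # one paralog alone keeps its value under the group label
  solo <- merge_paralogs(hits[1, ], groups)
  expect_identical(solo$tf, "Gata4/6")
  expect_equal(solo$norm_affinity, 0.3)
  # randomized check vs direct per-position max
  set.seed(14)
  rh <- data.frame(seq_id = "s",
                   tf = sample(c("Gata4", "Gata6"), 40, TRUE),
                   start = sample(1:10, 40, TRUE), width = 7L, strand = "+",
                   norm_affinity = runif(40), stringsAsFactors = FALSE)
  mg <- merge_paralogs(rh, groups)
  for (st in unique(rh$start))
    expect_equal(mg$norm_affinity[mg$start == st],
                 max(rh$norm_affinity[rh$start == st]))
})

test_that("hits are assigned to reference sites by any-overlap, else novel", {
  sites <- data.frame(site_id = c("s1", "s2"), start = c(10L, 40L),
                      end = c(17L, 47L), stringsAsFactors = FALSE)
  hits <- data.frame(seq_id = "x", tf = "Foxa2",
                     start = c(10L, 16L, 25L), width = 7L, strand = "+",
                     norm_affinity = 1, stringsAsFactors = FALSE)
  out <- overlap_with_reference(hits, sites)
  expect_identical(out$site_id, c("s1", "s1", "novel"))
  # randomized intervals vs brute-force intersection oracle
  set.seed(15)
  for (rep in 1:10) {
    hs <- data.frame(seq_id = "x", tf = "t", start = sample(0:50, 12),
                     width = sample(3:8, 12, TRUE), strand = "+",
                     norm_affinity = 1, stringsAsFactors = FALSE)
    ss <- data.frame(site_id = paste0("s", 1:4), start = sample(0:50, 4),
                     end = 0L, stringsAsFactors = FALSE)
    ss$end <- ss$start + sample(3:8, 4, TRUE)
    out <- overlap_with_reference(hs, ss)
    for (i in seq_len(nrow(hs))) {
      any_ov <- any(hs$start[i] < ss$end & ss$start < hs$start[i] + hs$width[i])
      expect_identical(out$site_id[i] != "novel", any_ov)
    }
  }
})

test_that("site affinity fold changes follow direct rescoring", {
  m <- default_motifs()$Foxa2
  nr <- compute_normalizer(m, n = 1e5, seed = 1)
  base <- paste0(strrep("A", 20), "TGTTTAC", strrep("C", 20))
  # identical sequences: fold change 1
  msa <- c(ref = base, a = base, b = base)
  site <- list(start = 20L, end = 27L)
  fc <- affinity_fold_change(msa, "a", "b", "ref", site, m, nr)
  expect_equal(fc$fold, 1)
  # one consensus base broken in b: fold = 0.1 (one off-consensus weight)
  b <- paste0(strrep("A", 20), "TGTTGAC", strrep("C", 20))
  msa2 <- c(ref = base, a = base, b = b)
  fc2 <- affinity_fold_change(msa2, "a", "b", "ref", site, m, nr)
  expect_equal(fc2$fold, fc2$aff_b / fc2$aff_a)
  expect_equal(fc2$fold, 0.1, tolerance = 1e-9)
  # site deleted in b is reported lost
  msa3 <- c(ref = base,
            a = base,
            b = paste0(strrep("A", 20), strrep("-", 7), strrep("C", 20)))
  fc3 <- affinity_fold_change(msa3, "a", "b", "ref", site, m, nr)
  expect_identical(fc3$status, "lost")
})

test_that("PSAM TSV round-trips through read/write", {
  f <- tempfile(fileext = ".tsv")
  motifs <- default_motifs()
  write_psams(motifs, f)
  back <- read_psams(f, paralog_groups = c(Gata4 = "Gata4/6",
                                           Gata6 = "Gata4/6"))
  expect_setequal(names(back), names(motifs))
  expect_equal(back$Foxa2$weights, motifs$Foxa2$weights)
  expect_identical(back$Gata4$paralog_group, "Gata4/6")
})
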