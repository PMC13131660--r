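demo_effects <- function() {
  single_effects(data.frame(mutation_id = c("m1", "m2", "m3"),
                            log2_effect = c(1, 1, -1),
                            stringsAsFactors = FALSE), y0 = 1)
}

test_that("combination predictions follow the additive and multiplicative formulas", {
  eff <- demo_effects()
  # empty subset returns the background
  expect_equal(predict_combination(eff, character(0), "additive"), 1)
  expect_equal(predict_combination(eff, character(0), "multiplicative"), 1)
  # single mutation: both models return its measured activity exactly
  expect_equal(predict_combination(eff, "m1", "additive"), 2)
  expect_equal(predict_combination(eff, "m1", "multiplicative"), 2)
  # y0 = 1, two x2 mutations: additive 3, multiplicative 4
  expect_equal(predict_combination(eff, c("m1", "m2"), "additive"), 3)
  expect_equal(predict_combination(eff, c("m1", "m2"), "multiplicative"), 4)
  # additive floors at zero
  eff2 <- single_effects(data.frame(mutation_id = c("a", "b"),
                                    log2_effect = c(-5, -5)), y0 = 1)
  expect_equal(predict_combination(eff2, c("a", "b"), "additive"), 0)
  expect_error(predict_combination(eff, "zz", "additive"), "zz")
})

test_that("models diverge monotonically for stacked positive effects", {
  eff <- single_effects(data.frame(mutation_id = sprintf("m%d", 1:4),
                                   log2_effect = rep(1, 4)), y0 = 1)
  gaps <- vapply(1:4, function(k) {
    ids <- sprintf("m%d", seq_len(k))
    predict_combination(eff, ids, "multiplicative") -
      predict_combination(eff, ids, "additive")
  }, numeric(1))
  expect_equal(gaps[1], 0)
  expect_true(all(diff(gaps) > 0))
})

test_that("model comparison identifies the generating model", {
  # multiplicative ground truth: multiplicative rho = 1
  eff <- single_effects(data.frame(mutation_id = c("m1", "m2", "m3"),
                                   log2_effect = c(2, -1.5, 0.8)), y0 = 1)
  mult_truth <- cumprod(2^c(2, -1.5, 0.8))
  tr <- traj_from_measurements(c("m1", "m2", "m3"), mult_truth)
  mc <- model_comparison(tr, eff)
  expect_equal(unname(mc$rho["multiplicative"]), 1)
  # additive ground truth with rank-discriminating effects
  eff2 <- single_effects(data.frame(mutation_id = c("m1", "m2", "m3"),
                                    log2_effect = log2(c(6, 0.1, 1.5))),
                         y0 = 1)
  add_truth <- 1 + cumsum(c(6, 0.1, 1.5) - 1)
  tr2 <- traj_from_measurements(c("m1", "m2", "m3"), add_truth)
  mc2 <- model_comparison(tr2, eff2)
  expect_equal(unname(mc2$rho["additive"]), 1)
  expect_lt(unname(mc2$rho["multiplicative"]), 1)
  # predictions identical to measurements: both rho = 1
  expect_equal(unname(mc$rho["multiplicative"]), 1)
  # constant measurements: undefined
  tr3 <- traj_from_measurements(c("m1", "m2", "m3"), c(1, 1, 1))
  expect_true(all(is.na(model_comparison(tr3, eff)$rho)))
})

test_that("order dependence is zero for context-free effects and detects gates", {
  # identical effect in every context: sd across contexts 0
  t1 <- traj_from_measurements(c("a", "b"), c(2, 4), sigma = c(0.01, 0.01))
  t2 <- traj_from_measurements(c("b", "a"), c(2, 4), sigma = c(0.01, 0.01))
  od <- order_dependence(list(t1, t2))
  expect_equal(od$sd_across_contexts, c(0, 0))
  # planted AND-gate: b only acts when a is already present
  g1 <- traj_from_measurements(c("a", "b"), c(1.1, 8), sigma = c(0.01, 0.01))
  g2 <- traj_from_measurements(c("b", "a"), c(1.0, 8), sigma = c(0.01, 0.01))
  odg <- order_dependence(list(g1, g2))
  expect_gt(odg$ratio[odg$mutation_id == "b"], 1)
  # mutations in fewer than two trajectories are excluded
  t3 <- traj_from_measurements("c", 2, sigma = 0.01)
  expect_message(od2 <- order_dependence(list(t1, t2, t3)), "excluding 1")
  expect_false("c" %in% od2$mutation_id)
})

test_that("replicate-noise propagation matches the closed form", {
  mu <- c(2, 4); sig <- c(0.2, 0.1)
  t1 <- traj_from_measurements(c("a", "b"), mu, sigma = sig)
  t2 <- traj_from_measurements(c("b", "a"), mu, sigma = sig)
  od <- order_dependence(list(t1, t2))
  # contexts for "b": t1 step 2 (after 4+-0.1, before 2+-0.2) and
  # t2 step 1 (after 2+-0.2, before y0 = 1 with sigma 0)
  noise_t1 <- sqrt((0.1 / (4 * log(2)))^2 + (0.2 / (2 * log(2)))^2)
  noise_t2 <- sqrt((0.2 / (2 * log(2)))^2 + 0)
  row_b <- od[od$mutation_id == "b", ]
  expect_equal(row_b$sd_replicate_noise,
               sqrt(mean(c(noise_t1^2, noise_t2^2))))
})

test_that("TFBS attribution splits gains by interval overlap", {
  inst_events <- data.frame(id = c("m1", "m2", "m3", "m4"),
                            kind = "substitution",
                            column_start = c(5L, 15L, 25L, 35L),
                            n_columns = 1L, ref_pos = c(5L, 15L, 25L, 35L),
                            from = "A", to = "G", stringsAsFactors = FALSE)
  mk <- function(measured) {
    steps <- data.frame(step = 0:4,
                        mutation_id = c(NA, "m1", "m2", "m3", "m4"),
                        sequence = "N/A", predicted = NA_real_,
                        measured = measured, stringsAsFactors = FALSE)
    t <- cretrace:::new_trajectory("model_optimized", "anc", "ext", steps)
    t$events <- inst_events
    t
  }
  sites <- data.frame(start = c(4L, 14L), end = c(8L, 18L))
  # all gains at TFBS steps: observed share 100
  tr <- mk(c(1, 2, 4, 4, 4))
  at <- tfbs_attribution(tr, sites)
  expect_equal(at$observed_share, 100)
  expect_equal(at$expected_share, 50)
  # uniform gains: observed equals expected
  tr2 <- mk(c(1, 2, 4, 8, 16))
  at2 <- tfbs_attribution(tr2, sites)
  expect_equal(at2$observed_share, at2$expected_share)
  # hand-assigned mixed gains
  tr3 <- mk(c(1, 2, 2, 8, 8))   # +1 bit at m1 (tfbs), +2 bits at m3 (not)
  at3 <- tfbs_attribution(tr3, sites)
  expect_equal(at3$observed_share, 100 * 1 / 3)
  # no positive gains: undefined
  tr4 <- mk(c(1, 1, 1, 1, 1))
  expect_true(is.na(tfbs_attribution(tr4, sites)$observed_share))
})

test_that("step classification distinguishes reconstituting, optimizing, background", {
  ts <- test_surrogate()
  motifs <- ts$cfg$motifs; normrefs <- ts$cfg$normrefs
  # ancestor lacks the Foxa2 site; extant has it plus an unrelated change
  anc <- paste0(strrep("A", 20), "TGTTGAC", strrep("C", 33))   # 1 mismatch
  ext <- paste0(strrep("A", 20), "TGTTTAC", strrep("C", 20), "G",
                strrep("C", 12))
  aln <- align_global(anc, ext)
  ms <- enumerate_mutations(aln)
  tr <- greedy_reconstitution(anc, ext, ts$oracle, scoring = "raw")
  sites <- data.frame(site_id = "foxa2", tf = "Foxa2", start = 20L,
                      end = 27L, col_start = 20L, col_end = 27L,
                      stringsAsFactors = FALSE)
  # the one-mismatch ancestral site sits at normalized affinity 1; with the
  # call threshold above it the fixing step crosses -> reconstituting
  cls <- classify_steps(tr, ext, sites, motifs, normrefs, threshold = 2)
  fixing <- cls$class[cls$mutation_id %in%
                        ms$id[ms$column_start >= 20 & ms$column_start < 27]]
  expect_identical(fixing, "reconstituting")
  other <- cls$class[cls$mutation_id %in% ms$id[ms$column_start >= 27]]
  expect_true(all(other == "background"))
  # with the threshold below the ancestral affinity the same step optimizes
  cls2 <- classify_steps(tr, ext, sites, motifs, normrefs, threshold = 0.5)
  fixing2 <- cls2$class[cls2$mutation_id %in%
                          ms$id[ms$column_start >= 20 & ms$column_start < 27]]
  expect_identical(fixing2, "optimizing")
})

test_that("single-effect tables validate and read from TSV", {
  expect_error(single_effects(data.frame(mutation_id = "a",
                                         log2_effect = Inf), 1), "finite")
  expect_error(demo_effects_y0 <- single_effects(
    data.frame(mutation_id = "a", log2_effect = 1), 0), "positive")
  f <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(mutation_id = c("a", "b"), position = 1:2,
                                from = "A", to = "G",
                                log2_effect = c(0.5, -0.5)),
                     f, sep = "\t", quote = FALSE, row.names = FALSE)
  eff <- read_single_effects(f, y0 = 2)
  expect_equal(predict_combination(eff, "a", "multiplicative"), 2 * 2^0.5)
})
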