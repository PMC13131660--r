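hand_table <- function() {
  # 3 barcodes, 1 replicate; chosen so the arithmetic is easy to do by hand
  data.frame(
    barcode = rep(c("b1", "b2", "b3"), 2),
    replicate = "rep1",
    molecule = rep(c("DNA", "RNA"), each = 3),
    count = c(10, 20, 70, 30, 30, 40),
    stringsAsFactors = FALSE)
}

test_that("count tables validate their schema", {
  expect_s3_class(count_table(hand_table()), "data.frame")
  bad <- hand_table(); bad$count[1] <- -1
  expect_error(count_table(bad), "nonnegative")
  bad2 <- hand_table(); bad2$molecule[1] <- "rna"
  expect_error(count_table(bad2), "DNA or RNA")
  bad3 <- rbind(hand_table(), hand_table()[1, ])
  expect_error(count_table(bad3), "duplicated")
  f <- tempfile(fileext = ".tsv")
  write_count_table(hand_table(), f)
  expect_equal(read_count_table(f), hand_table())
})

test_that("barcode filtering removes low-support associations", {
  map <- data.frame(barcode = c("b1", "b2", "b3"),
                    element = c("e1", "e1", "e2"),
                    reads = c(1, 5, 10), stringsAsFactors = FALSE)
  expect_equal(nrow(filter_barcodes(map, 0)), 3)
  expect_message(out <- filter_barcodes(map, 2), "removed 1")
  expect_identical(out$barcode, c("b2", "b3"))
  expect_warning(filter_barcodes(map, 100), "no barcodes")
  dup <- rbind(map, map[1, ])
  expect_error(filter_barcodes(dup), "at most one")
})

test_that("barcode expression normalizes within sample type and divides", {
  # hand computation: DNA shares 0.1/0.2/0.7; RNA shares 0.3/0.3/0.4
  be <- barcode_expression(hand_table(), "rep1")
  expect_equal(be$ratio, c(0.3 / 0.1, 0.3 / 0.2, 0.4 / 0.7))
  # equal proportions: all ratios 1
  t2 <- hand_table(); t2$count <- c(1, 2, 3, 10, 20, 30)
  expect_equal(barcode_expression(t2, "rep1")$ratio, c(1, 1, 1))
  # scale invariance: multiplying all RNA counts by 10 changes nothing
  t3 <- hand_table()
  t3$count[t3$molecule == "RNA"] <- t3$count[t3$molecule == "RNA"] * 10
  expect_equal(barcode_expression(t3, "rep1")$ratio,
               barcode_expression(hand_table(), "rep1")$ratio)
  # zero-DNA barcodes are excluded as NA
  t4 <- hand_table(); t4$count[1] <- 0
  expect_true(is.na(barcode_expression(t4, "rep1")$ratio[1]))
  expect_equal(barcode_expression(t4, "rep1", pseudocount = 1)$ratio[1],
               (31 / 103) / (1 / 93))
})

test_that("winsorization clamps at interpolated quantiles", {
  x <- c(1, 2, 3, 4, 100)
  w <- winsorize(x, 0.1)
  q <- stats::quantile(x, c(0.1, 0.9), names = FALSE, type = 7)
  expect_equal(w, pmin(pmax(x, q[1]), q[2]))
  expect_identical(winsorize(x, 0), x)
})

test_that("element activity matches an independent winsorize-then-sum oracle", {
  set.seed(50)
  n1 <- 150; n2 <- 50; n <- n1 + n2
  dna <- c(rpois(n1 - 2, 50), 4000, 1, rpois(n2, 50))  # two planted outliers
  rna <- c(rpois(n1 - 2, 100), 10, 5000, rpois(n2, 60))
  tab <- data.frame(barcode = rep(sprintf("b%03d", 1:n), 2),
                    replicate = "rep1",
                    molecule = rep(c("DNA", "RNA"), each = n),
                    count = c(dna, rna), stringsAsFactors = FALSE)
  map <- data.frame(barcode = sprintf("b%03d", 1:n),
                    element = rep(c("e1", "e2"), c(n1, n2)),
                    reads = 10, stringsAsFactors = FALSE)
  ea <- element_activity(tab, map, "rep1", winsor_frac = 0.01)
  # independent oracle coded from the definition
  dn <- dna / sum(dna); rn <- rna / sum(rna)
  clamp <- function(v, f) {
    q <- stats::quantile(v, c(f, 1 - f), names = FALSE, type = 7)
    pmin(pmax(v, q[1]), q[2])
  }
  manual <- sum(clamp(rn[1:n1], 0.01)) / sum(clamp(dn[1:n1], 0.01))
  expect_equal(ea$activity[ea$element == "e1"], manual)
  # winsorization blunts the planted outliers (estimate moves)
  plain <- sum(rn[1:n1]) / sum(dn[1:n1])
  expect_false(isTRUE(all.equal(manual, plain)))
  # winsor_frac = 0 equals the plain summed-ratio estimator exactly
  ea0 <- element_activity(tab, map, "rep1", winsor_frac = 0)
  expect_equal(ea0$activity[ea0$element == "e1"], plain)
})

test_that("single and identical barcodes reduce to the barcode ratio", {
  tab <- hand_table()
  map <- data.frame(barcode = c("b1", "b2", "b3"),
                    element = c("e1", "e2", "e2"), reads = 10,
                    stringsAsFactors = FALSE)
  be <- barcode_expression(tab, "rep1")
  ea <- element_activity(tab, map, "rep1", winsor_frac = 0.01)
  expect_equal(ea$activity[ea$element == "e1"], be$ratio[1])
  # ratios mode: identical barcodes give the common ratio
  t2 <- hand_table(); t2$count <- c(10, 10, 10, 20, 20, 20)
  ea2 <- element_activity(t2, map, "rep1", mode = "ratios")
  expect_equal(ea2$activity, c(1, 1))
})

test_that("replicate statistics give mean and standard error", {
  expect_equal(replicate_stats(c(2, 2, 2))$sigma, 0)
  st <- replicate_stats(c(1, 3))
  expect_equal(st$mu, 2)
  expect_equal(st$sigma, stats::sd(c(1, 3)) / sqrt(2))
  expect_true(is.na(replicate_stats(5)$sigma))
  set.seed(51)
  x <- rnorm(10)
  expect_equal(replicate_stats(x)$sigma, stats::sd(x) / sqrt(10))
})

test_that("fold changes versus negative controls follow the definition", {
  s <- data.frame(element = c("neg1", "neg2", "e"),
                  mu = c(0.1, 0.1, 0.7), sigma = 0, n_replicates = 3,
                  n_barcodes = 10, stringsAsFactors = FALSE)
  out <- fold_vs_controls(s, c("neg1", "neg2"))
  expect_equal(out$fold_vs_neg[3], 7)
  expect_equal(out$log2_fold_vs_neg[3], log2(7))
  expect_equal(out$fold_vs_neg[1], 1)
  expect_error(fold_vs_controls(s, "nope"), "no negative controls")
})

test_that("estimated activities track simulated truth across replicates", {
  acts <- stats::setNames(exp(seq(log(0.14), log(8), length.out = 25)),
                          sprintf("e%02d", 1:25))
  sim <- simulate_mpra(acts, barcodes_per_element = 20, depth = 2e5,
                       replicates = 3, seed = 77)
  q <- quantify_mpra(sim$counts, sim$map)
  est <- stats::setNames(q$summary$mu, q$summary$element)[names(acts)]
  rho <- stats::cor(est, acts, method = "spearman")
  expect_gte(rho, 0.95)
  # sigma is finite with 3 replicates
  expect_true(all(is.finite(q$summary$sigma)))
})

test_that("bootstrap CI brackets the point estimate", {
  acts <- c(e1 = 1, e2 = 3)
  sim <- simulate_mpra(acts, barcodes_per_element = 40, depth = 5e4, seed = 5)
  ci <- bootstrap_activity_ci(sim$counts, sim$map, "rep1", "e2", seed = 2)
  expect_true(ci$lower <= ci$estimate && ci$estimate <= ci$upper)
})
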