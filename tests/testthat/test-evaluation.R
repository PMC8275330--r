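toy_universe <- function() {
  build_edge_universe(gene_universe(c("tf1", "tf2", "g1", "g2"),
                                    c("tf1", "tf2")))
}

test_that("build_chip_reference applies the strict q and inclusive window", {
  tss <- data.frame(gene = c("g1", "g2"), chrom = c("chr1", "chr2"),
                    tss = c(10000, 50000))
  peaks <- data.frame(
    tf = c("tf1", "tf1", "tf2", "tf2"),
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    summit = c(15000, 4999, 45000, 55001),
    qvalue = c(1e-6, 1e-6, 1e-5, 1e-7))
  ref <- build_chip_reference(peaks, tss)
  keys <- paste(ref$edges$regulator, ref$edges$target, sep = "->")
  # |15000 - 10000| = 5000 exactly -> included
  expect_true("tf1->g1" %in% keys)
  # q = 1e-5 exactly -> excluded (strict inequality), 55001 is 5001 bp away
  expect_false("tf2->g2" %in% keys)
  # covered regulators include TFs with no passing peak
  expect_setequal(ref$covered_regulators, c("tf1", "tf2"))
})

test_that("build_chip_reference equals a double-loop distance check and is
           row-order invariant", {
  set.seed(6)
  peaks <- data.frame(tf = sample(c("tf1", "tf2", "tf3"), 40, TRUE),
                      chrom = sample(c("chr1", "chr2"), 40, TRUE),
                      summit = sample.int(100000, 40),
                      qvalue = 10^runif(40, -8, -3))
  tss <- data.frame(gene = paste0("g", 1:8),
                    chrom = sample(c("chr1", "chr2"), 8, TRUE),
                    tss = sample.int(100000, 8))
  ref <- build_chip_reference(peaks, tss, q_max = 1e-5, window = 5000)
  expected <- character(0)
  for (i in seq_len(nrow(peaks))) for (j in seq_len(nrow(tss))) {
    if (peaks$qvalue[i] < 1e-5 && peaks$chrom[i] == tss$chrom[j] &&
        abs(peaks$summit[i] - tss$tss[j]) <= 5000)
      expected <- union(expected, paste(peaks$tf[i], tss$gene[j], sep = "->"))
  }
  got <- paste(ref$edges$regulator, ref$edges$target, sep = "->")
  expect_setequal(got, expected)
  ref2 <- build_chip_reference(peaks[sample(40), ], tss[sample(8), ])
  expect_setequal(paste(ref2$edges$regulator, ref2$edges$target, sep = "->"),
                  expected)
  expect_warning(
    build_chip_reference(transform(peaks, chrom = paste0("x", chrom)), tss),
    "no shared chromosome")
})

test_that("auprc: perfect ranking, constant scores, brute-force agreement", {
  u <- toy_universe()  # 6 directed edges
  keys <- edge_keys(u)
  ref <- reference_network(data.frame(regulator = c("tf1", "tf2"),
                                      target = c("g1", "g2")),
                           covered_regulators = c("tf1", "tf2"))
  labels <- as.integer(keys %in% c("tf1->g1", "tf2->g2"))
  # perfect ranking
  s_perf <- ifelse(labels == 1, 1, 0.1)
  pr <- auprc(s_perf, u, ref)
  expect_equal(pr$auprc, 1)
  expect_equal(pr$ratio, 1 / pr$prevalence)
  # constant scores behave like a random predictor
  pr_const <- auprc(rep(0.5, u$n_edges), u, ref)
  expect_equal(pr_const$auprc, pr_const$prevalence)
  expect_equal(pr_const$ratio, 1)
  # mixed ranks match the brute-force oracle, including tied scores
  set.seed(8)
  for (i in 1:20) {
    s <- sample(c(runif(4), 0.3, 0.3))
    pr_i <- auprc(s, u, ref)
    expect_equal(pr_i$auprc, pr_area_oracle(s, labels), tolerance = 1e-12)
    expect_equal(pr_i$ratio, pr_i$auprc / pr_i$prevalence, tolerance = 1e-12)
  }
  # invariance under strictly monotone transforms
  s <- runif(u$n_edges)
  expect_equal(auprc(s, u, ref)$auprc, auprc(exp(3 * s), u, ref)$auprc)
  # no-positive and no-negative errors
  ref_none <- reference_network(data.frame(regulator = "tf1", target = "g9"),
                                covered_regulators = "tf1")
  expect_error(auprc(s, u, ref_none), "positives")
})

test_that("auprc restricts to covered regulators when asked", {
  u <- toy_universe()
  keys <- edge_keys(u)
  ref <- reference_network(data.frame(regulator = "tf1", target = "g1"),
                           covered_regulators = "tf1")
  s <- seq_len(u$n_edges) / 10
  pr_cov <- auprc(s, u, ref, restrict_to_covered = TRUE)
  expect_equal(pr_cov$n_eval_edges, sum(startsWith(keys, "tf1->")))
  pr_all <- auprc(s, u, ref, restrict_to_covered = FALSE)
  expect_equal(pr_all$n_eval_edges, u$n_edges)
})

test_that("paired_signed_rank: exact tail, oracle agreement, approximation", {
  # all-positive differences, n = 6: p = 1/2^6
  a <- c(2, 3, 4, 5, 6, 7); b <- a - seq(0.1, 0.6, length.out = 6)
  r <- paired_signed_rank(a, b)
  expect_true(r$exact)
  expect_equal(r$p_value, 1 / 64)
  # mixed small instances vs exhaustive sign-pattern enumeration
  set.seed(10)
  for (i in 1:5) {
    x <- rnorm(8); y <- rnorm(8)
    got <- paired_signed_rank(x, y)
    expect_equal(got$p_value, signed_rank_oracle(x, y), tolerance = 1e-12)
  }
  # zero differences dropped; all-zero errors
  expect_error(paired_signed_rank(1:5, 1:5), "all differences are zero")
  # normal approximation agrees with the base-R implementation
  set.seed(12)
  x <- rnorm(40) + 0.3; y <- rnorm(40)
  approx <- paired_signed_rank(x, y)
  expect_false(approx$exact)
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                            alternative = "greater",
                                            exact = FALSE, correct = TRUE))
  expect_equal(approx$p_value, unname(wt$p.value), tolerance = 1e-10)
})

test_that("evaluate_networks produces one row per cell type and reference", {
  u <- toy_universe()
  set.seed(14)
  scores <- matrix(runif(u$n_edges * 2), ncol = 2)
  stack <- edge_score_stack(scores, universe = u,
                            cell_types = c("ctA", "ctB"))
  refs <- list(chip = reference_network(
    data.frame(regulator = "tf1", target = c("g1", "g2"))))
  res <- evaluate_networks(stack, refs)
  expect_equal(nrow(res), 2)
  expect_named(res, c("cell_type", "reference", "auprc", "prevalence",
                      "ratio", "n_eval_edges"))
  expect_equal(res$ratio, res$auprc / res$prevalence)
})
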