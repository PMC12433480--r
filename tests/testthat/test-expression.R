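test_that("median-of-ratios size factors follow the estimator definition", {
  m <- cbind(s1 = c(5L, 9L, 12L), s2 = c(5L, 9L, 12L))
  expect_equal(unname(size_factors(m)), c(1, 1))
  # hand-computed: sample 2 is a doubled copy of sample 1
  m <- rbind(g1 = c(4L, 8L), g2 = c(16L, 32L))
  colnames(m) <- c("s1", "s2")
  expect_equal(unname(size_factors(m)), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_error(size_factors(matrix(0L, 3, 2)), class = "viroscore_no_reference_genes")
  # genes with any zero are excluded from the reference
  m <- rbind(g1 = c(4L, 8L), g2 = c(16L, 32L), g3 = c(0L, 50L))
  colnames(m) <- c("s1", "s2")
  expect_equal(unname(size_factors(m)), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
})

test_that("size factors of depth-scaled copies recover the scaling ratios", {
  set.seed(5)
  base <- rnbinom(300, mu = 50, size = 5) + 1L
  ratios <- c(0.5, 1, 2, 4)
  m <- vapply(ratios, function(r) as.integer(round(base * r)), integer(300))
  colnames(m) <- paste0("s", seq_along(ratios))
  sf <- size_factors(m)
  rel <- sf / exp(mean(log(sf)))
  expect_equal(unname(rel), ratios / exp(mean(log(ratios))), tolerance = 0.02)
  # ... i.e. sf/ratios is constant up to rounding of the scaled counts
  expect_lt(sd(log(sf / ratios)), 0.02)
})

test_that("size factors agree with the DESeq2 reference estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(6)
  m <- matrix(rnbinom(200 * 6, mu = 80, size = 3), nrow = 200,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:6)))
  oracle <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(size_factors(m)), unname(oracle), tolerance = 1e-9)
})

test_that("log normalization and row scaling follow their definitions", {
  m <- rbind(g1 = c(0L, 7L), g2 = c(3L, 3L))
  colnames(m) <- c("s1", "s2")
  ln <- log_normalize(m, sf = c(1, 1))
  expect_equal(ln["g1", ], c(s1 = 0, s2 = 3))
  expect_gt(log_normalize(rbind(c(14L, 7L)), sf = c(1, 1))[1, 1], ln["g1", "s2"])
  sc <- scale_rows(rbind(a = c(1, 2, 3), b = c(4, 4, 4)))
  expect_equal(sc["a", ], c(-1, 0, 1))
  expect_equal(sc["b", ], c(0, 0, 0))
  set.seed(7)
  r <- matrix(rnorm(50), 5)
  z <- scale_rows(r)
  expect_equal(unname(rowMeans(z)), rep(0, 5), tolerance = 1e-9)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 5), tolerance = 1e-9)
  # scaled rows are exactly the z-scores of the input rows
  expect_equal(z, (r - rowMeans(r)) / apply(r, 1, sd))
})

test_that("Spearman closed form equals Pearson on ranks for untied data", {
  expect_equal(spearman_rho(1:4, 4:1)$estimate, -1)
  expect_equal(spearman_rho(1:5, 1:5)$estimate, 1)
  set.seed(8)
  for (i in 1:200) {
    n <- sample(4:15, 1)
    x <- sample(1000, n); y <- sample(1000, n)
    z <- spearman_rho(x, y)
    expect_equal(z$estimate, cor(rank(x), rank(y)), tolerance = 1e-12)
    expect_false(z$tied)
    expect_equal(z$estimate, 1 - 6 * z$sum_sq_rank_diff / (n * (n^2 - 1)),
                 tolerance = 1e-12)
  }
  tied <- spearman_rho(c(1, 1, 2, 3), c(4, 3, 2, 1))
  expect_true(tied$tied)
  expect_true(is.na(tied$sum_sq_rank_diff))
  expect_error(spearman_rho(c(1, 1, 1), 1:3), class = "viroscore_constant_vector")
})

test_that("exact Spearman p agrees with the cor.test enumeration oracle", {
  expect_equal(spearman_p(1, 3, method = "exact")$p, 1 / 3, tolerance = 1e-12)
  set.seed(9)
  for (n in c(5, 6, 7)) {
    x <- sample(100, n); y <- sample(100, n)
    r <- spearman_rho(x, y)$estimate
    mine <- spearman_p(r, n, method = "exact")$p
    oracle <- cor.test(x, y, method = "spearman", exact = TRUE,
                       alternative = "two.sided")$p.value
    expect_equal(mine, min(1, oracle), tolerance = 1e-9)
  }
  expect_error(spearman_p(0.5, 9, method = "exact"),
               class = "viroscore_exact_too_large")
})

test_that("Monte-Carlo Spearman p is seeded and the t approximation exact", {
  a <- spearman_p(-0.6, 9, method = "montecarlo", n_draws = 2e4, seed = 42)
  b <- spearman_p(-0.6, 9, method = "montecarlo", n_draws = 2e4, seed = 42)
  expect_identical(a, b)
  expect_true(a$se > 0)
  r <- -0.7182; n <- 11
  tt <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(spearman_p(r, n, method = "t_approx")$p,
               2 * pt(-abs(tt), n - 2), tolerance = 1e-6)
})

test_that("Pearson correlation handles exact linear structure", {
  x <- c(2, 5, 9, 11)
  expect_equal(pearson_r(x, 2 * x + 1)$estimate, 1)
  expect_equal(pearson_r(x, -x)$estimate, -1)
  expect_equal(pearson_r(c(-1, 0, 1), c(1, -2, 1))$estimate, 0)
  expect_error(pearson_r(c(1, 1, 1), 1:3), class = "viroscore_constant_vector")
})

test_that("rank correlation of expression recovers planted effects", {
  scores <- setNames(seq(2, 30, length.out = 12), sprintf("L%02d", 1:12))
  sim <- simulate_counts(scores, n_genes = 40, b1 = 2.5, seed = 101)
  nx <- normalize_expression(sim$counts)
  ranks <- rank_cell_lines(scores)
  co <- correlate_with_susceptibility(nx$lognorm, sim$sample_to_line, ranks,
                                      genes = c("NECTIN1", "NECTIN2", "BG0001"),
                                      methods = "spearman")
  planted <- co[co$gene %in% c("NECTIN1", "NECTIN2"), ]
  expect_true(all(planted$estimate < 0))
  # permuting sample order leaves records unchanged
  perm <- sample(ncol(nx$lognorm))
  co2 <- correlate_with_susceptibility(nx$lognorm[, perm],
                                       sim$sample_to_line[perm], ranks,
                                       genes = c("NECTIN1", "NECTIN2", "BG0001"),
                                       methods = "spearman")
  expect_equal(co, co2)
  # constant gene flagged undefined, absent gene rejected
  ln <- nx$lognorm
  ln["BG0002", ] <- 1
  cf <- correlate_with_susceptibility(ln, sim$sample_to_line, ranks,
                                      genes = "BG0002", methods = "spearman")
  expect_true(cf$undefined)
  expect_error(correlate_with_susceptibility(ln, sim$sample_to_line, ranks,
                                             genes = "NOPE"),
               class = "viroscore_gene_absent")
})
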