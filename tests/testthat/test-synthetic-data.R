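test_that("noise-free growth tracks the closed-form logistic solution", {
  tr <- cell_line_truth("X", g = 0.05, K = 95, C0 = 5, kmax = 0, sigma = 0)
  de <- simulation_design(t_end = 170, dt = 2, n_wells = 1, n_repeats = 1)
  sim <- simulate_confluence(tr, de)
  closed <- 95 / (1 + (95 / 5 - 1) * exp(-0.05 * sim$time_h))
  expect_lt(max(abs(sim$confluence_pct - closed) / closed), 0.01)
})

test_that("simulators are bit-identical under a fixed seed", {
  tr <- susceptible_truth()
  de <- small_design(seed = 5)
  expect_identical(simulate_confluence(tr, de), simulate_confluence(tr, de))
  expect_identical(simulate_cytotox(tr, de), simulate_cytotox(tr, de))
  expect_identical(simulate_flt3l(tr, de, c(8, 24, 48, 72)),
                   simulate_flt3l(tr, de, c(8, 24, 48, 72)))
  # and differ under another seed
  expect_false(identical(simulate_confluence(tr, de),
                         simulate_confluence(tr, de, seed = 6)))
})

test_that("killing is off at MOI 0 and null lines show no dose effect", {
  tr <- susceptible_truth(sigma = 0)
  de <- small_design()
  sim <- simulate_cytotox(tr, de)
  expect_true(all(sim$dead_per_mm2[sim$moi == 0] == 0))
  # null line: no dead cells anywhere, all MOIs identical to untreated
  simn <- simulate_cytotox(null_truth(sigma = 0), de)
  expect_true(all(simn$dead_per_mm2 == 0))
  w0 <- simn$confluence_pct[simn$moi == 0]
  for (m in setdiff(unique(simn$moi), 0)) {
    expect_equal(simn$confluence_pct[simn$moi == m], w0)
  }
})

test_that("noise-free dead-cell density is monotone in time and MOI", {
  tr <- susceptible_truth(sigma = 0)
  de <- small_design()
  sim <- simulate_cytotox(tr, de)
  one <- sim[sim$moi == 10 & sim$bio_repeat == 1 & sim$replicate == 1, ]
  expect_true(all(diff(one$dead_per_mm2) >= 0))
  expect_gt(max(one$dead_per_mm2), 0)
  # pointwise MOI ordering holds while killing is weak relative to growth
  # (at strong killing the high-MOI well is cleared and its cumulative
  # death plateaus, so the ordering can invert at late times)
  trw <- cell_line_truth("WEAK", kmax = 0.02, m50 = 0.1, sigma = 0)
  simw <- simulate_cytotox(trw, de)
  hi <- simw[simw$moi == 10 & simw$bio_repeat == 1 & simw$replicate == 1, ]
  lo <- simw[simw$moi == 0.1 & simw$bio_repeat == 1 & simw$replicate == 1, ]
  expect_true(all(hi$dead_per_mm2 >= lo$dead_per_mm2))
  expect_gt(max(hi$dead_per_mm2 - lo$dead_per_mm2), 0)
})

test_that("secreted FLT3L accumulates with killing and is zero untreated", {
  de <- small_design()
  fz <- simulate_flt3l(cell_line_truth("B0", kmax = 0.1, beta = 0, sigma = 0), de,
                       c(24, 48, 72))
  expect_true(all(fz$concentration == 0))
  f <- simulate_flt3l(susceptible_truth(sigma = 0), de, c(24, 48, 72))
  expect_true(all(f$concentration[f$moi == 0] == 0))
  treated <- f[f$moi == 1 & f$bio_repeat == 1 & f$replicate == 1, ]
  expect_gte(treated$concentration[treated$time_h == 72],
             treated$concentration[treated$time_h == 24])
  expect_error(simulate_flt3l(susceptible_truth(), de, timepoints = 71),
               class = "viroscore_off_grid")
})

test_that("null lines give normalized AUC distributions centered at 1", {
  de <- simulation_design(t_end = 72, dt = 2, n_wells = 1, n_repeats = 1)
  tr <- null_truth(sigma = 0.05)
  vals <- unlist(lapply(1:100, function(s) {
    a <- summarize_auc(simulate_confluence(tr, de, seed = s))
    a$auc_norm[a$moi > 0]
  }))
  sem <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 1), 3 * sem)
})

test_that("count simulation plants score effects and respects the null", {
  scores <- setNames(seq(1, 30, length.out = 12), sprintf("L%02d", 1:12))
  a <- simulate_counts(scores, n_genes = 20, seed = 3)
  b <- simulate_counts(scores, n_genes = 20, seed = 3)
  expect_identical(a$counts, b$counts)
  expect_equal(dim(a$counts), c(24L, 36L))
  expect_true(all(a$counts >= 0))
  expect_equal(sum(a$truth$planted), 4)
  # b1 = 0: planted genes decorrelate from the score (null behaviour)
  rhos <- unlist(lapply(1:60, function(s) {
    sim <- simulate_counts(scores, n_genes = 8, b1 = 0, seed = s)
    ln <- log_normalize(sim$counts)
    agg <- vapply(names(scores), function(l)
      rowMeans(ln[, sim$sample_to_line == l, drop = FALSE]),
      numeric(nrow(ln)))
    vapply(sim$truth$gene[sim$truth$planted], function(g)
      spearman_rho(agg[g, ], rank(scores))$estimate, numeric(1))
  }))
  expect_lt(mean(abs(rhos)), 0.3)
  expect_error(simulate_counts(scores[1]), class = "viroscore_too_few_lines")
  expect_error(simulate_counts(scores, receptor_genes = c("A", "A")),
               class = "viroscore_duplicate_genes")
})
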