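test_that("one-way ANOVA reproduces the classical decomposition", {
  z <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(z$F, 0)
  expect_equal(z$p, 1)
  z <- one_way_anova(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(z$F, 27, tolerance = 1e-12)
  expect_equal(c(z$df1, z$df2), c(2, 6))
  expect_equal(z$ss_between, 54, tolerance = 1e-12)
  expect_equal(z$ss_within, 6, tolerance = 1e-12)
  expect_equal(z$p, pf(27, 2, 6, lower.tail = FALSE), tolerance = 1e-6)
  # all-constant table convention
  z <- one_way_anova(list(c(2, 2), c(2, 2)))
  expect_equal(c(z$F, z$p), c(0, 1))
  expect_error(one_way_anova(list(1, c(1, 2))), class = "viroscore_too_few_values")
})

test_that("Dunnett with one treatment equals the pooled two-sample t-test", {
  set.seed(21)
  for (i in 1:25) {
    x <- rnorm(sample(3:6, 1)); y <- rnorm(sample(3:6, 1), mean = runif(1, -1, 1))
    d <- dunnett_test(x, list(y))
    tt <- t.test(y, x, var.equal = TRUE)
    expect_lt(abs(d$p_adj - tt$p.value), 1e-6)
    expect_equal(d$p_unadj, tt$p.value, tolerance = 1e-12)
  }
})

test_that("Dunnett adjustment is a proper family-wise correction", {
  set.seed(22)
  ctrl <- rnorm(4)
  trts <- lapply(1:4, function(i) rnorm(3, mean = i / 4))
  d_all <- dunnett_test(ctrl, trts)
  expect_true(all(d_all$p_adj >= d_all$p_unadj - 1e-12))
  # adjusted p is non-decreasing in the number of comparisons for a fixed
  # statistic: evaluate the family-wise tail at the same q
  q <- 2.2
  p_k <- vapply(1:4, function(k) 1 - pdunnett(q, 4, rep(3, k), 9), numeric(1))
  expect_true(all(diff(p_k) > 0))
  # zero observed difference gives the maximal p
  d0 <- dunnett_test(c(1, 2, 3), list(c(1, 2, 3), c(3, 2, 1)))
  expect_equal(d0$p_adj[1], 1)
  # identical constant groups: no variance, no difference
  dc <- dunnett_test(c(2, 2, 2), list(c(2, 2, 2)))
  expect_equal(dc$p_adj, 1)
})

test_that("Dunnett quadrature matches an independent multivariate-t oracle", {
  skip_if_not_installed("mvtnorm")
  n0 <- 4; n <- c(3, 5, 4); df <- sum(c(n0, n)) - 4
  R <- outer(seq_along(n), seq_along(n), function(i, j)
    sqrt(n[i] * n[j] / ((n[i] + n0) * (n[j] + n0))))
  diag(R) <- 1
  for (q in c(1, 2, 3)) {
    set.seed(1)
    oracle <- as.numeric(mvtnorm::pmvt(
      lower = -rep(q, 3), upper = rep(q, 3), df = df, corr = R,
      algorithm = mvtnorm::GenzBretz(abseps = 1e-6, maxpts = 1e6)))
    expect_lt(abs(pdunnett(q, n0, n, df) - oracle), 1e-5)
  }
})

test_that("rank multiplier encodes the lowest significant MOI", {
  expect_equal(lowest_significant_rank(c(0.2, 0.2, 0.2, 0.01, 0.001)), 4L)
  expect_equal(lowest_significant_rank(rep(0.5, 5)), 6L)
  expect_equal(lowest_significant_rank(rep(0.01, 5)), 1L)
  # the threshold is inclusive: p = 0.05 counts as significant
  expect_equal(lowest_significant_rank(c(0.9, 0.9, 0.9, 0.9, 0.05)), 5L)
  expect_error(lowest_significant_rank(numeric(0)), class = "viroscore_empty")
})

test_that("susceptibility score is AUC sum times rank multiplier", {
  expect_equal(susceptibility_score(c(0.9, 0.8, 0.5, 0.3, 0.2), 3), 8.1)
  expect_equal(susceptibility_score(rep(1, 5), 6), 30)
  expect_equal(susceptibility_score(rep(0.1, 5), 1), 0.5)
  expect_error(susceptibility_score(c(0.5, -0.1), 2),
               class = "viroscore_negative_auc")
  # monotone: shrinking any AUC never increases the score
  set.seed(3)
  for (i in 1:20) {
    a <- runif(5); r <- sample(6, 1)
    a2 <- a; j <- sample(5, 1); a2[j] <- a2[j] * runif(1)
    expect_lte(susceptibility_score(a2, r), susceptibility_score(a, r))
  }
})

test_that("cell-line ranking is deterministic with documented tie-breaks", {
  expect_equal(rank_cell_lines(c(A = 8.1, B = 30)), c(A = 1L, B = 2L))
  r <- rank_cell_lines(c(B = 5, A = 5), auc_sums = c(B = 2, A = 2))
  expect_equal(r, c(B = 2L, A = 1L))
  r <- rank_cell_lines(c(B = 5, A = 5), auc_sums = c(B = 1, A = 2))
  expect_equal(r, c(B = 1L, A = 2L))
  s <- c(X = 3, Y = 1, Z = 2)
  expect_equal(rank_cell_lines(s)[names(s)],
               rank_cell_lines(s[c(3, 1, 2)])[names(s)])
})

test_that("type-III two-way ANOVA matches the balanced decomposition", {
  # additive noise-free table: interaction vanishes
  g <- expand.grid(time = factor(1:3), moi = factor(1:4))
  g <- rbind(g, g)
  g$y <- as.numeric(g$time) * 2 + as.numeric(g$moi) * 5
  tab <- two_way_anova_type3(g, "y", "time", "moi")
  expect_lt(tab$ss[tab$effect == "time:moi"], 1e-18)
  # balanced noisy table: type III == classical sequential ANOVA
  set.seed(33)
  g$y <- g$y + rnorm(nrow(g))
  tab <- two_way_anova_type3(g, "y", "time", "moi")
  ref <- anova(lm(y ~ time * moi, data = g))
  expect_equal(tab$ss[1:3], ref$`Sum Sq`[1:3], tolerance = 1e-9)
  expect_equal(tab$F[1:3], ref$`F value`[1:3], tolerance = 1e-6)
  expect_equal(tab$p[1:3], ref$`Pr(>F)`[1:3], tolerance = 1e-6)
  # SS additivity on balanced data
  total <- sum((g$y - mean(g$y))^2)
  expect_equal(sum(tab$ss), total, tolerance = 1e-9 * total)
  # unbalanced complete table: matches the car type-III oracle
  skip_if_not_installed("car")
  gu <- g[-c(1, 5, 6), ]
  tabu <- two_way_anova_type3(gu, "y", "time", "moi")
  fitu <- lm(y ~ time * moi, data = gu,
             contrasts = list(time = "contr.sum", moi = "contr.sum"))
  refu <- car::Anova(fitu, type = 3)
  expect_equal(tabu$ss[1:3], refu[c("time", "moi", "time:moi"), "Sum Sq"],
               tolerance = 1e-9)
  expect_equal(tabu$p[1:3], refu[c("time", "moi", "time:moi"), "Pr(>F)"],
               tolerance = 1e-9)
  # constant table convention
  g$y <- 5
  tab <- two_way_anova_type3(g, "y", "time", "moi")
  expect_equal(tab$p[1:3], rep(1, 3))
  expect_error(two_way_anova_type3(g[g$time == 1, ], "y", "time", "moi"),
               class = "viroscore_single_level")
})

test_that("pairwise adjustments follow their closed forms", {
  set.seed(44)
  grp <- lapply(1:4, function(i) rnorm(5, mean = i / 3))
  lsd <- pairwise_adjust(grp, "fisher_lsd")
  sid <- pairwise_adjust(grp, "sidak")
  tuk <- pairwise_adjust(grp, "tukey")
  m <- nrow(lsd)
  expect_equal(m, 6)
  expect_equal(sid$p_adj, 1 - (1 - lsd$p_unadj)^m, tolerance = 1e-12)
  expect_true(all(tuk$p_adj >= tuk$p_unadj - 1e-12))
  # sidak identity at m = 1
  one <- pairwise_adjust(grp[1:2], "sidak")
  expect_equal(one$p_adj, one$p_unadj, tolerance = 1e-12)
  expect_equal(1 - 0.99^6, 0.0585198506, tolerance = 1e-9)
  expect_error(pairwise_adjust(grp, "bonferroni"))
})

test_that("Tukey adjusted p matches a studentized-range Monte-Carlo oracle", {
  # null: 3 groups of 5; oracle simulates the max studentized range
  k <- 3; n <- 5; df <- k * (n - 1)
  set.seed(55)
  ndraw <- 2e5
  means <- matrix(rnorm(k * ndraw, sd = 1 / sqrt(n)), nrow = k)
  s <- sqrt(rchisq(ndraw, df) / df)
  qstat <- (apply(means, 2, max) - apply(means, 2, min)) / (s / sqrt(n))
  for (q in c(2.5, 3.5)) {
    mc <- mean(qstat >= q)
    expect_lt(abs((1 - ptukey(q, k, df)) - mc), 0.005)
  }
})

test_that("score_cell_lines separates susceptible from null lines", {
  des <- small_design(seed = 9)
  sims <- rbind(simulate_confluence(susceptible_truth("HOT"), des, seed = 9),
                simulate_confluence(null_truth("COLD"), des, seed = 10))
  dr <- score_cell_lines(summarize_auc(sims))
  hot <- dr[dr$cell_line == "HOT", ]
  cold <- dr[dr$cell_line == "COLD", ]
  expect_lt(hot$score, cold$score)
  expect_equal(hot$susceptibility_rank, 1L)
  expect_equal(dr$score, dr$auc_sum * dr$rank_multiplier)
  expect_true(all(dr$rank_multiplier %in% 1:6))
  dn <- attr(dr, "dunnett")
  expect_equal(nrow(dn), 10)
  expect_true(all(dn$p_adj >= 0 & dn$p_adj <= 1))
})
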