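#' One-way analysis of variance on replicate groups
#'
#' Classical between/within decomposition, computed through [stats::lm()].
#' A fully degenerate table (zero between-group and zero residual variance)
#' is reported as F = 0, p = 1 by convention.
#'
#' @param groups list of numeric vectors, one per condition; each needs at
#'   least two finite values.
#' @return list with `F`, `df1`, `df2`, `p`, `ss_between`, `ss_within`.
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))) # F = 27
#' @export
one_way_anova <- function(groups) {
  vs_check(length(groups) >= 2, "viroscore_too_few_groups",
           "ANOVA needs at least 2 groups")
  sizes <- lengths(groups)
  vs_check(all(sizes >= 2), "viroscore_too_few_values",
           "every group needs at least 2 values (sizes: %s)",
           paste(sizes, collapse = ", "))
  y <- unlist(groups, use.names = FALSE)
  vs_check(all(is.finite(y)), "viroscore_nonfinite", "non-finite values in groups")
  df1 <- length(groups) - 1L
  df2 <- length(y) - length(groups)
  # guard the zero-residual cases before handing off to lm/anova
  ssw_direct <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssw_direct <= .Machine$double.eps * max(sum(y^2), 1)) {
    means <- vapply(groups, mean, numeric(1))
    ssb_direct <- sum(sizes * (means - mean(y))^2)
    if (ssb_direct <= .Machine$double.eps * max(sum(y^2), 1)) {
      # all-constant table: nothing to test
      return(list(F = 0, df1 = df1, df2 = df2, p = 1,
                  ss_between = ssb_direct, ss_within = 0))
    }
    return(list(F = Inf, df1 = df1, df2 = df2, p = 0,
                ss_between = ssb_direct, ss_within = 0))
  }
  g <- factor(rep(seq_along(groups), sizes))
  tab <- anova(lm(y ~ g))
  list(F = tab$`F value`[[1]], df1 = tab$Df[[1]], df2 = tab$Df[[2]],
       p = tab$`Pr(>F)`[[1]], ss_between = tab$`Sum Sq`[[1]],
       ss_within = tab$`Sum Sq`[[2]])
}

#' Family-wise distribution function of Dunnett's many-to-one statistics
#'
#' Computes `P(max_j |T_j| <= q)` where `T_j` are the k many-to-one
#' t statistics comparing treatment j (size `n[j]`) against a shared
#' control (size `n0`) with a pooled variance on `df` degrees of freedom.
#' The implied correlation between comparisons is
#' `rho_ij = sqrt(n_i n_j / ((n_i + n0)(n_j + n0)))`.
#'
#' The probability is evaluated by conditioning on the control-group
#' variate and the pooled scale, which reduces the k-dimensional
#' multivariate-t orthant probability to a smooth two-dimensional integral:
#' Gauss-Hermite quadrature over the control variate crossed with
#' Gauss-Legendre quadrature on the quantile-transformed chi distribution
#' of the pooled scale. The default node counts (128 x 256) keep the
#' absolute error below 1e-6 against the univariate t distribution
#' (k = 1, any df from 1 to several thousand) and against multivariate-t
#' reference values for k > 1.
#'
#' @param q non-negative quantile (the common two-sided bound).
#' @param n0 control group size.
#' @param n integer vector of the k treatment group sizes.
#' @param df pooled residual degrees of freedom.
#' @param nodes_z,nodes_u quadrature nodes for the control variate and the
#'   pooled scale.
#' @return probability in \[0, 1\].
#' @export
pdunnett <- function(q, n0, n, df, nodes_z = 128, nodes_u = 256) {
  vs_check(length(n) >= 1, "viroscore_no_treatments", "at least one treatment group required")
  vs_check(df >= 1, "viroscore_bad_df", "pooled df must be >= 1")
  if (q <= 0) return(0)
  gh <- quad_cache("hermite", nodes_z)
  z0 <- sqrt(2) * gh$x                    # control-group variate ~ N(0, 1)
  wz <- gh$w / sqrt(pi)
  gl <- quad_cache("legendre01", nodes_u)
  u <- sqrt(qchisq(gl$x, df) / df)        # pooled scale, S/sigma
  wu <- gl$w
  w <- sqrt(1 / n + 1 / n0)
  Z0 <- matrix(z0 / sqrt(n0), nodes_z, nodes_u)
  U <- matrix(u, nodes_z, nodes_u, byrow = TRUE)
  prod_jk <- matrix(1, nodes_z, nodes_u)
  for (j in seq_along(n)) {
    half <- q * U * w[j]
    prod_jk <- prod_jk *
      (pnorm(sqrt(n[j]) * (Z0 + half)) - pnorm(sqrt(n[j]) * (Z0 - half)))
  }
  min(1, max(0, as.numeric(wz %*% prod_jk %*% wu)))
}

# memoized quadrature rules (node generation dominates small calls)
.quad_env <- new.env(parent = emptyenv())
quad_cache <- function(kind, n) {
  key <- paste0(kind, n)
  if (is.null(.quad_env[[key]])) {
    .quad_env[[key]] <- switch(kind,
      hermite = pracma::gaussHermite(n),
      legendre01 = pracma::gaussLegendre(n, 0, 1))
  }
  .quad_env[[key]]
}

#' Dunnett's many-to-one multiple comparisons test
#'
#' Compares each treatment group against a shared control using pooled-
#' variance t statistics with the single-step Dunnett family-wise
#' adjustment: `p_adj_i = P(max_j |T_j| >= |t_i|)` under the joint null
#' (see [pdunnett()]). With a single treatment the adjusted p equals the
#' ordinary two-sided pooled t-test p-value.
#'
#' @param control numeric vector of control replicate values.
#' @param treatments list of numeric vectors, one per treatment.
#' @return data frame with one row per treatment: `estimate` (mean
#'   difference vs control), `t`, `df`, `p_unadj`, `p_adj`.
#' @export
dunnett_test <- function(control, treatments) {
  vs_check(is.list(treatments) && length(treatments) >= 1, "viroscore_no_treatments",
           "treatments must be a non-empty list of replicate vectors")
  groups <- c(list(control), treatments)
  sizes <- lengths(groups)
  vs_check(all(sizes >= 1) && sum(sizes) - length(groups) >= 1, "viroscore_bad_df",
           "pooled residual df must be >= 1")
  y <- unlist(groups, use.names = FALSE)
  vs_check(all(is.finite(y)), "viroscore_nonfinite", "non-finite replicate values")
  means <- vapply(groups, mean, numeric(1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df <- sum(sizes) - length(groups)
  s2 <- ssw / df
  n0 <- sizes[[1]]
  nt <- sizes[-1]
  est <- means[-1] - means[[1]]
  sedr <- sqrt(s2 * (1 / nt + 1 / n0))
  if (s2 == 0) {
    # no residual variance anywhere: identical data give p = 1, any
    # non-zero difference is degenerate and reported as p = 0
    tstat <- ifelse(est == 0, 0, Inf)
    p_un <- ifelse(est == 0, 1, 0)
    p_ad <- p_un
  } else {
    tstat <- est / sedr
    p_un <- 2 * pt(-abs(tstat), df)
    p_ad <- vapply(abs(tstat), function(ti) {
      if (ti == 0) return(1)
      1 - pdunnett(ti, n0 = n0, n = nt, df = df)
    }, numeric(1))
  }
  data.frame(treatment = seq_along(treatments), estimate = est, t = tstat,
             df = df, p_unadj = p_un, p_adj = pmin(1, p_ad))
}

#' Rank of the lowest MOI with a significant growth difference
#'
#' Encodes the dose-response sensitivity of a cell line as an integer rank
#' multiplier: 1 if the lowest tested MOI already differs significantly
#' from untreated, up to `k` (the number of MOIs, 5 on the standard grid)
#' if only the highest MOI does, and `k + 1` (6) when no MOI reaches
#' significance at all.
#'
#' @param p_adj adjusted p-values ordered by ascending MOI.
#' @param alpha inclusive significance threshold (default 0.05, i.e.
#'   p <= 0.05 counts as significant).
#' @return integer in `1..(length(p_adj) + 1)`.
#' @examples
#' lowest_significant_rank(c(0.2, 0.2, 0.2, 0.01, 0.001)) # 4
#' lowest_significant_rank(rep(0.5, 5))                   # 6
#' @export
lowest_significant_rank <- function(p_adj, alpha = 0.05) {
  vs_check(length(p_adj) >= 1, "viroscore_empty", "p_adj must be non-empty")
  vs_check(all(p_adj >= 0 & p_adj <= 1), "viroscore_bad_p", "p-values must lie in [0, 1]")
  hit <- which(p_adj <= alpha)
  if (length(hit) == 0) length(p_adj) + 1L else as.integer(hit[[1]])
}

#' Composite susceptibility score
#'
#' Sum of the untreated-normalized AUCs across the MOI grid, multiplied by
#' the rank multiplier from [lowest_significant_rank()]. Lower scores mean
#' higher susceptibility to virus-mediated growth inhibition.
#'
#' @param auc_norm unitless treated/untreated AUC ratios, one per MOI.
#' @param rank_multiplier integer from [lowest_significant_rank()].
#' @return unitless score.
#' @examples
#' susceptibility_score(c(0.9, 0.8, 0.5, 0.3, 0.2), 3) # 8.1
#' @export
susceptibility_score <- function(auc_norm, rank_multiplier) {
  vs_check(length(auc_norm) >= 1, "viroscore_empty", "need at least one AUC value")
  vs_check(all(auc_norm >= 0), "viroscore_negative_auc",
           "normalized AUC values must be non-negative")
  vs_check(length(rank_multiplier) == 1 && rank_multiplier >= 1,
           "viroscore_bad_rank", "rank_multiplier must be a single integer >= 1")
  sum(auc_norm) * rank_multiplier
}

#' Rank cell lines from most to least susceptible
#'
#' Rank 1 goes to the smallest susceptibility score. Ties are broken by the
#' smaller AUC sum, then lexicographically by cell-line name, so the
#' ranking is deterministic and invariant to input order.
#'
#' @param scores named numeric vector of susceptibility scores.
#' @param auc_sums optional named numeric vector of AUC sums used as the
#'   first tie-break.
#' @return named integer vector of ranks (a permutation of `1..N`).
#' @export
rank_cell_lines <- function(scores, auc_sums = NULL) {
  vs_check(length(scores) >= 2, "viroscore_too_few_lines",
           "ranking needs at least 2 cell lines")
  vs_check(!is.null(names(scores)) && !anyDuplicated(names(scores)),
           "viroscore_bad_names", "scores must be uniquely named by cell line")
  vs_check(all(is.finite(scores)), "viroscore_nonfinite", "scores must be finite")
  nm <- names(scores)
  tie1 <- if (is.null(auc_sums)) rep(0, length(scores)) else unname(auc_sums[nm])
  ord <- order(scores, tie1, nm)
  ranks <- integer(length(scores))
  ranks[ord] <- seq_along(scores)
  setNames(ranks, nm)
}

#' Per-cell-line dose-response scoring
#'
#' Runs the full scoring procedure on an AUC summary table (from
#' [summarize_auc()]): per cell line, a one-way ANOVA across conditions and
#' Dunnett's test of every MOI against untreated determine the rank
#' multiplier; the sum of mean normalized AUCs times that multiplier is
#' the susceptibility score; lines are then ranked 1 (most susceptible)
#' to N.
#'
#' Biological repeats are the replication unit entering the tests. By
#' default the test operates on the per-repeat mean AUCs (fold-change x h,
#' after baseline normalization), where the untreated condition retains
#' replicate variance; `test_on = "auc_norm"` instead tests the
#' untreated-normalized ratios, in which case the untreated group is
#' identically 1 and contributes no variance.
#'
#' @param auc_summary data frame from [summarize_auc()].
#' @param alpha inclusive significance threshold.
#' @param test_on `"auc_norm"` (default) or `"auc"`.
#' @return data frame with one row per cell line: `auc_sum` (sum over
#'   treated MOIs of the mean normalized AUC), `anova_F`, `anova_p`,
#'   `rank_multiplier`, `score`, `susceptibility_rank`, plus an attribute
#'   `"dunnett"` holding the per-MOI adjusted p-values.
#' @export
score_cell_lines <- function(auc_summary, alpha = 0.05,
                             test_on = c("auc_norm", "auc")) {
  test_on <- match.arg(test_on)
  need <- c("cell_line", "bio_repeat", "moi", "auc_mean", "auc_norm")
  miss <- setdiff(need, names(auc_summary))
  vs_check(length(miss) == 0, "viroscore_schema",
           "missing column(s): %s", paste(miss, collapse = ", "))
  value_col <- if (test_on == "auc") "auc_mean" else "auc_norm"

  per_line <- lapply(split(auc_summary, auc_summary$cell_line), function(d) {
    mois <- sort(unique(d$moi))
    vs_check(0 %in% mois && length(mois) >= 2, "viroscore_no_untreated",
             "cell line %s needs an untreated condition and >= 1 MOI", d$cell_line[[1]])
    treated <- mois[mois > 0]
    grp <- lapply(mois, function(m) d[[value_col]][d$moi == m])
    aov1 <- one_way_anova(grp)
    dt <- dunnett_test(control = grp[[1]], treatments = grp[-1])
    p_adj <- setNames(dt$p_adj, treated)
    mult <- lowest_significant_rank(p_adj, alpha = alpha)
    mean_norm <- vapply(treated, function(m) mean(d$auc_norm[d$moi == m]), numeric(1))
    auc_sum <- sum(mean_norm)
    list(row = data.frame(cell_line = d$cell_line[[1]], auc_sum = auc_sum,
                          anova_F = aov1$F, anova_p = aov1$p,
                          rank_multiplier = mult,
                          score = susceptibility_score(mean_norm, mult)),
         dunnett = data.frame(cell_line = d$cell_line[[1]], moi = treated,
                              auc_norm_mean = mean_norm, p_adj = unname(p_adj)))
  })
  res <- do.call(rbind, lapply(per_line, `[[`, "row"))
  rownames(res) <- NULL
  if (nrow(res) >= 2) {
    ranks <- rank_cell_lines(setNames(res$score, res$cell_line),
                             setNames(res$auc_sum, res$cell_line))
    res$susceptibility_rank <- unname(ranks[res$cell_line])
  } else {
    res$susceptibility_rank <- 1L
  }
  attr(res, "dunnett") <- do.call(rbind, lapply(per_line, `[[`, "dunnett"))
  rownames(attr(res, "dunnett")) <- NULL
  res
}

#' Two-way ANOVA with type-III sums of squares
#'
#' Fixed-effects factorial ANOVA for two crossed factors (typically time
#' and MOI) with their interaction, using sum-to-zero contrasts and
#' type-III (marginal) tests, as a fixed-effects analog of mixed-model
#' software output. Each term's sum of squares is the Wald quadratic form
#' of its coefficient block, `b' [ (X'X)^-1 ]_bb^-1 b`, which for complete
#' balanced data equals the classical two-way decomposition. Noise-free
#' constructed tables (zero residual variance) are reported with the
#' convention F = 0, p = 1 for null effects and p = 0 for non-null ones.
#'
#' @param data data frame containing the response and both factors.
#' @param response name of the numeric response column.
#' @param factor_a,factor_b names of the two factor columns.
#' @return data frame with rows for both main effects, the interaction and
#'   residuals: `effect`, `ss`, `df`, `F`, `p`.
#' @export
two_way_anova_type3 <- function(data, response, factor_a, factor_b) {
  for (cl in c(response, factor_a, factor_b)) {
    vs_check(cl %in% names(data), "viroscore_schema", "missing column %s", cl)
  }
  a <- factor(data[[factor_a]]); b <- factor(data[[factor_b]])
  y <- data[[response]]
  vs_check(all(is.finite(y)), "viroscore_nonfinite", "non-finite response values")
  vs_check(nlevels(a) >= 2 && nlevels(b) >= 2, "viroscore_single_level",
           "both factors need at least 2 levels")
  cells <- table(a, b)
  vs_check(all(cells >= 1), "viroscore_empty_cell",
           "design has empty cells; complete (possibly unbalanced) data required")
  d <- data.frame(y = y, a = a, b = b)
  fit <- lm(y ~ a * b, data = d,
            contrasts = list(a = "contr.sum", b = "contr.sum"))
  X <- model.matrix(fit)
  beta <- coef(fit)
  xtx_inv <- solve(crossprod(X))
  asgn <- attr(X, "assign")            # 0 = intercept, 1 = a, 2 = b, 3 = a:b
  rss <- sum(resid(fit)^2)
  df_res <- fit$df.residual
  ss <- vapply(1:3, function(term) {
    idx <- which(asgn == term)
    bt <- beta[idx]
    as.numeric(t(bt) %*% solve(xtx_inv[idx, idx, drop = FALSE]) %*% bt)
  }, numeric(1))
  df_eff <- vapply(1:3, function(term) sum(asgn == term), numeric(1))
  tol <- 1e-12 * max(sum(y^2), 1)
  if (rss > tol) {
    Fv <- (ss / df_eff) / (rss / df_res)
    p <- stats::pf(Fv, df_eff, df_res, lower.tail = FALSE)
  } else {
    Fv <- ifelse(ss > tol, Inf, 0)
    p <- ifelse(ss > tol, 0, 1)
  }
  out <- data.frame(
    effect = c(factor_a, factor_b, paste0(factor_a, ":", factor_b), "residual"),
    ss = c(ss, rss), df = c(df_eff, df_res),
    F = c(Fv, NA), p = c(p, NA))
  rownames(out) <- NULL
  out
}

#' Pairwise multiple-comparison adjustment
#'
#' All-pairs pooled-variance t comparisons with a choice of adjustment:
#' Sidak (`1 - (1 - p)^m` over the m pairs), Tukey's studentized-range
#' adjustment (via [stats::ptukey()]), or Fisher's unprotected LSD
#' (unadjusted pairwise t with the single pooled variance).
#'
#' @param groups list of numeric replicate vectors (>= 2 groups).
#' @param method `"sidak"`, `"tukey"` or `"fisher_lsd"`.
#' @return data frame with one row per unordered pair: `group1`, `group2`,
#'   `estimate`, `t`, `p_unadj`, `p_adj`.
#' @export
pairwise_adjust <- function(groups, method = c("sidak", "tukey", "fisher_lsd")) {
  method <- match.arg(method)
  k <- length(groups)
  vs_check(k >= 2, "viroscore_too_few_groups", "need at least 2 groups")
  sizes <- lengths(groups)
  vs_check(all(sizes >= 2), "viroscore_too_few_values", "every group needs >= 2 values")
  means <- vapply(groups, mean, numeric(1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df <- sum(sizes) - k
  s2 <- ssw / df
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ])
  out$estimate <- means[out$group2] - means[out$group1]
  se <- sqrt(s2 * (1 / sizes[out$group1] + 1 / sizes[out$group2]))
  out$t <- ifelse(se == 0, ifelse(out$estimate == 0, 0, Inf), out$estimate / se)
  out$p_unadj <- 2 * pt(-abs(out$t), df)
  out$p_adj <- switch(method,
    sidak      = 1 - (1 - out$p_unadj)^m,
    tukey      = 1 - ptukey(abs(out$t) * sqrt(2), nmeans = k, df = df),
    fisher_lsd = out$p_unadj)
  out$p_adj <- pmin(1, pmax(0, out$p_adj))
  out
}
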