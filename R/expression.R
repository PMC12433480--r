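#' Median-of-ratios size factors
#'
#' Per-sample scaling constants for sequencing depth: the reference is the
#' per-gene geometric mean across samples (restricted to genes with
#' strictly positive counts in every sample), and each sample's factor is
#' the median over those genes of its count-to-reference ratio.
#'
#' @param counts non-negative integer matrix, genes in rows, samples in
#'   columns.
#' @return positive numeric vector of length `ncol(counts)`, named by
#'   sample.
#' @examples
#' m <- rbind(gene1 = c(4, 8), gene2 = c(16, 32))
#' size_factors(m) # 1/sqrt(2), sqrt(2)
#' @export
size_factors <- function(counts) {
  vs_check(is.matrix(counts) && ncol(counts) >= 1, "viroscore_bad_matrix",
           "counts must be a genes x samples matrix")
  vs_check(all(counts >= 0) && all(counts == round(counts)), "viroscore_bad_counts",
           "counts must be non-negative integers")
  allpos <- rowSums(counts == 0) == 0
  vs_check(any(allpos), "viroscore_no_reference_genes",
           "no gene has strictly positive counts in all samples; size factors undefined")
  lx <- log(counts[allpos, , drop = FALSE])
  ref <- rowMeans(lx)                     # log geometric mean
  sf <- apply(lx, 2, function(col) exp(median(col - ref)))
  setNames(sf, colnames(counts))
}

#' Depth-normalize and log-transform a count matrix
#'
#' `log2(count / size_factor + 1)`, elementwise.
#'
#' @param counts genes x samples count matrix.
#' @param sf positive per-sample size factors (defaults to
#'   [size_factors()] of `counts`).
#' @param base logarithm base (default 2).
#' @param pseudocount added before the log (default 1, so a zero count
#'   maps to 0).
#' @return matrix of the same shape on the log scale.
#' @export
log_normalize <- function(counts, sf = size_factors(counts), base = 2,
                          pseudocount = 1) {
  vs_check(all(sf > 0) && length(sf) == ncol(counts), "viroscore_bad_size_factors",
           "size factors must be positive, one per sample")
  log(sweep(counts, 2, sf, "/") + pseudocount, base = base)
}

#' Per-gene z-scaling of an expression matrix
#'
#' Each row is centered by its mean and divided by its sample standard
#' deviation (denominator n - 1), the form plotted in expression heatmaps.
#' Constant rows are mapped to all zeros.
#'
#' @param mat numeric matrix, genes in rows.
#' @return matrix of the same shape; every non-constant row has mean 0 and
#'   SD 1.
#' @export
scale_rows <- function(mat) {
  vs_check(is.matrix(mat) && ncol(mat) >= 2, "viroscore_too_few_samples",
           "row scaling needs at least 2 samples")
  mu <- rowMeans(mat)
  s <- apply(mat, 1, sd)
  out <- (mat - mu) / ifelse(s > 0, s, 1)
  out[s == 0, ] <- 0
  out
}

#' Normalize a count matrix end to end
#'
#' Convenience wrapper producing the size factors, the log-normalized
#' matrix and the per-gene scaled (z-score) matrix in one object.
#'
#' @inheritParams log_normalize
#' @return list with `size_factors`, `lognorm`, `scaled`.
#' @export
normalize_expression <- function(counts, base = 2, pseudocount = 1) {
  sf <- size_factors(counts)
  ln <- log_normalize(counts, sf, base = base, pseudocount = pseudocount)
  list(size_factors = sf, lognorm = ln, scaled = scale_rows(ln))
}

#' Spearman rank correlation with exact closed form for untied data
#'
#' Ranks both vectors (midranks for ties) and computes the Pearson
#' correlation of the ranks. For untied data the result additionally
#' satisfies the closed form `1 - 6 * sum(d^2) / (n (n^2 - 1))` exactly,
#' and the integer squared-rank-difference sum is reported.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return list: `estimate`, `n`, `tied` (logical), `sum_sq_rank_diff`
#'   (integer, `NA` when tied).
#' @export
spearman_rho <- function(x, y) {
  n <- length(x)
  vs_check(n == length(y), "viroscore_length_mismatch", "x and y differ in length")
  vs_check(n >= 3, "viroscore_too_few_values", "Spearman needs n >= 3")
  vs_check(all(is.finite(x)) && all(is.finite(y)), "viroscore_nonfinite",
           "non-finite values")
  vs_check(sd(x) > 0 && sd(y) > 0, "viroscore_constant_vector",
           "correlation undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  tied <- anyDuplicated(rx) > 0 || anyDuplicated(ry) > 0
  if (tied) {
    list(estimate = cor(rx, ry), n = n, tied = TRUE, sum_sq_rank_diff = NA_integer_)
  } else {
    d2 <- sum((rx - ry)^2)
    list(estimate = 1 - 6 * d2 / (n * (n^2 - 1)), n = n, tied = FALSE,
         sum_sq_rank_diff = as.integer(d2))
  }
}

# all permutations of 1..n as an n! x n matrix (n <= 8)
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (pos in seq_len(n)) {
    rows <- (pos - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, pos] <- n
    out[rows, -pos] <- sub
  }
  out
}

#' P-value for a Spearman correlation estimate
#'
#' Two-sided p-value for `P(|rho| >= |estimate|)` under the null of
#' exchangeable (untied) rankings. Three methods:
#' \describe{
#'   \item{exact}{full enumeration of all `n!` rank permutations; allowed
#'     for n <= 8.}
#'   \item{montecarlo}{seeded random-permutation sampling; returns the
#'     add-one permutation p-value and its Monte-Carlo standard error.}
#'   \item{t_approx}{`t = r sqrt((n - 2) / (1 - r^2))` referred to a t
#'     distribution on n - 2 degrees of freedom.}
#' }
#'
#' @param estimate Spearman correlation in \[-1, 1\].
#' @param n number of paired observations (>= 3).
#' @param method `"exact"`, `"montecarlo"` or `"t_approx"`.
#' @param n_draws Monte-Carlo draws.
#' @param seed integer seed for `"montecarlo"`.
#' @return list: `p`, `p_method`, and for Monte Carlo `se`.
#' @export
spearman_p <- function(estimate, n, method = c("exact", "montecarlo", "t_approx"),
                       n_draws = 1e5, seed = 1L) {
  method <- match.arg(method)
  vs_check(n >= 3, "viroscore_too_few_values", "Spearman p needs n >= 3")
  vs_check(abs(estimate) <= 1 + 1e-12, "viroscore_bad_estimate",
           "estimate must lie in [-1, 1]")
  tol <- 1e-10
  nf <- n * (n^2 - 1) / 6
  if (method == "exact") {
    vs_check(n <= 8, "viroscore_exact_too_large",
             "exact enumeration limited to n <= 8 (n! permutations); use method = 'montecarlo'")
    perms <- permutations_of(as.integer(n))
    id <- seq_len(n)
    rhos <- 1 - colSums((t(perms) - id)^2) / nf
    list(p = mean(abs(rhos) >= abs(estimate) - tol), p_method = "exact")
  } else if (method == "montecarlo") {
    set.seed(seed)
    id <- seq_len(n)
    hits <- sum(vapply(seq_len(n_draws), function(i) {
      abs(1 - sum((sample.int(n) - id)^2) / nf) >= abs(estimate) - tol
    }, logical(1)))
    p <- (1 + hits) / (1 + n_draws)
    list(p = p, p_method = "montecarlo", se = sqrt(p * (1 - p) / n_draws))
  } else {
    r <- max(-1, min(1, estimate))
    if (abs(r) == 1) return(list(p = 0, p_method = "t_approx"))
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    list(p = 2 * pt(-abs(tstat), df = n - 2), p_method = "t_approx")
  }
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length (n >= 3), neither constant.
#' @return list: `estimate`, `n`.
#' @export
pearson_r <- function(x, y) {
  n <- length(x)
  vs_check(n == length(y), "viroscore_length_mismatch", "x and y differ in length")
  vs_check(n >= 3, "viroscore_too_few_values", "Pearson needs n >= 3")
  vs_check(sd(x) > 0 && sd(y) > 0, "viroscore_constant_vector",
           "correlation undefined for a constant vector")
  list(estimate = cor(x, y), n = n)
}

#' Correlate gene expression with the susceptibility ranking
#'
#' For each requested gene, log-normalized expression is averaged over a
#' cell line's replicate samples and correlated against the line's
#' susceptibility rank (1 = most susceptible), by Spearman and optionally
#' Pearson. A gene with identical aggregated expression across all lines
#' has no defined correlation and is flagged instead of dropped.
#'
#' @param lognorm genes x samples log-normalized matrix (from
#'   [normalize_expression()]).
#' @param sample_to_line named character vector mapping sample -> cell
#'   line, covering every column of `lognorm`.
#' @param ranks named integer vector of susceptibility ranks per line
#'   (from [rank_cell_lines()] / [score_cell_lines()]).
#' @param genes gene names to test (default: all rows).
#' @param methods subset of `c("spearman", "pearson")`.
#' @param p_method passed to [spearman_p()]; `"auto"` picks exact
#'   enumeration for n <= 8 and the t approximation otherwise.
#' @param add_bh add a Benjamini-Hochberg adjusted column per method.
#' @param seed seed for a Monte-Carlo `p_method`.
#' @return data frame sorted by estimate: `gene`, `method`, `estimate`,
#'   `n`, `sum_sq_rank_diff`, `p`, `p_method`, `undefined`, and `p_bh`
#'   when requested.
#' @export
correlate_with_susceptibility <- function(lognorm, sample_to_line, ranks,
                                          genes = rownames(lognorm),
                                          methods = c("spearman", "pearson"),
                                          p_method = c("auto", "exact",
                                                       "montecarlo", "t_approx"),
                                          add_bh = FALSE, seed = 1L) {
  p_method <- match.arg(p_method)
  methods <- match.arg(methods, several.ok = TRUE)
  vs_check(all(colnames(lognorm) %in% names(sample_to_line)), "viroscore_unmapped_sample",
           "every sample column must appear in sample_to_line")
  absent <- setdiff(genes, rownames(lognorm))
  vs_check(length(absent) == 0, "viroscore_gene_absent",
           "gene(s) absent from matrix: %s", paste(absent, collapse = ", "))
  lines <- sort(names(ranks))
  vs_check(length(lines) >= 4, "viroscore_too_few_lines",
           "correlation against ranks needs >= 4 cell lines")
  line_of <- sample_to_line[colnames(lognorm)]
  vs_check(all(lines %in% line_of), "viroscore_missing_line",
           "every ranked line needs at least one sample")
  # aggregate replicate samples by mean per line, in a fixed line order
  agg <- vapply(lines, function(l) {
    rowMeans(lognorm[, line_of == l, drop = FALSE])
  }, numeric(nrow(lognorm)))
  if (is.null(dim(agg))) agg <- matrix(agg, nrow = 1, dimnames = list(rownames(lognorm), lines))
  rk <- as.numeric(ranks[lines])
  n <- length(lines)
  eff_p <- if (p_method == "auto") { if (n <= 8) "exact" else "t_approx" } else p_method

  rows <- list()
  for (g in genes) {
    expr <- agg[g, ]
    undef <- sd(expr) == 0
    for (m in methods) {
      if (undef) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, method = m, estimate = NA_real_, n = n,
          sum_sq_rank_diff = NA_integer_, p = NA_real_,
          p_method = NA_character_, undefined = TRUE)
      } else if (m == "spearman") {
        sr <- spearman_rho(expr, rk)
        sp <- spearman_p(sr$estimate, n, method = eff_p, seed = seed)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, method = "spearman", estimate = sr$estimate, n = n,
          sum_sq_rank_diff = sr$sum_sq_rank_diff, p = sp$p,
          p_method = sp$p_method, undefined = FALSE)
      } else {
        pr <- pearson_r(expr, rk)
        pp <- spearman_p(pr$estimate, n, method = "t_approx")
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, method = "pearson", estimate = pr$estimate, n = n,
          sum_sq_rank_diff = NA_integer_, p = pp$p,
          p_method = "t_approx", undefined = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (add_bh) {
    out$p_bh <- NA_real_
    for (m in unique(out$method)) {
      sel <- out$method == m & !out$undefined
      out$p_bh[sel] <- p.adjust(out$p[sel], method = "BH")
    }
  }
  out <- out[order(out$method, out$estimate), ]
  rownames(out) <- NULL
  out
}
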