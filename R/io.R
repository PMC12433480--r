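vs_log <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Read a long-format well time-series CSV
#'
#' Expected columns: `cell_line`, `treatment`, `moi`, `repeat`,
#' `replicate`, `time_h`, `confluence_pct`, optionally `dead_per_mm2`.
#' Rows with confluence outside \[0, 100\] are rejected with a warning
#' naming the rows; duplicated (well, time) rows and non-numeric fields
#' are errors. The `repeat` column (a reserved word in R) is returned as
#' `bio_repeat`.
#'
#' @param path CSV path (UTF-8, header required).
#' @return validated long data frame sorted by well and time.
#' @export
read_timeseries_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("cell_line", "treatment", "moi", "repeat", "replicate", "time_h",
            "confluence_pct")
  miss <- setdiff(need, names(df))
  vs_check(length(miss) == 0, "viroscore_schema",
           "time-series file %s is missing column(s): %s", path,
           paste(miss, collapse = ", "))
  names(df)[names(df) == "repeat"] <- "bio_repeat"
  for (cl in c("moi", "time_h", "confluence_pct")) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    vs_check(!anyNA(v), "viroscore_bad_field", "non-numeric values in column %s", cl)
    df[[cl]] <- v
  }
  if ("dead_per_mm2" %in% names(df)) {
    v <- suppressWarnings(as.numeric(df$dead_per_mm2))
    vs_check(!anyNA(v), "viroscore_bad_field", "non-numeric values in column dead_per_mm2")
    df$dead_per_mm2 <- v
  }
  bad <- which(df$confluence_pct < 0 | df$confluence_pct > 100)
  if (length(bad) > 0) {
    warning(sprintf("rejected %d row(s) with confluence outside [0, 100]: rows %s",
                    length(bad), paste(head(bad, 10), collapse = ", ")))
    df <- df[-bad, , drop = FALSE]
  }
  key <- paste(df$cell_line, df$moi, df$bio_repeat, df$replicate, df$time_h)
  dup <- which(duplicated(key))
  vs_check(length(dup) == 0, "viroscore_duplicate_rows",
           "duplicated (well, time) row(s): rows %s", paste(head(dup, 10), collapse = ", "))
  df <- df[order(df$cell_line, df$moi, df$bio_repeat, df$replicate, df$time_h), ]
  rownames(df) <- NULL
  df
}

#' Write a well time-series data frame to CSV
#'
#' Inverse of [read_timeseries_csv()]: emits the on-disk schema
#' (`repeat` column name, a `treatment` label derived from the MOI when
#' absent).
#'
#' @param df long data frame with a `bio_repeat` column.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(df, path) {
  out <- df
  if (!"treatment" %in% names(out)) {
    out$treatment <- ifelse(out$moi > 0, "virus", "untreated")
  }
  names(out)[names(out) == "bio_repeat"] <- "repeat"
  first <- c("cell_line", "treatment", "moi", "repeat", "replicate", "time_h",
             "confluence_pct")
  out <- out[, c(first, setdiff(names(out), first)), drop = FALSE]
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene x sample count matrix from TSV plus a sample map
#'
#' The TSV's first column holds gene names, remaining columns one sample
#' each; the sample map is a CSV with columns `sample`, `cell_line`.
#' Counts must be non-negative integers; duplicate gene names and samples
#' missing from the map are errors.
#'
#' @param path counts TSV.
#' @param sample_map_path sample map CSV.
#' @return list: `counts` (integer matrix), `sample_to_line` (named
#'   character vector).
#' @export
read_counts_tsv <- function(path, sample_map_path) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  vs_check(ncol(raw) >= 2, "viroscore_schema",
           "counts file needs a gene column plus >= 1 sample column")
  genes <- as.character(raw[[1]])
  vs_check(!anyDuplicated(genes), "viroscore_duplicate_genes",
           "duplicate gene name(s): %s",
           paste(unique(genes[duplicated(genes)]), collapse = ", "))
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  vs_check(!anyNA(m), "viroscore_bad_field", "non-numeric counts")
  vs_check(all(m >= 0) && all(m == round(m)), "viroscore_bad_counts",
           "counts must be non-negative integers")
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  map <- read.csv(sample_map_path, stringsAsFactors = FALSE)
  vs_check(all(c("sample", "cell_line") %in% names(map)), "viroscore_schema",
           "sample map needs columns sample, cell_line")
  unmapped <- setdiff(colnames(m), map$sample)
  vs_check(length(unmapped) == 0, "viroscore_unmapped_sample",
           "sample(s) absent from map: %s", paste(unmapped, collapse = ", "))
  list(counts = m,
       sample_to_line = setNames(map$cell_line, map$sample)[colnames(m)])
}

#' Read a count matrix in MatrixMarket triplet form
#'
#' @param mtx_path MTX file; @param genes_path,samples_path one name per
#'   line; @param sample_map_path as in [read_counts_tsv()].
#' @return as [read_counts_tsv()].
#' @export
read_counts_mtx <- function(mtx_path, genes_path, samples_path, sample_map_path) {
  vs_check(requireNamespace("Matrix", quietly = TRUE), "viroscore_missing_dep",
           "the Matrix package is required for MTX input")
  m <- as.matrix(Matrix::readMM(mtx_path))
  genes <- readLines(genes_path)
  samples <- readLines(samples_path)
  vs_check(nrow(m) == length(genes) && ncol(m) == length(samples),
           "viroscore_schema", "MTX dimensions do not match gene/sample files")
  vs_check(!anyDuplicated(genes), "viroscore_duplicate_genes", "duplicate gene names")
  vs_check(all(m >= 0) && all(m == round(m)), "viroscore_bad_counts",
           "counts must be non-negative integers")
  storage.mode(m) <- "integer"
  dimnames(m) <- list(genes, samples)
  map <- read.csv(sample_map_path, stringsAsFactors = FALSE)
  unmapped <- setdiff(samples, map$sample)
  vs_check(length(unmapped) == 0, "viroscore_unmapped_sample",
           "sample(s) absent from map: %s", paste(unmapped, collapse = ", "))
  list(counts = m, sample_to_line = setNames(map$cell_line, map$sample)[samples])
}

#' Pipeline configuration
#'
#' @param timeseries path to the long confluence CSV.
#' @param counts path to the counts TSV.
#' @param sample_map path to the sample map CSV.
#' @param out_dir output directory (created if absent).
#' @param alpha inclusive significance threshold in (0, 1).
#' @param baseline_mode `"divide"` or `"subtract"`.
#' @param test_on which AUC variable enters the Dunnett test (see
#'   [score_cell_lines()]).
#' @param p_method Spearman p-value method (see
#'   [correlate_with_susceptibility()]).
#' @param genes genes to correlate (default: all).
#' @param add_bh add a Benjamini-Hochberg column.
#' @param seed integer seed for stochastic p-value methods.
#' @param verbose log stage progress to standard error.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(timeseries, counts, sample_map, out_dir,
                            alpha = 0.05, baseline_mode = "divide",
                            test_on = "auc_norm", p_method = "auto", genes = NULL,
                            add_bh = FALSE, seed = 1L, verbose = FALSE) {
  vs_check(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1,
           "viroscore_bad_config", "alpha must lie in (0, 1), got %g", alpha)
  vs_check(baseline_mode %in% c("divide", "subtract"), "viroscore_bad_config",
           "unknown baseline_mode %s", baseline_mode)
  vs_check(test_on %in% c("auc", "auc_norm"), "viroscore_bad_config",
           "unknown test_on %s", test_on)
  vs_check(p_method %in% c("auto", "exact", "montecarlo", "t_approx"),
           "viroscore_bad_config", "unknown p_method %s", p_method)
  vs_check(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
           "viroscore_bad_config", "seed must be a single integer")
  structure(list(timeseries = timeseries, counts = counts,
                 sample_map = sample_map, out_dir = out_dir, alpha = alpha,
                 baseline_mode = baseline_mode, test_on = test_on,
                 p_method = p_method, genes = genes, add_bh = add_bh,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Run the susceptibility pipeline end to end
#'
#' growth kinetics (AUC summaries) -> dose-response scoring and ranking ->
#' expression normalization and rank correlation. Writes four artifacts to
#' `out_dir`: `dose_response.csv` (one row per cell line),
#' `ranking.csv`, `correlations.csv`, and `manifest.json` (config, seed,
#' package version, row counts), and returns the in-memory results.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list: `auc_summary`, `dose_response`, `ranking`,
#'   `correlations`, `manifest`, `paths`.
#' @export
run_pipeline <- function(config) {
  vs_check(inherits(config, "pipeline_config"), "viroscore_bad_config",
           "config must come from pipeline_config()")
  v <- config$verbose
  stage <- "growth_kinetics"
  res <- tryCatch({
    vs_log(v, stage, "reading %s", config$timeseries)
    wells <- read_timeseries_csv(config$timeseries)
    aucs <- summarize_auc(wells, baseline_mode = config$baseline_mode)

    stage <- "dose_response"
    vs_log(v, stage, "scoring %d cell line(s)", length(unique(aucs$cell_line)))
    dr <- score_cell_lines(aucs, alpha = config$alpha, test_on = config$test_on)
    ranking <- dr[order(dr$susceptibility_rank),
                  c("cell_line", "score", "auc_sum", "rank_multiplier",
                    "susceptibility_rank")]

    stage <- "expression"
    vs_log(v, stage, "reading %s", config$counts)
    cm <- read_counts_tsv(config$counts, config$sample_map)
    norm <- normalize_expression(cm$counts)
    ranks <- setNames(dr$susceptibility_rank, dr$cell_line)
    genes <- if (is.null(config$genes)) rownames(norm$lognorm) else config$genes
    corr <- correlate_with_susceptibility(
      norm$lognorm, cm$sample_to_line, ranks, genes = genes,
      p_method = config$p_method, add_bh = config$add_bh, seed = config$seed)

    list(auc_summary = aucs, dose_response = dr, ranking = ranking,
         correlations = corr, expression = norm)
  }, viroscore_error = function(e) {
    message(sprintf("[%s] FAILED: %s", stage, conditionMessage(e)))
    stop(e)
  })

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    dose_response = file.path(config$out_dir, "dose_response.csv"),
    ranking = file.path(config$out_dir, "ranking.csv"),
    correlations = file.path(config$out_dir, "correlations.csv"),
    manifest = file.path(config$out_dir, "manifest.json"))
  write.csv(res$dose_response, paths$dose_response, row.names = FALSE, quote = FALSE)
  write.csv(res$ranking, paths$ranking, row.names = FALSE, quote = FALSE)
  write.csv(res$correlations, paths$correlations, row.names = FALSE, quote = FALSE)
  manifest <- list(
    config = unclass(config)[c("timeseries", "counts", "sample_map", "alpha",
                               "baseline_mode", "test_on", "p_method",
                               "add_bh", "seed")],
    package_version = as.character(utils::packageVersion("viroscore")),
    rows = list(timeseries = nrow(res$auc_summary),
                dose_response = nrow(res$dose_response),
                correlations = nrow(res$correlations)))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  vs_log(v, "report", "wrote %s", config$out_dir)
  res$manifest <- manifest
  res$paths <- paths
  invisible(res)
}
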