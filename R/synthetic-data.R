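#' Ground-truth parameters of a simulated cell line
#'
#' Parameterizes the growth/killing mechanism used by the simulators:
#' logistic growth (rate `g`, carrying capacity `K`, initial confluence
#' `C0`) minus a Hill-type, MOI-dependent kill term
#' `k(m) = kmax * m^hill / (m^hill + m50^hill)` that switches on after a
#' delay `tau`. A line with `kmax = 0` is a true null: no MOI has any
#' effect, by construction.
#'
#' @param name cell-line label.
#' @param g intrinsic growth rate (1/h, > 0).
#' @param K carrying capacity (confluence %, <= 100).
#' @param C0 initial confluence (%), `0 < C0 < K`.
#' @param kmax maximal kill rate (1/h, >= 0).
#' @param m50 MOI of half-maximal killing (PFU/cell, > 0).
#' @param hill Hill coefficient (> 0).
#' @param tau killing onset delay (h, >= 0).
#' @param beta FLT3L secretion coefficient (pg/mL per unit of killed
#'   biomass x h).
#' @param sigma multiplicative (log-scale) measurement noise SD (>= 0).
#' @return object of class `cell_line_truth`.
#' @export
cell_line_truth <- function(name, g = 0.05, K = 95, C0 = 5, kmax = 0,
                            m50 = 0.1, hill = 1.5, tau = 24, beta = 1,
                            sigma = 0.05) {
  vs_check(is.character(name) && nchar(name) > 0, "viroscore_bad_truth", "name required")
  vs_check(is.finite(g) && g > 0, "viroscore_bad_truth", "g must be > 0")
  vs_check(is.finite(K) && K <= 100 && K > 0, "viroscore_bad_truth", "K must be in (0, 100]")
  vs_check(is.finite(C0) && C0 > 0 && C0 < K, "viroscore_bad_truth", "need 0 < C0 < K")
  vs_check(is.finite(kmax) && kmax >= 0, "viroscore_bad_truth", "kmax must be >= 0")
  vs_check(is.finite(m50) && m50 > 0, "viroscore_bad_truth", "m50 must be > 0")
  vs_check(is.finite(hill) && hill > 0, "viroscore_bad_truth", "hill must be > 0")
  vs_check(is.finite(tau) && tau >= 0, "viroscore_bad_truth", "tau must be >= 0")
  vs_check(is.finite(beta) && beta >= 0, "viroscore_bad_truth", "beta must be >= 0")
  vs_check(is.finite(sigma) && sigma >= 0, "viroscore_bad_truth", "sigma must be >= 0")
  structure(list(name = name, g = g, K = K, C0 = C0, kmax = kmax, m50 = m50,
                 hill = hill, tau = tau, beta = beta, sigma = sigma),
            class = "cell_line_truth")
}

#' Simulation design: sampling grid and replication
#'
#' The default mirrors the live-cell-imaging study layout: confluence read
#' every 2 h up to 170 h, an MOI grid of 0.001, 0.01, 0.1, 1 and 10
#' PFU/cell plus an untreated (MOI 0) condition, triplicate wells, and 3
#' biological repeats.
#'
#' @param moi_grid MOI values including 0 (untreated) exactly once.
#' @param t_end horizon (h), a multiple of `dt`.
#' @param dt sampling interval (h, > 0).
#' @param n_wells technical replicate wells per condition.
#' @param n_repeats biological repeats.
#' @param seed integer seed.
#' @param n_sub Euler refinement: integration substeps per sampling
#'   interval.
#' @return object of class `simulation_design`.
#' @export
simulation_design <- function(moi_grid = c(0, 0.001, 0.01, 0.1, 1, 10),
                              t_end = 170, dt = 2, n_wells = 3,
                              n_repeats = 3, seed = 1L, n_sub = 10L) {
  vs_check(dt > 0, "viroscore_bad_design", "dt must be > 0")
  vs_check(dt < t_end, "viroscore_bad_design", "dt must be smaller than t_end")
  vs_check(abs(t_end / dt - round(t_end / dt)) < 1e-9, "viroscore_bad_design",
           "t_end must be a multiple of dt")
  vs_check(sum(moi_grid == 0) == 1, "viroscore_bad_design",
           "moi_grid must contain 0 (untreated) exactly once")
  vs_check(all(is.finite(moi_grid)) && all(moi_grid >= 0), "viroscore_bad_design",
           "MOIs must be finite and non-negative")
  vs_check(n_wells >= 1 && n_repeats >= 1, "viroscore_bad_design",
           "n_wells and n_repeats must be >= 1")
  vs_check(n_sub >= 1, "viroscore_bad_design", "n_sub must be >= 1")
  structure(list(moi_grid = sort(moi_grid), t_end = t_end, dt = dt,
                 n_wells = as.integer(n_wells), n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed), n_sub = as.integer(n_sub)),
            class = "simulation_design")
}

# MOI-dependent kill rate (1/h); exactly 0 at m = 0
kill_rate <- function(truth, m) {
  if (m <= 0) return(0)
  truth$kmax * m^truth$hill / (m^truth$hill + truth$m50^truth$hill)
}

# Noise-free trajectory on the sampling grid: confluence C(t) and the
# cumulative kill integral Q(t) = int_0^t k(m) C(s) 1[s > tau] ds
noise_free_trajectory <- function(truth, design, moi) {
  times <- seq(0, design$t_end, by = design$dt)
  k <- kill_rate(truth, moi)
  h <- design$dt / design$n_sub
  n_fine <- design$n_sub * (length(times) - 1L)
  C <- numeric(length(times)); Q <- numeric(length(times))
  C[[1]] <- truth$C0
  c_cur <- truth$C0; q_cur <- 0; t_cur <- 0
  for (i in seq_len(n_fine)) {
    active <- t_cur > truth$tau
    dC <- truth$g * c_cur * (1 - c_cur / truth$K) - (if (active) k * c_cur else 0)
    if (active) q_cur <- q_cur + h * k * c_cur
    c_cur <- max(0, c_cur + h * dC)
    t_cur <- t_cur + h
    if (i %% design$n_sub == 0) {
      idx <- i %/% design$n_sub + 1L
      C[[idx]] <- c_cur
      Q[[idx]] <- q_cur
    }
  }
  list(times = times, confluence = C, kill_integral = Q)
}

# shared well-level noise wrapper: one long block per (moi, repeat, well)
simulate_well_table <- function(truth, design, seed, with_dead) {
  set.seed(seed)
  traj <- lapply(design$moi_grid, function(m) noise_free_trajectory(truth, design, m))
  names(traj) <- as.character(design$moi_grid)
  nt <- length(traj[[1]]$times)
  rows <- vector("list", length(design$moi_grid) * design$n_repeats * design$n_wells)
  i <- 0L
  for (m in design$moi_grid) {
    tr <- traj[[as.character(m)]]
    for (r in seq_len(design$n_repeats)) {
      for (wl in seq_len(design$n_wells)) {
        i <- i + 1L
        conf <- tr$confluence * exp(rnorm(nt, 0, truth$sigma))
        conf <- pmin(100, pmax(0, conf))
        block <- data.frame(cell_line = truth$name, moi = m, bio_repeat = r,
                            replicate = wl, time_h = tr$times,
                            confluence_pct = conf)
        if (with_dead) {
          dead <- tr$kill_integral * exp(rnorm(nt, 0, truth$sigma))
          block$dead_per_mm2 <- pmax(0, dead)
        }
        rows[[i]] <- block
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate confluence time series for one cell line
#'
#' Euler-discretized logistic growth minus delayed Hill-type killing,
#' `C'(t) = g C (1 - C/K) - k(m) C 1[t > tau]`, integrated on a refined
#' grid (`n_sub` substeps per sampling interval) and reported on the
#' sampling grid with per-timepoint multiplicative lognormal noise,
#' clipped to \[0, 100\] %. Identical `(truth, design, seed)` give
#' bit-identical tables.
#'
#' @param truth a [cell_line_truth()].
#' @param design a [simulation_design()].
#' @param seed seed (defaults to `design$seed`).
#' @return long data frame: `cell_line`, `moi`, `bio_repeat`, `replicate`,
#'   `time_h`, `confluence_pct`.
#' @export
simulate_confluence <- function(truth, design, seed = design$seed) {
  vs_check(inherits(truth, "cell_line_truth"), "viroscore_bad_truth",
           "truth must come from cell_line_truth()")
  vs_check(inherits(design, "simulation_design"), "viroscore_bad_design",
           "design must come from simulation_design()")
  simulate_well_table(truth, design, seed, with_dead = FALSE)
}

#' Simulate cytotoxicity (dead-cell density) time series
#'
#' Dead-cell density is the accumulated killed biomass,
#' `D(t) = gamma * int_0^t k(m) C(s) ds` with the area-conversion constant
#' `gamma` fixed at 1 cell/mm^2 per % confluence killed (the arbitrary
#' scale cancels in downstream normalization). Emitted on the same grid as
#' confluence, with the confluence column included so the death index can
#' be formed directly. Noise-free `D` is non-decreasing in time and
#' pointwise non-decreasing in MOI.
#'
#' @inheritParams simulate_confluence
#' @return long data frame as [simulate_confluence()] plus `dead_per_mm2`.
#' @export
simulate_cytotox <- function(truth, design, seed = design$seed) {
  vs_check(inherits(truth, "cell_line_truth"), "viroscore_bad_truth",
           "truth must come from cell_line_truth()")
  vs_check(inherits(design, "simulation_design"), "viroscore_bad_design",
           "design must come from simulation_design()")
  simulate_well_table(truth, design, seed, with_dead = TRUE)
}

#' Simulate secreted FLT3L concentrations
#'
#' Secreted transgene concentration is proportional to the killed biomass:
#' `F(t) = beta * int_0^t k(m) C(s) ds`, sampled at the requested
#' timepoints with multiplicative replicate noise. Untreated wells (and
#' any line with `beta = 0` or `kmax = 0`) are exactly 0 before noise, and
#' noise-free concentrations are non-decreasing in time.
#'
#' @inheritParams simulate_confluence
#' @param timepoints sampling times (h); must lie on the design grid.
#' @return long data frame: `cell_line`, `moi`, `bio_repeat`, `replicate`,
#'   `time_h`, `concentration`.
#' @export
simulate_flt3l <- function(truth, design, timepoints = c(8, 24, 48, 72, 120),
                           seed = design$seed) {
  vs_check(inherits(truth, "cell_line_truth"), "viroscore_bad_truth",
           "truth must come from cell_line_truth()")
  grid <- seq(0, design$t_end, by = design$dt)
  off <- setdiff(timepoints, grid)
  vs_check(length(off) == 0, "viroscore_off_grid",
           "timepoint(s) not on the sampling grid: %s", paste(off, collapse = ", "))
  set.seed(seed)
  rows <- list()
  for (m in design$moi_grid) {
    tr <- noise_free_trajectory(truth, design, m)
    f <- truth$beta * tr$kill_integral[match(timepoints, tr$times)]
    for (r in seq_len(design$n_repeats)) {
      for (wl in seq_len(design$n_wells)) {
        conc <- pmax(0, f * exp(rnorm(length(f), 0, truth$sigma)))
        rows[[length(rows) + 1L]] <- data.frame(
          cell_line = truth$name, moi = m, bio_repeat = r, replicate = wl,
          time_h = timepoints, concentration = conc)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default panel of simulated cell lines
#'
#' Eleven lines spanning the susceptibility spectrum, from strong killing
#' at sub-0.01 MOIs down to a complete null (`kmax = 0`), with mild
#' variation in growth parameters.
#'
#' @param sigma measurement noise SD applied to every line.
#' @return list of [cell_line_truth()] objects.
#' @export
default_truth_panel <- function(sigma = 0.05) {
  kmax <- c(0.20, 0.16, 0.12, 0.09, 0.07, 0.05, 0.035, 0.02, 0.012, 0.006, 0)
  m50  <- c(0.003, 0.005, 0.01, 0.03, 0.05, 0.1, 0.3, 0.8, 2, 5, 1)
  g    <- seq(0.04, 0.06, length.out = 11)
  C0   <- rep(c(5, 8, 10), length.out = 11)
  mapply(function(i) {
    cell_line_truth(name = sprintf("CL%02d", i), g = g[[i]], K = 95,
                    C0 = C0[[i]], kmax = kmax[[i]], m50 = m50[[i]],
                    hill = 1.5, tau = 24, beta = 1, sigma = sigma)
  }, seq_len(11), SIMPLIFY = FALSE)
}

#' Export a truth panel as a table
#'
#' @param truths list of [cell_line_truth()] objects.
#' @return data frame with one row per cell line.
#' @export
truth_table <- function(truths) {
  do.call(rbind, lapply(truths, function(tr) as.data.frame(unclass(tr))))
}

#' Simulate an RNA-seq count matrix with planted susceptibility effects
#'
#' Negative-binomial counts for `n_genes` background genes plus a named
#' set of "receptor" genes whose mean expression decreases with the
#' susceptibility score: for receptor genes the per-line log2 mean is
#' `b0 - b1 * z(score)` (so that more susceptible lines — lower scores —
#' express more), while background genes draw a score-independent base
#' mean. Per-sample depth factors are lognormal
#' (`meanlog = 0`, `sdlog = depth_sd`) so that size-factor estimation is
#' exercised.
#'
#' @param scores named numeric vector of susceptibility scores (>= 2
#'   lines, unique names).
#' @param n_genes number of background genes.
#' @param receptor_genes character names of the planted genes.
#' @param b1 planted effect size (log2 units per score SD).
#' @param b0 receptor-gene baseline log2 mean.
#' @param dispersion NB dispersion (rnbinom `size = 1/dispersion`).
#' @param n_reps replicate samples per cell line.
#' @param depth_sd lognormal SD of the per-sample depth factors.
#' @param seed integer seed.
#' @return list: `counts` (genes x samples integer matrix),
#'   `sample_to_line` (named character), `truth` (data frame: gene,
#'   planted, log2 effect per score SD).
#' @export
simulate_counts <- function(scores, n_genes = 500,
                            receptor_genes = c("NECTIN1", "NECTIN2",
                                               "TNFRSF14", "ITGB6"),
                            b1 = 2, b0 = 8, dispersion = 0.1, n_reps = 3,
                            depth_sd = 0.2, seed = 1L) {
  vs_check(length(scores) >= 2, "viroscore_too_few_lines",
           "need at least 2 cell lines")
  vs_check(!is.null(names(scores)) && !anyDuplicated(names(scores)),
           "viroscore_bad_names", "scores must be uniquely named")
  vs_check(!anyDuplicated(receptor_genes), "viroscore_duplicate_genes",
           "duplicate receptor gene names")
  vs_check(n_genes >= length(receptor_genes), "viroscore_bad_inputs",
           "n_genes must be >= number of receptor genes")
  set.seed(seed)
  lines <- names(scores)
  z <- as.numeric(scale(scores))
  bg_names <- sprintf("BG%04d", seq_len(n_genes))
  genes <- c(receptor_genes, bg_names)
  samples <- as.vector(t(outer(lines, seq_len(n_reps), paste, sep = "_rep")))
  line_of <- rep(lines, each = n_reps)
  depth <- exp(rnorm(length(samples), 0, depth_sd))
  bg_base <- runif(n_genes, 3, 10)
  n_rec <- length(receptor_genes)
  log2mu <- rbind(
    matrix(b0, n_rec, length(lines)) -
      matrix(b1 * z, n_rec, length(lines), byrow = TRUE),
    matrix(bg_base, n_genes, length(lines)))
  mu_sample <- 2^log2mu[, match(line_of, lines), drop = FALSE] *
    matrix(depth, nrow = length(genes), ncol = length(samples), byrow = TRUE)
  counts <- matrix(rnbinom(length(mu_sample), mu = as.vector(mu_sample),
                           size = 1 / dispersion),
                   nrow = length(genes),
                   dimnames = list(genes, samples))
  list(counts = counts,
       sample_to_line = setNames(line_of, samples),
       truth = data.frame(gene = genes,
                          planted = genes %in% receptor_genes,
                          effect = ifelse(genes %in% receptor_genes, -b1, 0)))
}

#' Simulate a full multi-line study bundle
#'
#' Runs the confluence, cytotoxicity and FLT3L simulators for every line
#' in a truth panel, with per-line seeds derived from the design seed.
#'
#' @param truths list of [cell_line_truth()] (default
#'   [default_truth_panel()]).
#' @param design a [simulation_design()].
#' @param flt3l_timepoints passed to [simulate_flt3l()].
#' @return list: `confluence`, `cytotox`, `flt3l` (long data frames over
#'   all lines), `truth` (the truth table).
#' @export
simulate_study <- function(truths = default_truth_panel(),
                           design = simulation_design(),
                           flt3l_timepoints = c(8, 24, 48, 72, 120)) {
  flt3l_timepoints <- flt3l_timepoints[flt3l_timepoints <= design$t_end]
  conf <- list(); cyto <- list(); fl <- list()
  for (i in seq_along(truths)) {
    sd_i <- design$seed + 1000L * i
    conf[[i]] <- simulate_confluence(truths[[i]], design, seed = sd_i)
    cyto[[i]] <- simulate_cytotox(truths[[i]], design, seed = sd_i + 1L)
    fl[[i]] <- simulate_flt3l(truths[[i]], design, flt3l_timepoints,
                              seed = sd_i + 2L)
  }
  list(confluence = do.call(rbind, conf), cytotox = do.call(rbind, cyto),
       flt3l = do.call(rbind, fl), truth = truth_table(truths))
}
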