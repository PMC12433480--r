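# Shared fixtures: all built in code at test time.

# a quiet, fast design for unit tests (not the full study layout)
small_design <- function(seed = 1L, ...) {
  simulation_design(t_end = 72, dt = 2, n_wells = 2, n_repeats = 3,
                    seed = seed, ...)
}

susceptible_truth <- function(name = "HOT", sigma = 0.05) {
  cell_line_truth(name, g = 0.05, K = 95, C0 = 5, kmax = 0.15, m50 = 0.01,
                  hill = 1.5, tau = 24, beta = 1, sigma = sigma)
}

null_truth <- function(name = "NULL1", sigma = 0.05) {
  cell_line_truth(name, g = 0.05, K = 95, C0 = 5, kmax = 0, sigma = sigma)
}

# seeded search for an untied rank pair (1..n vs a permutation) whose
# squared-rank-difference sum equals d2_target; random-restart hill climb
# over pairwise swaps (each swap changes the sum by an even amount)
rank_pair_with_d2 <- function(n, d2_target, seed = 1L) {
  set.seed(seed)
  for (restart in 1:100) {
    p <- sample.int(n)
    cur <- sum((p - seq_len(n))^2)
    for (iter in 1:20000) {
      if (cur == d2_target) return(list(x = seq_len(n), y = p))
      ij <- sample.int(n, 2)
      q <- p
      q[ij] <- q[rev(ij)]
      new <- sum((q - seq_len(n))^2)
      if (abs(new - d2_target) <= abs(cur - d2_target)) {
        p <- q
        cur <- new
      }
    }
  }
  stop(sprintf("no rank pair with sum of squared differences %d found", d2_target))
}
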