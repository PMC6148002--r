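# Independent oracles, written directly from the model definitions and kept
# free of the package's engine code paths.

# Per-edge brute-force payoff accumulation: iterate every undirected edge
# once and add the two directed payoffs.
oracle_payoffs <- function(strategies, topology, matrix) {
  s <- ifelse(strategies == 1L, "C", "D")
  pay <- numeric(topology$n_players)
  for (i in seq_len(topology$n_players)) {
    for (j in topology$neighbor_lists[[i]]) {
      if (j > i) {
        pay[i] <- pay[i] + matrix[s[i], s[j]]
        pay[j] <- pay[j] + matrix[s[j], s[i]]
      }
    }
  }
  pay
}

# Minimal standard-Fermi simulator (no reputation): synchronous updating,
# classical adoption probability 1 / (1 + exp((P_i - P_j) / (k_i K))).
# Mirrors the documented RNG protocol (seed -> n init uniforms; per step,
# n model uniforms then n adoption uniforms) so trajectories are comparable
# step for step.
oracle_standard_fermi <- function(topology, b, K, n_steps, seed) {
  set.seed(seed)
  n <- topology$n_players
  s <- as.integer(runif(n) < 0.5)            # 1 = C, 0 = D
  pm <- matrix(c(0, 0, b, 1), nrow = 2)      # pm[si+1, sj+1], weak PDG
  rho <- numeric(n_steps + 1)
  rho[1] <- mean(s)
  traj <- vector("list", n_steps + 1)
  traj[[1]] <- s
  for (t in seq_len(n_steps)) {
    pay <- numeric(n)
    for (i in seq_len(n)) {
      for (j in topology$neighbor_lists[[i]]) {
        pay[i] <- pay[i] + pm[s[i] + 1L, s[j] + 1L]
      }
    }
    u1 <- runif(n)
    u2 <- runif(n)
    s_new <- s
    for (i in seq_len(n)) {
      k <- topology$degree[i]
      j <- topology$neighbor_lists[[i]][min(floor(u1[i] * k) + 1, k)]
      prob <- 1 / (1 + exp((pay[i] - pay[j]) / (k * K)))
      if (u2[i] < prob) s_new[i] <- s[j]
    }
    s <- s_new
    rho[t + 1] <- mean(s)
    traj[[t + 1]] <- s
  }
  list(rho_c = rho, strategies = traj)
}

# Convenience: population state with prescribed strategies and reputations.
make_state <- function(strategies, reputations = numeric(length(strategies))) {
  st <- repgame::init_population(length(strategies))
  st$strategies <- as.integer(strategies)
  st$reputations <- as.numeric(reputations)
  st
}

# Small random strategy vector (1 = C, 0 = D).
random_strategies <- function(n) as.integer(runif(n) < 0.5)
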