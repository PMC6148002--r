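#' Reputation-biased Fermi adoption probability
#'
#' Probability that focal player \eqn{i} adopts the strategy of its model
#' neighbour \eqn{j}:
#' \deqn{Prob_i = \frac{1}{1 + \exp[(P_i - P_j)/(k_i K) - R_j]}}
#' where \eqn{(P_i - P_j)/k_i} is the normalised payoff difference,
#' \eqn{K} the selection intensity, and \eqn{R_j} the model's reputation
#' ("teaching ability"): a positive \eqn{R_j} raises the adoption
#' probability, a negative one lowers it. With \eqn{R_j = 0} this is the
#' classical Fermi rule. Evaluated in a branch-stable form so large
#' exponents do not overflow.
#'
#' @param payoff_i,payoff_j Total payoffs of the focal player and its model.
#' @param degree_i Degree \eqn{k_i} of the focal player (>= 1).
#' @param reputation_j Reputation score of the model neighbour.
#' @param selection_intensity Selection intensity \eqn{K > 0}; 0.1 throughout
#'   unless stated otherwise.
#' @return Adoption probability, strictly inside (0, 1) for finite inputs
#'   of moderate size. Vectorised over all arguments.
#' @examples
#' adoption_probability(4, 4.6, 4, 0)     # classical Fermi, payoff deficit
#' adoption_probability(4, 4, 4, 3)       # equal payoffs, reputable model
#' @export
adoption_probability <- function(payoff_i, payoff_j, degree_i, reputation_j,
                                 selection_intensity = 0.1) {
  if (any(degree_i < 1L)) stop("degree_i must be >= 1", call. = FALSE)
  if (selection_intensity <= 0) stop("selection_intensity must be > 0",
                                     call. = FALSE)
  x <- (payoff_i - payoff_j) / (degree_i * selection_intensity) - reputation_j
  # 1 / (1 + exp(x)) == plogis(-x), which is overflow-safe
  stats::plogis(-x)
}

#' Draw one model neighbour per player
#'
#' Every player independently picks one of its neighbours uniformly at
#' random as the reference target whose strategy it may adopt. Consumes
#' exactly `n_players` uniforms from R's RNG stream (the same discipline the
#' compiled engine uses).
#'
#' @param topology A `topology` object.
#' @return Integer vector of model indices (1-based), one per player.
#' @export
select_models <- function(topology) {
  n <- topology$n_players
  k <- topology$degree
  u <- runif(n)
  idx <- pmin(as.integer(u * k), k - 1L)     # 0-based slot within nbr list
  topology$nbr_flat0[topology$offset[seq_len(n)] + idx + 1L] + 1L
}

new_population_state <- function(strategies, reputations, time_step = 0L) {
  structure(list(strategies = as.integer(strategies),
                 reputations = as.numeric(reputations),
                 time_step = as.integer(time_step)),
            class = "population_state")
}

#' Initial population state
#'
#' Strategies are assigned i.i.d. cooperator/defector with probability 1/2
#' each; all reputations start at 0 so no player has a preferential
#' influence. Consumes `n` uniforms from the current RNG stream.
#'
#' @param n Number of players.
#' @return A `population_state` with integer `strategies` (1 = C, 0 = D),
#'   numeric `reputations`, and `time_step = 0`.
#' @export
init_population <- function(n) {
  new_population_state(as.integer(runif(n) < 0.5), numeric(n), 0L)
}

#' Simulation configuration
#'
#' Bundles everything one replicate needs: the game, the interaction
#' topology, the reputation parameters \eqn{\delta} (per-round reputation
#' increment) and \eqn{\alpha} (saturation bound, \eqn{R_i \in [-\alpha,
#' \alpha]}), the selection intensity \eqn{K}, run length and averaging
#' window, and the seed. \eqn{\delta = 0} recovers the traditional
#' (reputation-free) model; \eqn{\delta/\alpha} is the fluctuation ratio of
#' reputation and may exceed 1.
#'
#' @param game A [game_spec()].
#' @param topology A `topology` object.
#' @param delta Reputation increment per round, >= 0.
#' @param alpha Reputation bound, > 0.
#' @param selection_intensity Fermi selection intensity \eqn{K}, default 0.1.
#' @param n_steps Full Monte Carlo steps to run (default 61000).
#' @param averaging_window Trailing steps averaged for steady-state
#'   observables (default 1000; must not exceed `n_steps`).
#' @param n_replicates Independent runs used by sweep helpers (default 10).
#' @param seed Base RNG seed.
#' @param rep_update When reputations are incremented within a step:
#'   `"after_adoption"` (default; imitators see reputations from before the
#'   current round) or `"before_adoption"` (imitators already see the
#'   current round's behaviour). Both orderings update reputations from the
#'   strategy each player actually played in the payoff stage.
#' @param engine `"cpp"` (compiled, default) or `"r"` (pure-R reference
#'   twin; identical trajectories under the same seed).
#' @param early_stop Stop stepping once strategies are homogeneous (the
#'   composition is absorbing); recorded observables are identical to the
#'   full run.
#' @param record_snapshots Integer vector of steps at which to store the
#'   full strategy configuration.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(game, topology, delta, alpha,
                              selection_intensity = 0.1,
                              n_steps = 61000L,
                              averaging_window = 1000L,
                              n_replicates = 10L,
                              seed = 1L,
                              rep_update = c("after_adoption",
                                             "before_adoption"),
                              engine = c("cpp", "r"),
                              early_stop = TRUE,
                              record_snapshots = integer(0)) {
  rep_update <- match.arg(rep_update)
  engine <- match.arg(engine)
  if (!inherits(game, "game_spec")) stop("game must be a game_spec",
                                         call. = FALSE)
  if (!inherits(topology, "topology")) stop("topology must be a topology",
                                            call. = FALSE)
  if (delta < 0) stop("delta must be >= 0", call. = FALSE)
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (selection_intensity <= 0) stop("selection_intensity must be > 0",
                                     call. = FALSE)
  n_steps <- as.integer(n_steps)
  averaging_window <- as.integer(averaging_window)
  if (n_steps < 0L) stop("n_steps must be >= 0", call. = FALSE)
  if (averaging_window < 1L || averaging_window > max(n_steps, 1L)) {
    stop("averaging_window must lie in [1, n_steps]", call. = FALSE)
  }
  structure(list(game = game, topology = topology,
                 delta = delta, alpha = alpha,
                 selection_intensity = selection_intensity,
                 n_steps = n_steps,
                 averaging_window = averaging_window,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed),
                 rep_update = rep_update,
                 engine = engine,
                 early_stop = early_stop,
                 record_snapshots = as.integer(record_snapshots)),
            class = "simulation_config")
}

#' One synchronous Monte Carlo step (pure-R reference)
#'
#' Executes, in order: (1) payoff accrual from current strategies;
#' (2) uniform model selection; (3) synchronous reputation-biased Fermi
#' adoption, every decision reading the pre-step snapshot of strategies,
#' payoffs, and reputations; (4) reputation update from the strategies
#' played in stage (1), clipped to \eqn{[-\alpha, \alpha]}. With
#' `rep_update = "before_adoption"` stage (4) runs before stage (3).
#' RNG draw order matches the compiled engine (n model uniforms, then n
#' adoption uniforms), so the two engines produce bit-identical
#' trajectories from the same seed.
#'
#' @param state A `population_state`.
#' @param topology A `topology`.
#' @param matrix Payoff matrix from [build_payoff_matrix()].
#' @param config A [simulation_config()] (only `delta`, `alpha`,
#'   `selection_intensity`, `rep_update` are used).
#' @return The next `population_state`.
#' @export
monte_carlo_step <- function(state, topology, matrix, config) {
  s <- state$strategies
  rep_ <- state$reputations
  n <- topology$n_players
  K <- config$selection_intensity
  payoffs <- accumulate_payoffs(s, topology, matrix)
  u1 <- runif(n)
  u2 <- runif(n)
  k <- topology$degree
  idx <- pmin(as.integer(u1 * k), k - 1L)
  j <- topology$nbr_flat0[topology$offset[seq_len(n)] + idx + 1L] + 1L
  if (config$rep_update == "before_adoption") {
    rep_ <- pmin(pmax(rep_ + ifelse(s == STRAT_C, config$delta,
                                    -config$delta), -config$alpha),
                 config$alpha)
  }
  prob <- adoption_probability(payoffs, payoffs[j], k, rep_[j], K)
  s_new <- ifelse(u2 < prob, s[j], s)
  if (config$rep_update == "after_adoption") {
    rep_ <- pmin(pmax(rep_ + ifelse(s == STRAT_C, config$delta,
                                    -config$delta), -config$alpha),
                 config$alpha)
  }
  new_population_state(as.integer(s_new), rep_, state$time_step + 1L)
}

#' Run one replicate of the coevolutionary dynamics
#'
#' Seeds the RNG from `config$seed`, draws the random 50/50 initial
#' strategies (all reputations zero), then executes `n_steps` synchronous
#' Monte Carlo steps, recording the cooperation fraction and the
#' strategy-retention rates at every step. Once the population is
#' strategy-homogeneous the composition is absorbing and, with
#' `early_stop = TRUE`, stepping halts while observables are extended as
#' constants (identical values to the full run).
#'
#' @param config A [simulation_config()].
#' @param seed Optional seed overriding `config$seed` (used by replicate
#'   drivers).
#' @return A `trajectory_record`: list with `rho_c` (length `n_steps + 1`,
#'   entry t+1 is the fraction after t steps), `rho_cc`/`rho_dd` (retention
#'   between steps t-1 and t; `NA` at step 0), `snapshots`, final state,
#'   `stopped_at` (-1 if never absorbed), and a config echo.
#' @examples
#' cfg <- simulation_config(game_spec("weak_pdg", 1.05),
#'                          build_lattice(10), delta = 0, alpha = 1,
#'                          n_steps = 50, averaging_window = 10, seed = 7)
#' traj <- run_simulation(cfg)
#' tail(traj$rho_c)
#' @export
run_simulation <- function(config, seed = config$seed) {
  set.seed(seed)
  top <- config$topology
  state <- init_population(top$n_players)
  pm <- payoff_matrix_coded(build_payoff_matrix(config$game))

  if (config$engine == "cpp") {
    res <- run_engine_cpp(top$nbr_flat0, top$offset, top$degree,
                          state$strategies, state$reputations, pm,
                          config$delta, config$alpha,
                          config$selection_intensity,
                          config$n_steps,
                          config$rep_update == "before_adoption",
                          config$record_snapshots,
                          config$early_stop)
  } else {
    res <- run_engine_r(state, config)
  }
  snapshots <- lapply(res$snapshots, function(v) {
    if (!is.na(top$side_length)) {
      matrix(v, nrow = top$side_length, byrow = TRUE)
    } else v
  })
  structure(list(rho_c = res$rho_c,
                 rho_cc = res$rho_cc,
                 rho_dd = res$rho_dd,
                 snapshots = snapshots,
                 final_strategies = res$final_strategies,
                 final_reputations = res$final_reputations,
                 stopped_at = res$stopped_at,
                 seed = as.integer(seed),
                 config = config),
            class = "trajectory_record")
}

# Pure-R engine twin: same step order and RNG discipline as run_engine_cpp.
run_engine_r <- function(state, config) {
  top <- config$topology
  matrix_ <- build_payoff_matrix(config$game)
  n <- top$n_players
  n_steps <- config$n_steps
  rho_c <- numeric(n_steps + 1L)
  rho_cc <- rep(NA_real_, n_steps + 1L)
  rho_dd <- rep(NA_real_, n_steps + 1L)
  rho_c[1L] <- mean(state$strategies == STRAT_C)
  snap_at <- config$record_snapshots
  snapshots <- list()
  if (0L %in% snap_at) snapshots[["0"]] <- state$strategies
  stopped_at <- -1L
  t <- 1L
  while (t <= n_steps) {
    nc <- sum(state$strategies)
    if (config$early_stop && (nc == 0L || nc == n)) {
      stopped_at <- t - 1L
      break
    }
    prev <- state$strategies
    state <- monte_carlo_step(state, top, matrix_, config)
    ret <- retention_rates(prev, state$strategies)
    rho_cc[t + 1L] <- ret[["rho_cc"]]
    rho_dd[t + 1L] <- ret[["rho_dd"]]
    rho_c[t + 1L] <- mean(state$strategies == STRAT_C)
    if (t %in% snap_at) snapshots[[as.character(t)]] <- state$strategies
    t <- t + 1L
  }
  if (stopped_at >= 0L) {
    all_c <- all(state$strategies == STRAT_C)
    fill <- (stopped_at + 2L):(n_steps + 1L)
    rho_c[fill] <- rho_c[stopped_at + 1L]
    rho_cc[fill] <- if (all_c) 1 else 0
    rho_dd[fill] <- if (all_c) 0 else 1
    for (tt in snap_at[snap_at > stopped_at]) {
      snapshots[[as.character(tt)]] <- state$strategies
    }
    rem <- n_steps - stopped_at
    drift <- ifelse(state$strategies == STRAT_C, 1, -1) * config$delta * rem
    state$reputations <- pmin(pmax(state$reputations + drift,
                                   -config$alpha), config$alpha)
  }
  list(rho_c = rho_c, rho_cc = rho_cc, rho_dd = rho_dd,
       final_strategies = state$strategies,
       final_reputations = state$reputations,
       snapshots = snapshots, stopped_at = stopped_at)
}

#' @export
print.trajectory_record <- function(x, ...) {
  n_steps <- length(x$rho_c) - 1L
  cat(sprintf(
    "<trajectory_record> %d steps, final rho_c = %.4f%s\n",
    n_steps, x$rho_c[n_steps + 1L],
    if (x$stopped_at >= 0L)
      sprintf(" (absorbed at step %d)", x$stopped_at) else ""))
  invisible(x)
}

#' @export
as.data.frame.trajectory_record <- function(x, ...) {
  data.frame(step = 0:(length(x$rho_c) - 1L),
             rho_c = x$rho_c, rho_cc = x$rho_cc, rho_dd = x$rho_dd)
}

#' Run independent replicates of a configuration
#'
#' Replicate seeds are derived reproducibly from the base seed: the base
#' seed initialises the stream, and `n_replicates` seeds are drawn with
#' `sample.int`, so the full set of runs is determined by `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param n_replicates Number of runs (default `config$n_replicates`).
#' @return List of `trajectory_record`s, one per replicate.
#' @export
run_replicates <- function(config, n_replicates = config$n_replicates) {
  seeds <- replicate_seeds(config$seed, n_replicates)
  lapply(seeds, function(s) run_simulation(config, seed = s))
}

replicate_seeds <- function(seed, n) {
  local_seed(seed, sample.int(2147483646L, n))
}

#' Serialise a trajectory to CSV with a JSON sidecar
#'
#' Writes the per-step observables (`step`, `rho_c`, `rho_cc`, `rho_dd`) as
#' CSV and the full configuration (game, topology summary, parameters, seed)
#' as a JSON sidecar next to it, sufficient to reproduce the run.
#'
#' @param traj A `trajectory_record`.
#' @param path CSV output path; the sidecar is `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  cfg <- traj$config
  meta <- list(game_kind = cfg$game$game_kind,
               temptation_param = cfg$game$temptation_param,
               topology = cfg$topology$kind,
               n_players = cfg$topology$n_players,
               side_length = cfg$topology$side_length,
               delta = cfg$delta, alpha = cfg$alpha,
               selection_intensity = cfg$selection_intensity,
               n_steps = cfg$n_steps,
               averaging_window = cfg$averaging_window,
               rep_update = cfg$rep_update,
               seed = traj$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
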