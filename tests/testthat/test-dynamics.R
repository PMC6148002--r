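test_that("adoption probability reproduces the analytic values", {
  # zero exponent
  expect_equal(adoption_probability(4, 4, 4, 0, 0.1), 0.5)
  # payoff deficit of 0.6 at k = 4, K = 0.1: 1 / (1 + exp(-1.5))
  expect_equal(adoption_probability(4.0, 4.6, 4, 0, 0.1),
               1 / (1 + exp(-1.5)), tolerance = 1e-12)
  # equal payoffs, reputable / notorious model
  expect_equal(adoption_probability(1, 1, 4, 3, 0.1),
               1 / (1 + exp(-3)), tolerance = 1e-12)
  expect_equal(adoption_probability(1, 1, 4, -3, 0.1),
               1 / (1 + exp(3)), tolerance = 1e-12)
})

test_that("adoption probability is a proper, monotone, stable probability", {
  set.seed(21)
  for (i in 1:200) {
    pi_ <- runif(1, 0, 8)
    pj <- runif(1, 0, 8)
    k <- sample(c(4L, 8L), 1)
    rj <- runif(1, -4, 4)
    p0 <- adoption_probability(pi_, pj, k, rj)
    expect_gt(p0, 0)
    expect_lt(p0, 1)
    # strictly increasing in R_j and P_j, decreasing in P_i
    expect_gt(adoption_probability(pi_, pj, k, rj + 0.5), p0)
    expect_gt(adoption_probability(pi_, pj + 0.5, k, rj), p0)
    expect_lt(adoption_probability(pi_ + 0.5, pj, k, rj), p0)
  }
  # logistic symmetry at equal payoffs: Prob(R_j) + Prob(-R_j) = 1
  r <- runif(50, -5, 5)
  expect_equal(adoption_probability(2, 2, 4, r) +
                 adoption_probability(2, 2, 4, -r),
               rep(1, 50), tolerance = 1e-12)
  # overflow-safe for huge exponents
  expect_equal(adoption_probability(0, 4000, 4, 0, 1e-4), 1)
  expect_equal(adoption_probability(4000, 0, 4, 0, 1e-4), 0)
  # deterministic-imitation limit K -> 0
  expect_equal(adoption_probability(1, 2, 4, 0, 1e-12), 1)
  expect_equal(adoption_probability(2, 1, 4, 0, 1e-12), 0)
  expect_error(adoption_probability(1, 1, 0, 0), "degree")
  expect_error(adoption_probability(1, 1, 4, 0, 0), "selection_intensity")
})

test_that("model selection is uniform over neighbours and seed-reproducible", {
  top <- build_lattice(3, "von_neumann")
  set.seed(5)
  draws <- replicate(30000, select_models(top)[1])
  freqs <- table(draws) / length(draws)
  expect_setequal(as.integer(names(freqs)), top$neighbor_lists[[1]])
  expect_true(all(abs(freqs - 0.25) < 0.01))

  set.seed(99)
  a <- replicate(10, select_models(top))
  set.seed(99)
  b <- replicate(10, select_models(top))
  expect_identical(a, b)
})

test_that("reputation saturates exactly after ceiling(alpha/delta) rounds", {
  top <- build_lattice(4)
  m <- build_payoff_matrix(game_spec("weak_pdg", 1.15))
  for (prm in list(c(delta = 0.9, alpha = 3), c(delta = 1, alpha = 2.5),
                   c(delta = 2, alpha = 2))) {
    cfg <- simulation_config(game_spec("weak_pdg", 1.15), top,
                             delta = prm[["delta"]], alpha = prm[["alpha"]],
                             n_steps = 10, averaging_window = 5)
    n_rounds <- ceiling(prm[["alpha"]] / prm[["delta"]])
    # all-C: reputations climb to exactly +alpha; all-D mirrors to -alpha
    st <- make_state(rep(1L, 16))
    set.seed(1)
    for (t in seq_len(n_rounds)) st <- monte_carlo_step(st, top, m, cfg)
    expect_identical(st$reputations, rep(prm[["alpha"]], 16))
    st <- make_state(rep(0L, 16))
    set.seed(1)
    for (t in seq_len(n_rounds)) st <- monte_carlo_step(st, top, m, cfg)
    expect_identical(st$reputations, rep(-prm[["alpha"]], 16))
  }
  # clipping: cooperator at R = 2.5 with delta = 1, alpha = 3 ends at 3
  cfg <- simulation_config(game_spec("weak_pdg", 1.15), top, delta = 1,
                           alpha = 3, n_steps = 5, averaging_window = 2)
  st <- make_state(rep(1L, 16), rep(2.5, 16))
  st <- monte_carlo_step(st, top, m, cfg)
  expect_identical(st$reputations, rep(3, 16))
})

test_that("homogeneous strategy states are absorbing", {
  top <- build_lattice(5)
  m <- build_payoff_matrix(game_spec("weak_pdg", 1.6))
  cfg <- simulation_config(game_spec("weak_pdg", 1.6), top, delta = 1.5,
                           alpha = 3, n_steps = 30, averaging_window = 10)
  set.seed(3)
  for (s0 in list(rep(0L, 25), rep(1L, 25))) {
    st <- make_state(s0)
    for (t in 1:10) st <- monte_carlo_step(st, top, m, cfg)
    expect_identical(st$strategies, s0)
    # reputations keep drifting toward the saturation bound
    expect_identical(st$reputations,
                     rep(if (s0[1] == 1L) 3 else -3, 25))
  }
})

test_that("delta = 0 reduces to the standard Fermi rule, step for step", {
  top <- build_lattice(10)
  b <- 1.25
  oracle <- oracle_standard_fermi(top, b, K = 0.1, n_steps = 100, seed = 17)
  cfg <- simulation_config(game_spec("weak_pdg", b), top, delta = 0,
                           alpha = 1, n_steps = 100, averaging_window = 10,
                           seed = 17, early_stop = FALSE,
                           record_snapshots = 0:100)
  for (eng in c("cpp", "r")) {
    cfg$engine <- eng
    traj <- run_simulation(cfg)
    expect_equal(traj$rho_c, oracle$rho_c)
    for (t in c(1, 10, 50, 100)) {
      expect_identical(as.integer(t(traj$snapshots[[as.character(t)]])),
                       oracle$strategies[[t + 1]])
    }
  }
})

test_that("compiled and pure-R engines produce bit-identical trajectories", {
  top <- build_lattice(8)
  for (ru in c("after_adoption", "before_adoption")) {
    cfg <- simulation_config(game_spec("weak_pdg", 1.15), top, delta = 0.75,
                             alpha = 3, n_steps = 60, averaging_window = 10,
                             seed = 23, rep_update = ru)
    a <- run_simulation(cfg)
    cfg$engine <- "r"
    b <- run_simulation(cfg)
    expect_identical(a$rho_c, b$rho_c)
    expect_identical(a$rho_cc, b$rho_cc)
    expect_identical(a$rho_dd, b$rho_dd)
    expect_identical(a$final_strategies, b$final_strategies)
    expect_identical(a$final_reputations, b$final_reputations)
  }
})

test_that("early stop changes no recorded observable", {
  top <- build_lattice(10)
  # b far above threshold: cooperators die out quickly under delta = 0
  cfg <- simulation_config(game_spec("weak_pdg", 1.6), top, delta = 0.5,
                           alpha = 2, n_steps = 400, averaging_window = 50,
                           seed = 31, early_stop = TRUE)
  a <- run_simulation(cfg)
  expect_gte(a$stopped_at, 0)    # absorbed well before 400 steps
  cfg$early_stop <- FALSE
  b <- run_simulation(cfg)
  expect_identical(a$rho_c, b$rho_c)
  expect_identical(a$rho_cc, b$rho_cc)
  expect_identical(a$rho_dd, b$rho_dd)
  expect_identical(a$final_strategies, b$final_strategies)
  expect_identical(a$final_reputations, b$final_reputations)
})

test_that("runs are bit-reproducible from the seed", {
  top <- build_lattice(8)
  cfg <- simulation_config(game_spec("snowdrift", 0.4), top, delta = 1,
                           alpha = 2, n_steps = 50, averaging_window = 10,
                           seed = 7)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$rho_c, b$rho_c)
  expect_identical(a$final_reputations, b$final_reputations)
  expect_identical(run_replicates(cfg, 3)[[2]]$rho_c,
                   run_replicates(cfg, 3)[[2]]$rho_c)
})

test_that("initial conditions are a 50/50 strategy mix with zero reputation", {
  cfg <- simulation_config(game_spec("weak_pdg", 1.15), build_lattice(40),
                           delta = 1, alpha = 2, n_steps = 0,
                           averaging_window = 1, seed = 2)
  traj <- run_simulation(cfg)
  expect_lt(abs(traj$rho_c[1] - 0.5), 0.03)   # binomial error at N = 1600
  expect_identical(traj$final_reputations, numeric(1600))
})
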