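fake_traj <- function(rho_c, window = length(rho_c)) {
  structure(list(rho_c = rho_c,
                 config = list(averaging_window = window)),
            class = "trajectory_record")
}

test_that("cooperation fraction is the plain cooperator count over N", {
  expect_equal(cooperation_fraction(rep("C", 7)), 1)
  expect_equal(cooperation_fraction(rep("D", 7)), 0)
  expect_equal(cooperation_fraction(c(rep("C", 3), rep("D", 6))), 1 / 3)
  set.seed(41)
  for (i in 1:10) {
    s <- random_strategies(30)
    expect_equal(cooperation_fraction(s), sum(s == 1L) / 30)
  }
  expect_error(cooperation_fraction(integer(0)), "empty")
})

test_that("retention rates follow the per-class definitions and conventions", {
  # no switches, both classes present
  s <- c(1L, 1L, 0L, 0L)
  expect_equal(retention_rates(s, s), c(rho_cc = 1, rho_dd = 1))
  # 4 cooperators, one defects
  a <- c(1L, 1L, 1L, 1L, 0L)
  b <- c(1L, 1L, 1L, 0L, 0L)
  expect_equal(retention_rates(a, b)[["rho_cc"]], 0.75)
  # all-defector rounds: empty cooperator class yields 0 by convention
  expect_equal(retention_rates(rep(0L, 5), rep(0L, 5)),
               c(rho_cc = 0, rho_dd = 1))
  expect_equal(retention_rates(rep(1L, 5), rep(1L, 5)),
               c(rho_cc = 1, rho_dd = 0))
  expect_error(retention_rates(c(1L, 0L), c(1L, 0L, 0L)), "length")

  # brute-force per-player loop agreement on random transitions
  set.seed(42)
  for (i in 1:10) {
    a <- random_strategies(40)
    b <- random_strategies(40)
    kept_c <- 0; kept_d <- 0
    for (p in 1:40) {
      if (a[p] == 1L && b[p] == 1L) kept_c <- kept_c + 1
      if (a[p] == 0L && b[p] == 0L) kept_d <- kept_d + 1
    }
    expect_equal(retention_rates(a, b),
                 c(rho_cc = if (sum(a) > 0) kept_c / sum(a) else 0,
                   rho_dd = if (sum(1 - a) > 0) kept_d / sum(1 - a) else 0))
  }
})

test_that("steady-state averaging pools windows then replicates", {
  expect_equal(steady_state_average(fake_traj(rep(0.37, 50)), 10)$mean, 0.37)
  # two absorbed replicates, one extinct and one all-C
  reps <- list(fake_traj(rep(0, 20)), fake_traj(rep(1, 20)))
  ss <- steady_state_average(reps, 20)
  expect_equal(ss$mean, 0.5)
  expect_equal(ss$per_replicate, c(0, 1))
  expect_equal(ss$se, sd(c(0, 1)) / sqrt(2))
  # invariant to the prefix once absorbed
  expect_equal(steady_state_average(fake_traj(c(0.9, 0.4, rep(0, 30))),
                                    10)$mean, 0)
  expect_error(steady_state_average(fake_traj(rep(0.5, 5)), 10), "window")
})

test_that("trajectory absorbing invariant: rho_c sticks at 0 and 1", {
  top <- build_lattice(10)
  cfg <- simulation_config(game_spec("weak_pdg", 1.5), top, delta = 0,
                           alpha = 1, n_steps = 300, averaging_window = 50,
                           seed = 13)
  traj <- run_simulation(cfg)
  hit <- which(traj$rho_c %in% c(0, 1))[1]
  expect_false(is.na(hit))
  expect_true(all(traj$rho_c[hit:length(traj$rho_c)] == traj$rho_c[hit]))
  expect_true(all(traj$rho_c >= 0 & traj$rho_c <= 1))
})

test_that("threshold sweep finds the smallest all-extinct grid value", {
  top <- build_lattice(20)
  cfg <- simulation_config(game_spec("weak_pdg", 1.0), top, delta = 0,
                           alpha = 1, n_steps = 600, averaging_window = 100,
                           n_replicates = 3, seed = 5)
  est <- estimate_extinction_threshold(cfg, seq(1.0, 1.3, by = 0.05),
                                       stop_at_first = FALSE)
  expect_false(est$open)
  expect_true(est$threshold <= 1.3 && est$threshold >= 1.0)
  # every replicate at the threshold is extinct, window mean exactly zero
  at <- est$sweep[est$sweep$param == est$threshold, ]
  expect_true(all(at$rho_c == 0))

  # a grid on which cooperators always survive returns an open bound
  surv <- estimate_extinction_threshold(cfg, 1.0)
  expect_true(surv$open)
  expect_equal(surv$threshold, 1.0)
  expect_false(surv$inconclusive)

  # stricter extinction predicates never lower the threshold
  loose <- estimate_extinction_threshold(cfg, seq(1.0, 1.3, by = 0.05),
                                         n_extinct_required = 1L,
                                         stop_at_first = FALSE)
  expect_lte(loose$threshold, est$threshold)
})

test_that("sweep results serialise to tidy CSV plus JSON summary", {
  top <- build_lattice(10)
  cfg <- simulation_config(game_spec("weak_pdg", 1.0), top, delta = 0,
                           alpha = 1, n_steps = 100, averaging_window = 20,
                           n_replicates = 2, seed = 3)
  est <- estimate_extinction_threshold(cfg, c(1.2, 1.4))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_sweep(est, csv, js)
  back <- utils::read.csv(csv)
  expect_named(back, c("param", "replicate", "seed", "rho_c", "extinct"))
  summ <- jsonlite::fromJSON(js)
  expect_equal(summ$threshold, est$threshold)
})
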