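#' Fraction of cooperators
#'
#' @param strategies Per-player strategies (`"C"`/`"D"` or 0/1 with 1 = C).
#' @return Number of cooperators divided by the population size.
#' @export
cooperation_fraction <- function(strategies) {
  s <- as_strategy_int(strategies)
  if (length(s) == 0L) stop("empty population", call. = FALSE)
  mean(s == STRAT_C)
}

#' Strategy-retention rates between two consecutive rounds
#'
#' \eqn{\rho_{c \to c}} is the fraction of the round-\eqn{t} cooperators that
#' still cooperate at round \eqn{t + 1}; \eqn{\rho_{d \to d}} is the
#' analogous defector retention. An empty class yields 0 by convention (so a
#' cooperator-extinct population reports \eqn{\rho_{c \to c} = 0},
#' \eqn{\rho_{d \to d} = 1}).
#'
#' @param strategies_t,strategies_t1 Strategy vectors of equal length at
#'   rounds t and t + 1.
#' @return Named numeric vector `c(rho_cc = , rho_dd = )`.
#' @export
retention_rates <- function(strategies_t, strategies_t1) {
  a <- as_strategy_int(strategies_t)
  b <- as_strategy_int(strategies_t1)
  if (length(a) != length(b)) stop("strategy vectors differ in length",
                                   call. = FALSE)
  nc <- sum(a == STRAT_C)
  nd <- length(a) - nc
  rho_cc <- if (nc > 0L) sum(a == STRAT_C & b == STRAT_C) / nc else 0
  rho_dd <- if (nd > 0L) sum(a == STRAT_D & b == STRAT_D) / nd else 0
  c(rho_cc = rho_cc, rho_dd = rho_dd)
}

#' Steady-state cooperation level across replicates
#'
#' Per replicate, averages \eqn{\rho_c} over the final `window` recorded
#' steps; the reported level is the unweighted mean of those per-replicate
#' means, with the across-replicate standard error.
#'
#' @param trajectories A `trajectory_record` or a list of them (replicates).
#' @param window Number of trailing steps to average; defaults to the
#'   averaging window in the first trajectory's config.
#' @return List with `mean`, `se` (NA for a single replicate), and
#'   `per_replicate` means.
#' @export
steady_state_average <- function(trajectories, window = NULL) {
  if (inherits(trajectories, "trajectory_record")) {
    trajectories <- list(trajectories)
  }
  stopifnot(length(trajectories) >= 1L)
  if (is.null(window)) window <- trajectories[[1L]]$config$averaging_window
  per <- vapply(trajectories, function(tr) {
    m <- length(tr$rho_c)
    if (window > m) stop("window exceeds recorded series length",
                         call. = FALSE)
    mean(tr$rho_c[(m - window + 1L):m])
  }, numeric(1))
  list(mean = mean(per),
       se = if (length(per) > 1L) stats::sd(per) / sqrt(length(per))
            else NA_real_,
       per_replicate = per)
}

#' Estimate the cooperator-extinction threshold by a grid sweep
#'
#' Runs the dynamics at each value of the game's temptation parameter
#' (\eqn{b} for the weak PDG, \eqn{r} for the snowdrift game) on an
#' ascending grid, with `n_replicates` independent runs per grid point.
#' A grid point counts as extinct when at least `n_extinct_required`
#' replicates end with steady-state \eqn{\rho_c} exactly 0 — exact, because
#' the all-defector state is absorbing, so its window average is exactly
#' zero. The threshold \eqn{b_c} (or \eqn{r_c}) is the smallest extinct
#' grid value; if cooperators survive through the whole grid the bound is
#' open (`open = TRUE`) and the grid maximum is returned as a lower bound.
#'
#' @param config A [simulation_config()] template; its temptation parameter
#'   is replaced by each grid value.
#' @param param_grid Ascending numeric grid of temptation values.
#' @param n_replicates Replicates per grid point (default
#'   `config$n_replicates`).
#' @param n_extinct_required How many replicates must be extinct for the
#'   point to count (default: all of them).
#' @param seed Base seed for the per-replicate seed table (default
#'   `config$seed`).
#' @param stop_at_first Stop sweeping upward at the first extinct grid
#'   point (default TRUE); set FALSE to record the full sweep.
#' @return A `threshold_estimate`: list with `threshold`, `open`,
#'   `inconclusive`, and `sweep` (data frame: param, replicate, seed,
#'   rho_c, extinct).
#' @export
estimate_extinction_threshold <- function(config, param_grid,
                                          n_replicates = config$n_replicates,
                                          n_extinct_required = n_replicates,
                                          seed = config$seed,
                                          stop_at_first = TRUE) {
  stopifnot(length(param_grid) >= 1L, !is.unsorted(param_grid))
  stopifnot(n_extinct_required >= 1L, n_extinct_required <= n_replicates)
  seeds <- replicate_seeds(seed, n_replicates)
  rows <- list()
  threshold <- NA_real_
  for (p in param_grid) {
    cfg_p <- config
    cfg_p$game <- game_spec(config$game$game_kind, p)
    extinct_count <- 0L
    for (r in seq_len(n_replicates)) {
      traj <- run_simulation(cfg_p, seed = seeds[r])
      ss <- steady_state_average(list(traj),
                                 window = config$averaging_window)$mean
      rows[[length(rows) + 1L]] <- data.frame(
        param = p, replicate = r, seed = seeds[r], rho_c = ss,
        extinct = (ss == 0))
      if (ss == 0) extinct_count <- extinct_count + 1L
    }
    if (is.na(threshold) && extinct_count >= n_extinct_required) {
      threshold <- p
      if (stop_at_first) break
    }
  }
  sweep <- do.call(rbind, rows)
  open <- is.na(threshold)
  any_survival <- any(!sweep$extinct)
  structure(list(threshold = if (open) max(param_grid) else threshold,
                 open = open,
                 inconclusive = open && !any_survival,
                 sweep = sweep),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  sym <- if (x$open) "> " else "= "
  cat(sprintf("<threshold_estimate> extinction threshold %s%g%s\n",
              sym, x$threshold,
              if (x$inconclusive) " (inconclusive)" else ""))
  invisible(x)
}

#' Write sweep results as tidy CSV plus a JSON threshold summary
#'
#' @param estimate A `threshold_estimate`.
#' @param csv_path Tidy per-(parameter, replicate) CSV path.
#' @param json_path Threshold summary JSON path (optional).
#' @return `csv_path`, invisibly.
#' @export
write_sweep <- function(estimate, csv_path, json_path = NULL) {
  utils::write.csv(estimate$sweep, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(threshold = estimate$threshold,
                              open = estimate$open,
                              inconclusive = estimate$inconclusive),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
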