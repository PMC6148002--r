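#' Parse a JSON run configuration
#'
#' Reads a structured-text (JSON) configuration and resolves it into a
#' [simulation_config()], applying the standard defaults for every missing
#' field: weak PDG with b = 1.15 on a 200x200 von Neumann lattice,
#' traditional baseline delta = 0 with alpha = 3, K = 0.1, 61000 steps,
#' averaging window 1000, 10 replicates, seed 1. An empty file (or `{}`)
#' therefore yields the full default configuration. Unknown keys and
#' out-of-range values raise descriptive errors.
#'
#' Recognised keys: `game_kind`, `temptation_param`, `delta`, `alpha`,
#' `selection_intensity`, `n_steps`, `averaging_window`, `n_replicates`,
#' `seed`, `rep_update`, `engine`, and `topology` (an object with `kind` =
#' `"lattice_vn"`, `"lattice_moore"` or `"er_random"`, plus `side_length`
#' for lattices or `n_players`/`mean_degree` for ER graphs).
#'
#' @param path Path to a JSON file.
#' @return A [simulation_config()].
#' @export
parse_config <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  raw <- if (nzchar(trimws(txt))) jsonlite::fromJSON(txt) else list()
  if (!is.list(raw)) stop("config must be a JSON object", call. = FALSE)
  known <- c("game_kind", "temptation_param", "delta", "alpha",
             "selection_intensity", "n_steps", "averaging_window",
             "n_replicates", "seed", "rep_update", "engine", "topology")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults <- list(game_kind = "weak_pdg", temptation_param = 1.15,
                   delta = 0, alpha = 3, selection_intensity = 0.1,
                   n_steps = 61000L, averaging_window = 1000L,
                   n_replicates = 10L, seed = 1L,
                   rep_update = "after_adoption", engine = "cpp",
                   topology = list(kind = "lattice_vn", side_length = 200L))
  cfg <- utils::modifyList(defaults, raw)
  if (cfg$delta < 0) stop("delta must be >= 0", call. = FALSE)
  if (cfg$alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  ts <- cfg$topology
  top <- switch(as.character(ts$kind),
    lattice_vn = build_lattice(ts$side_length, "von_neumann"),
    lattice_moore = build_lattice(ts$side_length, "moore"),
    er_random = build_er_graph(ts$n_players,
                               if (is.null(ts$mean_degree)) 4
                               else ts$mean_degree,
                               seed = cfg$seed),
    stop("unknown topology kind: ", ts$kind, call. = FALSE))
  simulation_config(game = game_spec(cfg$game_kind, cfg$temptation_param),
                    topology = top,
                    delta = cfg$delta, alpha = cfg$alpha,
                    selection_intensity = cfg$selection_intensity,
                    n_steps = cfg$n_steps,
                    averaging_window = cfg$averaging_window,
                    n_replicates = cfg$n_replicates,
                    seed = cfg$seed,
                    rep_update = cfg$rep_update,
                    engine = cfg$engine)
}

# Scale presets. Full scale matches the published runs (200x200 lattice,
# 61000 MCS, last-1000 averaging, 10 replicates); desk scale is a documented
# reduction that reproduces the trends in minutes on one CPU.
experiment_scale <- function(scale) {
  switch(scale,
    full = list(side = 200L, snap_side = 100L, n_steps = 61000L,
                window = 1000L, n_reps = 10L, er_n = 10000L,
                ratio_grid = seq(0, 1, by = 0.1),
                b_grid = seq(1.0, 2.0, by = 0.01),
                er_b_grid = seq(1.0, 2.5, by = 0.1),
                r_grid = seq(0.05, 0.95, by = 0.05)),
    desk = list(side = 50L, snap_side = 50L, n_steps = 3000L,
                window = 500L, n_reps = 5L, er_n = 2000L,
                ratio_grid = seq(0, 1, by = 0.25),
                b_grid = seq(1.0, 2.0, by = 0.05),
                er_b_grid = seq(1.0, 2.5, by = 0.1),
                r_grid = seq(0.1, 0.9, by = 0.2)),
    stop("scale must be 'full' or 'desk'", call. = FALSE))
}

#' Run a canned experiment
#'
#' Drivers that regenerate the package's headline figures at either the
#' published scale (`"full"`) or a reduced desk scale (`"desk"`, labelled as
#' such in all outputs):
#' \describe{
#'   \item{fig1_vn / fig1_moore}{steady-state \eqn{\rho_c} vs the
#'     fluctuation ratio \eqn{\delta/\alpha} for \eqn{\alpha \in \{1,2,3\}}
#'     at b = 1.15.}
#'   \item{fig2_snapshots}{lattice strategy snapshots: a time series at
#'     \eqn{\delta = 1.5, \alpha = 3} and final states for
#'     \eqn{\delta \in \{0, 0.75, 1.5, 2.25, 3\}}, b = 1.17.}
#'   \item{fig3_retention}{retention-rate time series at b = 1.2,
#'     \eqn{\delta/\alpha = 0.75}, \eqn{\alpha \in \{1,2,4\}} plus the
#'     traditional baseline.}
#'   \item{fig4_thresholds}{extinction threshold \eqn{b_c} vs
#'     \eqn{\delta/\alpha} on the von Neumann lattice.}
#'   \item{fig5_er_pdg}{\eqn{\rho_c} vs b on an ER graph (mean degree 4)
#'     for \eqn{\delta \in \{0,1,2,3\}} at \eqn{\delta/\alpha = 1}.}
#'   \item{fig5_sdg}{\eqn{\rho_c} vs r for the snowdrift game on the
#'     lattice, same \eqn{\delta} set.}
#' }
#' Each driver writes tidy CSVs, a plot, and a JSON manifest carrying the
#' resolved parameters and every per-replicate seed, sufficient to reproduce
#' the outputs bit-exactly.
#'
#' @param figure_id One of `"fig1_vn"`, `"fig1_moore"`, `"fig2_snapshots"`,
#'   `"fig3_retention"`, `"fig4_thresholds"`, `"fig5_er_pdg"`, `"fig5_sdg"`.
#' @param scale `"desk"` (default) or `"full"`.
#' @param overrides Named list overriding scale presets: `side`, `n_steps`,
#'   `window`, `n_reps`, `er_n`, `ratio_grid`, `b_grid`, `er_b_grid`,
#'   `r_grid`, `alpha_values`, `delta_values`.
#' @param out_dir Output directory (created if missing).
#' @param seed Base seed recorded in the manifest.
#' @return Invisibly, a list with the result data frame(s) and the paths
#'   written.
#' @export
run_experiment <- function(figure_id, scale = c("desk", "full"),
                           overrides = list(), out_dir = tempfile("repgame-"),
                           seed = 1L) {
  scale <- match.arg(scale)
  valid <- c("fig1_vn", "fig1_moore", "fig2_snapshots", "fig3_retention",
             "fig4_thresholds", "fig5_er_pdg", "fig5_sdg")
  if (!figure_id %in% valid) {
    stop("unknown figure_id: ", figure_id, "; must be one of ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- utils::modifyList(experiment_scale(scale), overrides)
  driver <- switch(figure_id,
                   fig1_vn = ,
                   fig1_moore = experiment_fig1,
                   fig2_snapshots = experiment_fig2,
                   fig3_retention = experiment_fig3,
                   fig4_thresholds = experiment_fig4,
                   fig5_er_pdg = experiment_fig5_er,
                   fig5_sdg = experiment_fig5_sdg)
  res <- driver(figure_id, sc, out_dir, seed)
  manifest <- list(figure_id = figure_id, scale = scale, seed = seed,
                   parameters = sc[!vapply(sc, is.function, logical(1))],
                   replicate_seeds = res$seeds,
                   files = res$files)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(res, list(manifest = manifest_path, out_dir = out_dir)))
}

base_config <- function(sc, game, top, delta, alpha, seed) {
  simulation_config(game = game, topology = top, delta = delta,
                    alpha = alpha,
                    n_steps = sc$n_steps, averaging_window = sc$window,
                    n_replicates = sc$n_reps, seed = seed)
}

experiment_fig1 <- function(figure_id, sc, out_dir, seed) {
  nb <- if (figure_id == "fig1_moore") "moore" else "von_neumann"
  top <- build_lattice(sc$side, nb)
  alphas <- if (is.null(sc$alpha_values)) c(1, 2, 3) else sc$alpha_values
  rows <- list()
  seeds <- replicate_seeds(seed, sc$n_reps)
  for (a in alphas) {
    for (ratio in sc$ratio_grid) {
      cfg <- base_config(sc, game_spec("weak_pdg", 1.15), top,
                         delta = ratio * a, alpha = a, seed = seed)
      for (r in seq_len(sc$n_reps)) {
        traj <- run_simulation(cfg, seed = seeds[r])
        ss <- steady_state_average(list(traj), window = sc$window)$mean
        rows[[length(rows) + 1L]] <- data.frame(
          alpha = a, ratio = ratio, replicate = r, seed = seeds[r],
          rho_c = ss)
      }
    }
  }
  df <- do.call(rbind, rows)
  csv <- file.path(out_dir, paste0(figure_id, "_sweep.csv"))
  utils::write.csv(df, csv, row.names = FALSE)
  agg <- stats::aggregate(rho_c ~ alpha + ratio, df, mean)
  plot_path <- file.path(out_dir, paste0(figure_id, ".pdf"))
  p <- ggplot2::ggplot(agg, ggplot2::aes(x = ratio, y = rho_c,
                                         colour = factor(alpha))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = expression(delta / alpha), y = expression(rho[c]),
                  colour = expression(alpha)) +
    ggplot2::ylim(0, 1) + ggplot2::theme_minimal()
  ggplot2::ggsave(plot_path, p, width = 5, height = 4)
  list(data = df, seeds = seeds, files = c(csv, plot_path))
}

experiment_fig2 <- function(figure_id, sc, out_dir, seed) {
  side <- if (is.null(sc$snap_side)) sc$side else sc$snap_side
  top <- build_lattice(side, "von_neumann")
  t_end <- sc$n_steps
  snap_times <- unique(pmin(c(0L, 5L, 10L, 100L, t_end), t_end))
  seeds <- replicate_seeds(seed, 1L)
  files <- character(0)
  # upper row: time series at delta = 1.5, alpha = 3
  cfg <- base_config(sc, game_spec("weak_pdg", 1.17), top,
                     delta = 1.5, alpha = 3, seed = seed)
  cfg$record_snapshots <- snap_times
  traj <- run_simulation(cfg, seed = seeds[1L])
  for (nm in names(traj$snapshots)) {
    f <- file.path(out_dir, sprintf("snapshot_delta1.5_t%s.png", nm))
    write_snapshot_png(traj$snapshots[[nm]], f)
    files <- c(files, f)
  }
  # lower row: final state across delta
  deltas <- if (is.null(sc$delta_values)) c(0, 0.75, 1.5, 2.25, 3)
            else sc$delta_values
  finals <- list()
  for (d in deltas) {
    cfg <- base_config(sc, game_spec("weak_pdg", 1.17), top,
                       delta = d, alpha = 3, seed = seed)
    cfg$record_snapshots <- t_end
    traj <- run_simulation(cfg, seed = seeds[1L])
    finals[[as.character(d)]] <- traj$snapshots[[as.character(t_end)]]
    f <- file.path(out_dir, sprintf("snapshot_final_delta%g.png", d))
    write_snapshot_png(finals[[as.character(d)]], f)
    files <- c(files, f)
  }
  list(data = NULL, seeds = seeds, files = files, finals = finals)
}

experiment_fig3 <- function(figure_id, sc, out_dir, seed) {
  top <- build_lattice(sc$side, "von_neumann")
  alphas <- if (is.null(sc$alpha_values)) c(1, 2, 4) else sc$alpha_values
  cases <- c(list(list(label = "traditional", delta = 0, alpha = 1)),
             lapply(alphas, function(a)
               list(label = sprintf("alpha=%g", a), delta = 0.75 * a,
                    alpha = a)))
  seeds <- replicate_seeds(seed, 1L)
  rows <- list()
  for (cs in cases) {
    cfg <- base_config(sc, game_spec("weak_pdg", 1.2), top,
                       delta = cs$delta, alpha = cs$alpha, seed = seed)
    traj <- run_simulation(cfg, seed = seeds[1L])
    df <- as.data.frame(traj)
    df$case <- cs$label
    rows[[length(rows) + 1L]] <- df
  }
  df <- do.call(rbind, rows)
  csv <- file.path(out_dir, "fig3_retention.csv")
  utils::write.csv(df, csv, row.names = FALSE)
  long <- df[!is.na(df$rho_cc), ]
  plot_path <- file.path(out_dir, "fig3_retention.pdf")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = step)) +
    ggplot2::geom_line(ggplot2::aes(y = rho_cc, colour = "rho_c->c")) +
    ggplot2::geom_line(ggplot2::aes(y = rho_dd, colour = "rho_d->d")) +
    ggplot2::facet_wrap(~case) +
    ggplot2::labs(x = "t (MCS)", y = "retention rate", colour = NULL) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(plot_path, p, width = 7, height = 5)
  list(data = df, seeds = seeds, files = c(csv, plot_path))
}

experiment_fig4 <- function(figure_id, sc, out_dir, seed) {
  top <- build_lattice(sc$side, "von_neumann")
  alphas <- if (is.null(sc$alpha_values)) c(1, 2, 3) else sc$alpha_values
  ratios <- sc$ratio_grid[sc$ratio_grid > 0]
  rows <- list()
  for (a in alphas) {
    for (ratio in ratios) {
      cfg <- base_config(sc, game_spec("weak_pdg", 1.0), top,
                         delta = ratio * a, alpha = a, seed = seed)
      est <- estimate_extinction_threshold(cfg, sc$b_grid,
                                           n_replicates = sc$n_reps,
                                           seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        alpha = a, ratio = ratio, b_c = est$threshold, open = est$open)
    }
  }
  df <- do.call(rbind, rows)
  csv <- file.path(out_dir, "fig4_thresholds.csv")
  utils::write.csv(df, csv, row.names = FALSE)
  plot_path <- file.path(out_dir, "fig4_thresholds.pdf")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = ratio, y = b_c,
                                        colour = factor(alpha))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = expression(delta / alpha), y = expression(b[c]),
                  colour = expression(alpha)) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(plot_path, p, width = 5, height = 4)
  list(data = df, seeds = replicate_seeds(seed, sc$n_reps),
       files = c(csv, plot_path))
}

experiment_fig5_er <- function(figure_id, sc, out_dir, seed) {
  top <- build_er_graph(sc$er_n, 4, seed = seed)
  deltas <- if (is.null(sc$delta_values)) c(0, 1, 2, 3) else sc$delta_values
  seeds <- replicate_seeds(seed, sc$n_reps)
  rows <- list()
  for (d in deltas) {
    for (b in sc$er_b_grid) {
      cfg <- base_config(sc, game_spec("weak_pdg", b), top,
                         delta = d, alpha = max(d, 1), seed = seed)
      for (r in seq_len(sc$n_reps)) {
        traj <- run_simulation(cfg, seed = seeds[r])
        ss <- steady_state_average(list(traj), window = sc$window)$mean
        rows[[length(rows) + 1L]] <- data.frame(
          delta = d, b = b, replicate = r, seed = seeds[r], rho_c = ss)
      }
    }
  }
  df <- do.call(rbind, rows)
  csv <- file.path(out_dir, "fig5_er_pdg.csv")
  utils::write.csv(df, csv, row.names = FALSE)
  agg <- stats::aggregate(rho_c ~ delta + b, df, mean)
  plot_path <- file.path(out_dir, "fig5_er_pdg.pdf")
  p <- ggplot2::ggplot(agg, ggplot2::aes(x = b, y = rho_c,
                                         colour = factor(delta))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "b", y = expression(rho[c]),
                  colour = expression(delta)) +
    ggplot2::ylim(0, 1) + ggplot2::theme_minimal()
  ggplot2::ggsave(plot_path, p, width = 5, height = 4)
  list(data = df, seeds = seeds, files = c(csv, plot_path))
}

experiment_fig5_sdg <- function(figure_id, sc, out_dir, seed) {
  top <- build_lattice(sc$side, "von_neumann")
  deltas <- if (is.null(sc$delta_values)) c(0, 1, 2, 3) else sc$delta_values
  seeds <- replicate_seeds(seed, sc$n_reps)
  rows <- list()
  for (d in deltas) {
    for (r_par in sc$r_grid) {
      cfg <- base_config(sc, game_spec("snowdrift", r_par), top,
                         delta = d, alpha = max(d, 1), seed = seed)
      for (r in seq_len(sc$n_reps)) {
        traj <- run_simulation(cfg, seed = seeds[r])
        ss <- steady_state_average(list(traj), window = sc$window)$mean
        rows[[length(rows) + 1L]] <- data.frame(
          delta = d, r = r_par, replicate = r, seed = seeds[r], rho_c = ss)
      }
    }
  }
  df <- do.call(rbind, rows)
  csv <- file.path(out_dir, "fig5_sdg.csv")
  utils::write.csv(df, csv, row.names = FALSE)
  agg <- stats::aggregate(rho_c ~ delta + r, df, mean)
  plot_path <- file.path(out_dir, "fig5_sdg.pdf")
  p <- ggplot2::ggplot(agg, ggplot2::aes(x = r, y = rho_c,
                                         colour = factor(delta))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "r", y = expression(rho[c]),
                  colour = expression(delta)) +
    ggplot2::ylim(0, 1) + ggplot2::theme_minimal()
  ggplot2::ggsave(plot_path, p, width = 5, height = 4)
  list(data = df, seeds = seeds, files = c(csv, plot_path))
}

#' Write a lattice strategy snapshot as a PNG
#'
#' Cooperators are drawn green, defectors red.
#'
#' @param grid Integer strategy matrix (1 = C, 0 = D) as stored in a
#'   trajectory's `snapshots`.
#' @param path PNG output path.
#' @return `path`, invisibly.
#' @export
write_snapshot_png <- function(grid, path) {
  stopifnot(is.matrix(grid))
  grDevices::png(path, width = 400, height = 400)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({
    graphics::par(op)
    grDevices::dev.off()
  })
  graphics::image(t(grid[nrow(grid):1, , drop = FALSE]),
                  col = c("red", "green3"), zlim = c(0, 1), axes = FALSE,
                  useRaster = TRUE)
  invisible(path)
}
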