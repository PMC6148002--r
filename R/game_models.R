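#' Specify a two-strategy game
#'
#' The weak prisoner's dilemma is parameterised by the temptation to defect
#' \eqn{b}: mutual cooperation pays \eqn{R = 1}, a defector exploiting a
#' cooperator earns \eqn{T = b}, and both the sucker's payoff and the
#' punishment are zero (\eqn{S = P = 0}), so the dilemma strength is
#' controlled by \eqn{b} alone. The snowdrift game is parameterised by the
#' cost-to-benefit ratio \eqn{r}: \eqn{T = 1 + r}, \eqn{R = 1},
#' \eqn{S = 1 - r}, \eqn{P = 0}, which keeps the ranking
#' \eqn{T > R > S > P} for all \eqn{0 < r < 1}.
#'
#' @param game_kind `"weak_pdg"` or `"snowdrift"`.
#' @param temptation_param \eqn{b} for the weak PDG (typically
#'   \eqn{1 < b < 2}; values outside only raise a warning because threshold
#'   sweeps start at \eqn{b = 1}), \eqn{r} for the snowdrift game
#'   (must satisfy \eqn{0 < r < 1}).
#' @return An object of class `game_spec`.
#' @examples
#' game_spec("weak_pdg", 1.15)
#' game_spec("snowdrift", 0.3)
#' @export
game_spec <- function(game_kind = c("weak_pdg", "snowdrift"),
                      temptation_param) {
  game_kind <- match.arg(game_kind)
  stopifnot(is.numeric(temptation_param), length(temptation_param) == 1L,
            is.finite(temptation_param))
  if (game_kind == "weak_pdg") {
    if (temptation_param < 1 || temptation_param > 2) {
      warning("weak PDG is usually run with 1 <= b <= 2; got b = ",
              temptation_param, call. = FALSE)
    }
  } else {
    if (temptation_param <= 0 || temptation_param >= 1) {
      stop("snowdrift game requires 0 < r < 1", call. = FALSE)
    }
  }
  structure(list(game_kind = game_kind,
                 temptation_param = temptation_param),
            class = "game_spec")
}

#' @export
print.game_spec <- function(x, ...) {
  sym <- if (x$game_kind == "weak_pdg") "b" else "r"
  cat(sprintf("<game_spec> %s, %s = %g\n", x$game_kind, sym,
              x$temptation_param))
  invisible(x)
}

#' Build the focal-player payoff matrix of a game
#'
#' Returns the 2x2 table of payoffs to the focal (row) player, with rows and
#' columns named `"C"` and `"D"`.
#'
#' @param spec A [game_spec()].
#' @return A 2x2 numeric matrix; `m["C", "D"]` is the payoff of a cooperator
#'   facing a defector.
#' @examples
#' build_payoff_matrix(game_spec("weak_pdg", 1.15))
#' @export
build_payoff_matrix <- function(spec) {
  if (!inherits(spec, "game_spec")) stop("spec must be a game_spec",
                                         call. = FALSE)
  p <- spec$temptation_param
  m <- switch(spec$game_kind,
    weak_pdg = matrix(c(1, 0, p, 0), nrow = 2, byrow = TRUE),
    snowdrift = matrix(c(1, 1 - p, 1 + p, 0), nrow = 2, byrow = TRUE),
    stop("unknown game_kind", call. = FALSE))
  dimnames(m) <- list(focal = c("C", "D"), opponent = c("C", "D"))
  m
}

# Reindex a named payoff matrix into the engine's integer coding
# (index s + 1 with s = 0 for D, 1 for C).
payoff_matrix_coded <- function(matrix) {
  ord <- c("D", "C")
  unname(matrix[ord, ord])
}

#' Accumulate per-player total payoffs
#'
#' Each player plays the one-shot game once with every neighbour and collects
#' the sum of focal payoffs: \eqn{P_i = \sum_{j \in N(i)} A(s_i, s_j)}.
#' Payoffs are totals, not degree averages; the degree normalisation enters
#' only inside the adoption probability. Self-play is excluded by
#' construction of the topology.
#'
#' @param strategies Per-player strategies (`"C"`/`"D"` characters or 0/1
#'   integers with 1 = C).
#' @param topology A [build_lattice()] or [build_er_graph()] topology.
#' @param matrix A payoff matrix from [build_payoff_matrix()].
#' @return Numeric vector of total payoffs, one per player.
#' @examples
#' top <- build_lattice(3, "von_neumann")
#' m <- build_payoff_matrix(game_spec("weak_pdg", 1.15))
#' accumulate_payoffs(rep("C", 9), top, m)
#' @export
accumulate_payoffs <- function(strategies, topology, matrix) {
  s <- as_strategy_int(strategies)
  if (length(s) != topology$n_players) {
    stop("strategies and topology have different player counts",
         call. = FALSE)
  }
  accumulate_payoffs_cpp(topology$nbr_flat0, topology$offset, s,
                         payoff_matrix_coded(matrix))
}
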