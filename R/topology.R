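new_topology <- function(nbr, kind, side_length = NA_integer_) {
  n <- length(nbr)
  degree <- lengths(nbr)
  structure(list(
    n_players = n,
    neighbor_lists = nbr,                 # 1-based, per player
    degree = as.integer(degree),
    kind = kind,
    side_length = as.integer(side_length),
    # flat 0-based representation consumed by the compiled engine
    nbr_flat0 = as.integer(unlist(nbr, use.names = FALSE) - 1L),
    offset = as.integer(c(0L, cumsum(degree)))
  ), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("<topology> %s, %d players, mean degree %.2f\n",
              x$kind, x$n_players, mean(x$degree)))
  invisible(x)
}

#' Build a periodic square lattice
#'
#' Players sit on an `side_length` x `side_length` torus (periodic boundaries
#' in both axes), indexed row-major and 1-based. The von Neumann
#' neighbourhood connects the 4 orthogonal neighbours (degree 4); the Moore
#' neighbourhood adds the 4 diagonals (degree 8).
#'
#' @param side_length Lattice side, at least 3 (smaller sides make the
#'   periodic wrap degenerate: neighbours would coincide).
#' @param neighborhood `"von_neumann"` or `"moore"`.
#' @return A `topology` object with `n_players = side_length^2`.
#' @examples
#' build_lattice(10, "von_neumann")
#' @export
build_lattice <- function(side_length,
                          neighborhood = c("von_neumann", "moore")) {
  neighborhood <- match.arg(neighborhood)
  side_length <- as.integer(side_length)
  if (is.na(side_length) || side_length < 3L) {
    stop("side_length must be an integer >= 3", call. = FALSE)
  }
  L <- side_length
  n <- L * L
  idx0 <- 0:(n - 1L)
  row <- idx0 %/% L
  col <- idx0 %% L
  shift <- function(dr, dc) ((row + dr) %% L) * L + ((col + dc) %% L) + 1L
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (neighborhood == "moore") {
    offs <- c(offs, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  }
  cols <- lapply(offs, function(d) shift(d[1L], d[2L]))
  nbr_mat <- do.call(cbind, cols)
  nbr <- lapply(seq_len(n), function(i) nbr_mat[i, ])
  kind <- if (neighborhood == "von_neumann") "lattice_vn" else "lattice_moore"
  new_topology(nbr, kind, side_length = L)
}

#' Build an Erdos-Renyi random graph topology
#'
#' Samples \eqn{G(N, p)} with \eqn{p = \bar{k} / (N - 1)} via
#' [igraph::sample_gnp()]. Because the adoption rule divides by the degree
#' and an isolated player has no model to imitate, isolated vertices are not
#' allowed: each one is repaired by attaching it to a uniformly random other
#' vertex. (At the sizes used here, \eqn{N e^{-\bar{k}}} isolated vertices
#' are expected per draw, so rejection sampling is not viable; the repair
#' perturbs the realised mean degree by well under 1\% at \eqn{\bar{k} = 4}.)
#' The graph is quenched: sampled once and then fixed for a whole run.
#'
#' @param n_players Number of nodes (at least 10).
#' @param mean_degree Target mean degree; `p` is clamped to 1 when
#'   `mean_degree >= n_players - 1`.
#' @param seed Integer seed making the draw reproducible.
#' @return A `topology` object of kind `"er_random"`.
#' @examples
#' top <- build_er_graph(200, 4, seed = 1)
#' mean(top$degree)
#' @export
build_er_graph <- function(n_players, mean_degree, seed) {
  n_players <- as.integer(n_players)
  if (is.na(n_players) || n_players < 10L) {
    stop("n_players must be an integer >= 10", call. = FALSE)
  }
  if (mean_degree <= 0 || mean_degree >= n_players) {
    stop("mean_degree must lie in (0, n_players - 1]", call. = FALSE)
  }
  p <- min(1, mean_degree / (n_players - 1))
  g <- local_seed(seed, {
    gg <- igraph::sample_gnp(n_players, p, directed = FALSE)
    iso <- which(igraph::degree(gg) == 0L)
    for (v in iso) {
      if (igraph::degree(gg, v) > 0L) next   # already repaired as a target
      repeat {
        u <- sample.int(n_players, 1L)
        if (u != v && !igraph::are_adjacent(gg, v, u)) break
      }
      gg <- igraph::add_edges(gg, c(v, u))
    }
    gg
  })
  nbr <- igraph::as_adj_list(g, mode = "all")
  nbr <- lapply(nbr, function(v) sort(as.integer(v)))
  new_topology(nbr, "er_random")
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's stream afterwards.
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Export / import a topology as an edge list
#'
#' Plain-text exchange format: two 0-based integer columns, one undirected
#' edge per line, each unordered pair appearing once.
#'
#' @param topology A `topology` object.
#' @param path File path.
#' @return `write_topology()` returns `path` invisibly; `read_topology()`
#'   returns a `topology` of kind `"imported"`.
#' @export
write_topology <- function(topology, path) {
  el <- topology_edges(topology)
  utils::write.table(el - 1L, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  el <- as.matrix(utils::read.table(path, header = FALSE,
                                    colClasses = "integer")) + 1L
  dimnames(el) <- NULL
  n <- max(el)
  nbr <- vector("list", n)
  for (i in seq_len(n)) nbr[[i]] <- integer(0)
  for (r in seq_len(nrow(el))) {
    a <- el[r, 1L]; b <- el[r, 2L]
    nbr[[a]] <- c(nbr[[a]], b)
    nbr[[b]] <- c(nbr[[b]], a)
  }
  new_topology(lapply(nbr, sort), "imported")
}

# Unique undirected edges (1-based, i < j), one row per edge.
topology_edges <- function(topology) {
  i <- rep.int(seq_len(topology$n_players), topology$degree)
  j <- topology$nbr_flat0 + 1L
  keep <- i < j
  cbind(i[keep], j[keep])
}
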