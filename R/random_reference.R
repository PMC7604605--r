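# Degree-matched random reference networks and small-worldness.

#' Degree-matched random surrogate of a connectome
#'
#' Rewires the topology by repeated double-edge swaps (Maslov-Sneppen),
#' which preserve the number of nodes, the number of edges and the exact
#' degree sequence while randomizing everything else; swaps creating
#' self-loops or multi-edges are rejected. The original edge weights are
#' then reassigned to the rewired edges as a uniformly random permutation,
#' so the weight multiset is conserved exactly.
#'
#' @param x `connectome` object or weight matrix with at least 2 edges.
#' @param swap_multiplier Attempted swaps per edge (default 10).
#' @param seed Optional integer; when given, the surrogate is a
#'   deterministic function of `(x, seed)`.
#' @return Weight matrix of the surrogate network (same dimnames as the
#'   input).
#' @export
matched_random_network <- function(x, swap_multiplier = 10, seed = NULL) {
  w <- as_weight_matrix(x)
  m <- sum(w[upper.tri(w)] > 0)
  if (m < 2L) stop("need at least 2 edges to rewire")
  with_seed(seed, {
    g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected",
                                             diag = FALSE)
    g <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                  niter = swap_multiplier * m))
    el <- igraph::as_edgelist(g, names = FALSE)
    weights <- sample(w[upper.tri(w)][w[upper.tri(w)] > 0])
    out <- matrix(0, nrow(w), ncol(w), dimnames = dimnames(w))
    out[el] <- weights
    out[el[, c(2, 1)]] <- weights
    out
  })
}

#' Small-worldness against a degree-matched random ensemble
#'
#' Computes the normalized clustering coefficient
#' \eqn{\gamma = C_p / \bar C_p^{rand}}, normalized characteristic path
#' length \eqn{\lambda = L_p / \bar L_p^{rand}}, and small-worldness
#' \eqn{\sigma = \gamma/\lambda}, where the reference values are means over
#' `n_random` degree-matched random networks built by
#' [matched_random_network()]. A network with \eqn{\sigma > 1} (much more
#' clustered than random at comparable path length) is considered
#' small-world.
#'
#' @param x `connectome` object or weight matrix.
#' @param n_random Ensemble size (default 100).
#' @param swap_multiplier Passed to [matched_random_network()].
#' @param seed Optional integer seeding the whole ensemble.
#' @return List of class `small_world_result` with elements `gamma`,
#'   `lambda`, `sigma`, `cp`, `lp`, `cp_random`, `lp_random`, `n_random`.
#' @export
small_worldness <- function(x, n_random = 100, swap_multiplier = 10,
                            seed = NULL) {
  w <- as_weight_matrix(x)
  stopifnot(n_random >= 1)
  cp <- clustering_coefficient(w)
  eg <- global_efficiency(w)
  if (eg == 0) stop("small-worldness is undefined for a network with zero global efficiency")
  lp <- 1 / eg
  cps <- numeric(n_random)
  lps <- numeric(n_random)
  with_seed(seed, {
    for (r in seq_len(n_random)) {
      rnd <- matched_random_network(w, swap_multiplier = swap_multiplier)
      cps[r] <- clustering_coefficient(rnd)
      e_r <- global_efficiency(rnd)
      lps[r] <- if (e_r > 0) 1 / e_r else Inf
    }
  })
  cp_rand <- mean(cps)
  lp_rand <- mean(lps)
  if (cp_rand == 0) stop("degenerate null ensemble: mean random clustering is zero")
  gamma <- cp / cp_rand
  lambda <- lp / lp_rand
  structure(list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
                 cp = cp, lp = lp, cp_random = cp_rand, lp_random = lp_rand,
                 n_random = n_random),
            class = "small_world_result")
}

#' @export
print.small_world_result <- function(x, ...) {
  cat(sprintf("small-worldness over %d matched random networks:\n", x$n_random))
  cat(sprintf("  gamma = %.4f  lambda = %.4f  sigma = %.4f\n",
              x$gamma, x$lambda, x$sigma))
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`;
# a NULL seed leaves the caller's RNG stream untouched (and advances it).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
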