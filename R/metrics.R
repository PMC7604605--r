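# Weighted nodal and global graph metrics.
#
# Conventions fixed here for the whole package:
#  * edge length for shortest paths = 1 / w  (stronger connections are
#    shorter), so path lengths are in units of inverse weight;
#  * disconnected pairs have infinite path length and contribute 0 to
#    efficiency (1/Inf = 0);
#  * clustering uses the geometric-mean (Onnela) form with weights
#    normalized by the matrix maximum, so C_i <= 1 and unit-weight graphs
#    are unchanged;
#  * nodes with fewer than 2 neighbors have C_i = 0 and contribute 0 to
#    local efficiency;
#  * characteristic path length is the inverse of global efficiency
#    (harmonic-mean convention), never an arithmetic mean of distances.

as_weight_matrix <- function(x) {
  w <- if (inherits(x, "connectome")) x$weights else as.matrix(x)
  stopifnot(nrow(w) == ncol(w))
  w
}

as_length_graph <- function(w) {
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::E(g)$length <- 1 / igraph::E(g)$weight
  g
}

#' Per-edge lengths for shortest-path computations
#'
#' Maps weights to lengths as `1/w` for `w > 0`; node pairs without a
#' direct connection (and the diagonal) get `Inf`.
#'
#' @param x `connectome` object or weight matrix.
#' @return Square numeric matrix of edge lengths.
#' @export
edge_lengths <- function(x) {
  w <- as_weight_matrix(x)
  len <- ifelse(w > 0, 1 / w, Inf)
  diag(len) <- Inf
  len
}

#' Shortest weighted path lengths between all node pairs
#'
#' Dijkstra distances under the `1/w` edge-length convention; `Inf` for
#' disconnected pairs, 0 on the diagonal.
#'
#' @inheritParams edge_lengths
#' @return Symmetric matrix of path lengths `L_ij`.
#' @export
shortest_path_lengths <- function(x) {
  w <- as_weight_matrix(x)
  g <- as_length_graph(w)
  d <- igraph::distances(g, weights = igraph::E(g)$length,
                         algorithm = "dijkstra")
  dimnames(d) <- dimnames(w)
  d
}

#' Nodal strength
#'
#' Sum of the weights of all connections of each node,
#' \eqn{S_i = \sum_j w_{ij}}.
#'
#' @inheritParams edge_lengths
#' @return Named numeric vector, one value per node.
#' @export
nodal_strength <- function(x) {
  rowSums(as_weight_matrix(x))
}

#' Nodal efficiency
#'
#' Mean inverse shortest path length from each node to all others,
#' \eqn{E_{nod,i} = \frac{1}{N-1}\sum_{j \ne i} 1/L_{ij}}, measuring the
#' node's capacity to exchange information with the rest of the network.
#' Disconnected pairs contribute 0.
#'
#' @inheritParams edge_lengths
#' @return Named numeric vector in `[0, Inf)` (`[0, 1]` for `w <= 1`).
#' @export
nodal_efficiency <- function(x) {
  d <- shortest_path_lengths(x)
  n <- nrow(d)
  if (n < 2L) return(stats::setNames(numeric(n), rownames(d)))
  inv <- 1 / d
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

#' Weighted local clustering coefficient
#'
#' Geometric-mean weighted clustering
#' \eqn{C_i = \sum_{j,h} (\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3} /
#' (k_i(k_i-1))} over ordered neighbor pairs, with weights normalized by
#' the matrix maximum (\eqn{\hat w = w/\max w}) and \eqn{k_i} the number of
#' nonzero connections of node `i`. Nodes with `k < 2` get 0.
#'
#' @inheritParams edge_lengths
#' @return Named numeric vector in `[0, 1]`.
#' @export
local_clustering <- function(x) {
  w <- as_weight_matrix(x)
  n <- nrow(w)
  k <- rowSums(w > 0)
  out <- stats::setNames(numeric(n), rownames(w))
  wmax <- max(w)
  if (wmax == 0) return(out)
  cr <- (w / wmax)^(1 / 3)
  num <- diag(cr %*% cr %*% cr)
  ok <- k >= 2
  out[ok] <- num[ok] / (k[ok] * (k[ok] - 1))
  out
}

#' Betweenness centrality
#'
#' Fraction of all shortest weighted paths in the network passing through
#' each node: \eqn{B_i = \frac{1}{(N-1)(N-2)} \sum_{j \ne h \ne i}
#' \delta_{jh}(i)/\delta_{jh}} over ordered pairs, where
#' \eqn{\delta_{jh}(i)} counts shortest `j`-`h` paths through `i`. Paths
#' are shortest under the `1/w` length convention.
#'
#' @inheritParams edge_lengths
#' @return Named numeric vector in `[0, 1]`.
#' @export
betweenness_centrality <- function(x) {
  w <- as_weight_matrix(x)
  n <- nrow(w)
  out <- stats::setNames(numeric(n), rownames(w))
  if (n < 3L) return(out)
  g <- as_length_graph(w)
  b <- igraph::betweenness(g, weights = igraph::E(g)$length, directed = FALSE)
  # igraph sums over unordered pairs; the ordered-pair sum is twice that
  out[] <- 2 * b / ((n - 1) * (n - 2))
  out
}

#' Global efficiency
#'
#' Average of the nodal efficiencies, \eqn{E_{glob} = \frac{1}{N}\sum_i
#' E_{nod,i}}.
#'
#' @inheritParams edge_lengths
#' @return Scalar.
#' @export
global_efficiency <- function(x) {
  mean(nodal_efficiency(x))
}

#' Node vulnerability
#'
#' Proportional drop in global efficiency when a node and all its
#' connections are removed:
#' \eqn{V_i = (E_{glob} - E_{glob}^{(i)}) / E_{glob}}, with
#' \eqn{E_{glob}^{(i)}} the global efficiency of the remaining
#' \eqn{(N-1)}-node network. Values can be negative when removing a weakly
#' connected node raises the average efficiency; the maximum is 1 (removal
#' disconnects everything).
#'
#' @inheritParams edge_lengths
#' @return Named numeric vector, each value `<= 1`.
#' @export
vulnerability <- function(x) {
  w <- as_weight_matrix(x)
  e_glob <- global_efficiency(w)
  if (e_glob == 0) {
    stop("vulnerability is undefined for a network with zero global efficiency")
  }
  n <- nrow(w)
  v <- stats::setNames(numeric(n), rownames(w))
  for (i in seq_len(n)) {
    e_i <- global_efficiency(w[-i, -i, drop = FALSE])
    v[i] <- (e_glob - e_i) / e_glob
  }
  v
}

#' Local efficiency
#'
#' Average over nodes of the global efficiency of each node's neighborhood
#' subgraph (the subnetwork induced by its neighbors, the node itself
#' excluded): \eqn{E_{loc} = \frac{1}{N}\sum_i E_{glob,i}}. Nodes with
#' fewer than 2 neighbors contribute 0.
#'
#' @inheritParams edge_lengths
#' @return Scalar.
#' @export
local_efficiency <- function(x) {
  w <- as_weight_matrix(x)
  n <- nrow(w)
  if (n == 0L) return(0)
  total <- 0
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    if (length(nb) >= 2L) {
      total <- total + global_efficiency(w[nb, nb, drop = FALSE])
    }
  }
  total / n
}

#' Global clustering coefficient
#'
#' Average of the local clustering coefficients over all nodes,
#' \eqn{C_p = \frac{1}{N}\sum_i C_i}.
#'
#' @inheritParams edge_lengths
#' @return Scalar in `[0, 1]`.
#' @export
clustering_coefficient <- function(x) {
  mean(local_clustering(x))
}

#' Characteristic path length
#'
#' Harmonic-mean path length, defined as the inverse of global efficiency:
#' \eqn{L_p = 1/E_{glob}}. Returns `Inf` for a network with zero global
#' efficiency (no finite paths).
#'
#' @inheritParams edge_lengths
#' @return Scalar in `(0, Inf]`.
#' @export
characteristic_path_length <- function(x) {
  e <- global_efficiency(x)
  if (e == 0) return(Inf)
  1 / e
}

#' All nodal metrics for one subject
#'
#' @param x `connectome` object.
#' @param include_vulnerability Compute vulnerability (needs one network
#'   deletion per node, hence N extra shortest-path sweeps); default `TRUE`.
#' @return data.frame with one row per node: `subject_id`, `node`,
#'   `degree`, `strength`, `nodal_efficiency`, `local_clustering`,
#'   `betweenness`, `vulnerability`.
#' @export
nodal_metrics <- function(x, include_vulnerability = TRUE) {
  w <- as_weight_matrix(x)
  sid <- if (inherits(x, "connectome")) x$subject_id else "subject"
  data.frame(
    subject_id = sid,
    node = rownames(w) %||% as.character(seq_len(nrow(w))),
    degree = rowSums(w > 0),
    strength = nodal_strength(w),
    nodal_efficiency = nodal_efficiency(w),
    local_clustering = local_clustering(w),
    betweenness = betweenness_centrality(w),
    vulnerability = if (include_vulnerability) vulnerability(w) else NA_real_,
    row.names = NULL
  )
}

#' All global metrics for one subject
#'
#' @param x `connectome` object.
#' @param n_random Size of the degree-matched random ensemble for
#'   small-worldness; 0 (default) skips the small-world block.
#' @param seed Optional seed for the random ensemble.
#' @return One-row data.frame: `subject_id`, `global_efficiency`,
#'   `local_efficiency`, `clustering_coefficient`,
#'   `characteristic_path_length`, and when `n_random > 0` also `gamma`,
#'   `lambda`, `sigma`, `cp_random`, `lp_random`.
#' @export
global_metrics <- function(x, n_random = 0, seed = NULL) {
  w <- as_weight_matrix(x)
  sid <- if (inherits(x, "connectome")) x$subject_id else "subject"
  out <- data.frame(
    subject_id = sid,
    global_efficiency = global_efficiency(w),
    local_efficiency = local_efficiency(w),
    clustering_coefficient = clustering_coefficient(w),
    characteristic_path_length = characteristic_path_length(w)
  )
  if (n_random > 0) {
    sw <- small_worldness(x, n_random = n_random, seed = seed)
    out$gamma <- sw$gamma
    out$lambda <- sw$lambda
    out$sigma <- sw$sigma
    out$cp_random <- sw$cp_random
    out$lp_random <- sw$lp_random
  }
  out
}

#' Write nodal and global metrics as one tidy TSV
#'
#' Long format: `subject_id`, `node` (`"GLOBAL"` for network-level rows),
#' `metric`, `value`.
#'
#' @param nodal data.frame from [nodal_metrics()] (possibly row-bound over
#'   subjects), or `NULL`.
#' @param global data.frame from [global_metrics()], or `NULL`.
#' @param path Output TSV path.
#' @export
write_metrics_tsv <- function(nodal = NULL, global = NULL, path) {
  pieces <- list()
  if (!is.null(nodal)) {
    vars <- setdiff(names(nodal), c("subject_id", "node"))
    pieces$nodal <- do.call(rbind, lapply(vars, function(v) {
      data.frame(subject_id = nodal$subject_id, node = nodal$node,
                 metric = v, value = nodal[[v]])
    }))
  }
  if (!is.null(global)) {
    vars <- setdiff(names(global), "subject_id")
    pieces$global <- do.call(rbind, lapply(vars, function(v) {
      data.frame(subject_id = global$subject_id, node = "GLOBAL",
                 metric = v, value = global[[v]])
    }))
  }
  out <- do.call(rbind, pieces)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
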