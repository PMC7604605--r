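# Brute-force reference implementations of the weighted graph metrics,
# independent of the package internals (and of igraph): exhaustive simple
# path enumeration and explicit triple loops. Only feasible for tiny
# graphs; used as the oracle the fast implementations must match.

# Enumerate all simple paths between every ordered node pair and reduce to
# shortest-path length, shortest-path count, and per-intermediate-node
# pass-through counts.
oracle_paths <- function(w, tol = 1e-9) {
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  L <- matrix(Inf, n, n)
  diag(L) <- 0
  count <- matrix(0, n, n)
  through <- array(0, c(n, n, n)) # [j, h, i] = shortest j-h paths via i
  for (j in seq_len(n)) {
    # collect all simple paths from j: list of (nodes, dist) per endpoint
    found <- vector("list", n)
    rec <- function(path, dist) {
      cur <- path[length(path)]
      for (nb in which(w[cur, ] > 0)) {
        if (nb %in% path) next
        d <- dist + len[cur, nb]
        found[[nb]][[length(found[[nb]]) + 1L]] <<- list(path = c(path, nb),
                                                         dist = d)
        rec(c(path, nb), d)
      }
    }
    rec(j, 0)
    for (h in seq_len(n)) {
      if (h == j || length(found[[h]]) == 0L) next
      dists <- vapply(found[[h]], `[[`, 0, "dist")
      dmin <- min(dists)
      L[j, h] <- dmin
      sel <- which(dists <= dmin * (1 + tol) + tol)
      count[j, h] <- length(sel)
      for (s in sel) {
        internal <- setdiff(found[[h]][[s]]$path, c(j, h))
        through[j, h, internal] <- through[j, h, internal] + 1
      }
    }
  }
  list(L = L, count = count, through = through)
}

oracle_strength <- function(w) {
  n <- nrow(w)
  s <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) s[i] <- s[i] + w[i, j]
  s
}

oracle_nodal_efficiency <- function(w, paths = oracle_paths(w)) {
  n <- nrow(w)
  vapply(seq_len(n), function(i) {
    acc <- 0
    for (j in seq_len(n)) {
      if (j != i && is.finite(paths$L[i, j])) acc <- acc + 1 / paths$L[i, j]
    }
    acc / (n - 1)
  }, 0)
}

oracle_global_efficiency <- function(w) {
  mean(oracle_nodal_efficiency(w))
}

oracle_clustering <- function(w) {
  n <- nrow(w)
  wh <- w / max(w)
  vapply(seq_len(n), function(i) {
    k <- sum(w[i, ] > 0)
    if (k < 2) return(0)
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      acc <- acc + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
    }
    acc / (k * (k - 1))
  }, 0)
}

oracle_betweenness <- function(w, paths = oracle_paths(w)) {
  n <- nrow(w)
  vapply(seq_len(n), function(i) {
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == h || j == i || h == i || paths$count[j, h] == 0) next
      acc <- acc + paths$through[j, h, i] / paths$count[j, h]
    }
    acc / ((n - 1) * (n - 2))
  }, 0)
}

oracle_local_efficiency <- function(w) {
  n <- nrow(w)
  total <- 0
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    if (length(nb) >= 2) {
      total <- total + oracle_global_efficiency(w[nb, nb, drop = FALSE])
    }
  }
  total / n
}

oracle_vulnerability <- function(w) {
  eg <- oracle_global_efficiency(w)
  vapply(seq_len(nrow(w)), function(i) {
    (eg - oracle_global_efficiency(w[-i, -i, drop = FALSE])) / eg
  }, 0)
}

# Random symmetric weighted graph on n nodes, edge probability p.
random_weight_matrix <- function(n, p = 0.5, wmin = 0.2, wmax = 2) {
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w))
  on <- stats::runif(length(ut)) < p
  w[ut[on]] <- stats::runif(sum(on), wmin, wmax)
  w + t(w)
}

# Flood-fill (BFS) connected components of an edge list; independent of
# the union-find used by the package.
flood_fill_components <- function(ia, ib, n) {
  comp_node <- rep(NA_integer_, n)
  nodes <- sort(unique(c(ia, ib)))
  cid <- 0L
  for (s in nodes) {
    if (!is.na(comp_node[s])) next
    cid <- cid + 1L
    queue <- s
    comp_node[s] <- cid
    while (length(queue) > 0L) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- c(ib[ia == v], ia[ib == v])
      new <- nb[is.na(comp_node[nb])]
      comp_node[new] <- cid
      queue <- c(queue, new)
    }
  }
  comp_node[ia] # component id per edge
}
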