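# Network-based statistic: permutation inference on connected components
# of edges whose group difference exceeds an initial threshold.

# Union-find with path compression; returns a component id per edge given
# endpoint index vectors. Used both for the observed components and inside
# the permutation loop, where speed matters.
edge_components <- function(ia, ib, n) {
  parent <- seq_len(n)
  find <- function(v) {
    while (parent[v] != v) {
      parent[v] <<- parent[parent[v]]
      v <- parent[v]
    }
    v
  }
  for (e in seq_along(ia)) {
    ra <- find(ia[e])
    rb <- find(ib[e])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(ia, find, integer(1))
}

max_component_extent <- function(ia, ib, n) {
  if (length(ia) == 0L) return(0L)
  comp <- edge_components(ia, ib, n)
  max(tabulate(comp))
}

#' Network-based statistic comparison of two groups
#'
#' Tests every edge with the covariate-adjusted GLM group contrast
#' (`weight ~ group + age + sex`), keeps edges whose one-tailed parametric
#' p-value falls below `initial_p`, extracts connected components of the
#' surviving edges, and assigns each component a family-wise-error
#' corrected p-value by comparing its extent (edge count) against the
#' permutation null distribution of the maximum component extent. The
#' permutation scheme is the same Freedman-Lane residual permutation as
#' [permutation_glm()], with one stream shared between the decrease and
#' increase directions.
#'
#' Edges enter testing when nonzero in at least `edge_inclusion` of the
#' subjects of either group, which keeps near-absent connections from
#' producing unstable edge fits.
#'
#' @param connectomes List of `connectome` objects (one per design row,
#'   same order), or a 3-D array `nodes x nodes x subjects`.
#' @param design [cohort_design()] table.
#' @param initial_p Edge-level threshold on the one-tailed parametric p
#'   (default 0.005); the component-level inference is purely
#'   permutation-based.
#' @param n_perm Number of permutations (default 10000).
#' @param alpha Component significance level used for the `significant`
#'   flag (default 0.05).
#' @param directions Subset of `c("decrease", "increase")`: decrease means
#'   lower weights in the tested (second-level) group.
#' @param edge_inclusion Minimum within-group nonzero fraction for an edge
#'   to be tested (default 0.5).
#' @param seed Optional integer for a reproducible permutation stream.
#' @return List of class `nbs_result` with one entry per direction, each a
#'   list of components (fields `edges` [data.frame `node_a`, `node_b`],
#'   `n_edges`, `n_nodes`, `direction`, `p_value`, `significant`), sorted
#'   by decreasing extent; attributes carry `n_edges_tested`, `initial_p`,
#'   `n_perm`, `alpha`.
#' @export
nbs_compare <- function(connectomes, design, initial_p = 0.005,
                        n_perm = 10000, alpha = 0.05,
                        directions = c("decrease", "increase"),
                        edge_inclusion = 0.5, seed = NULL) {
  stopifnot(initial_p > 0, initial_p <= 1)
  directions <- match.arg(directions, several.ok = TRUE)
  if (is.list(connectomes)) {
    labels <- rownames(connectomes[[1]]$weights)
    arr <- vapply(connectomes, function(ci) as_weight_matrix(ci),
                  matrix(0, length(labels), length(labels)))
  } else {
    arr <- connectomes
    labels <- dimnames(arr)[[1]] %||% as.character(seq_len(dim(arr)[1]))
  }
  n_node <- dim(arr)[1]
  n_subj <- dim(arr)[3]
  dm <- design_matrices(design)
  if (n_subj != nrow(dm$X)) stop("one connectome per design row is required")

  ut <- which(upper.tri(matrix(0, n_node, n_node)), arr.ind = TRUE)
  # subjects x edges matrix of weights
  Y_all <- t(apply(arr, 3, function(w) w[upper.tri(w)]))
  if (n_subj == 1L) Y_all <- matrix(Y_all, nrow = 1L)
  g <- as.numeric(design$group) - 1
  frac1 <- colMeans(Y_all[g == 0, , drop = FALSE] > 0)
  frac2 <- colMeans(Y_all[g == 1, , drop = FALSE] > 0)
  tested <- which(pmax(frac1, frac2) >= edge_inclusion)
  out <- stats::setNames(vector("list", length(directions)), directions)
  if (length(tested) == 0L) {
    return(structure(out, class = "nbs_result", n_edges_tested = 0L,
                     initial_p = initial_p, n_perm = n_perm, alpha = alpha))
  }
  Y <- Y_all[, tested, drop = FALSE]
  ia <- ut[tested, 1]
  ib <- ut[tested, 2]

  obs <- glm_tstats(dm$X, Y, dm$cidx)
  df <- obs$df
  # one-tailed parametric screening thresholds on t
  t_lo <- stats::qt(initial_p, df)        # decrease: t <= t_lo
  t_hi <- stats::qt(1 - initial_p, df)    # increase: t >= t_hi
  supra <- list(decrease = is.finite(obs$t) & obs$t <= t_lo,
                increase = is.finite(obs$t) & obs$t >= t_hi)

  red <- stats::lm.fit(dm$Z, Y)
  fit_red <- red$fitted.values
  res_red <- red$residuals
  max_null <- list(decrease = numeric(n_perm), increase = numeric(n_perm))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n_subj)
      t_b <- glm_tstats(dm$X, fit_red + res_red[idx, , drop = FALSE],
                        dm$cidx)$t
      if ("decrease" %in% directions) {
        keep <- is.finite(t_b) & t_b <= t_lo
        max_null$decrease[b] <- max_component_extent(ia[keep], ib[keep],
                                                     n_node)
      }
      if ("increase" %in% directions) {
        keep <- is.finite(t_b) & t_b >= t_hi
        max_null$increase[b] <- max_component_extent(ia[keep], ib[keep],
                                                     n_node)
      }
    }
  })
  for (dir in directions) {
    keep <- supra[[dir]]
    comps <- list()
    if (any(keep)) {
      cid <- edge_components(ia[keep], ib[keep], n_node)
      ka <- ia[keep]
      kb <- ib[keep]
      tabs <- sort(table(cid), decreasing = TRUE)
      for (cc in names(tabs)) {
        sel <- cid == as.integer(cc)
        extent <- sum(sel)
        p_comp <- (1 + sum(max_null[[dir]] >= extent)) / (1 + n_perm)
        comps[[length(comps) + 1L]] <- list(
          edges = data.frame(node_a = labels[ka[sel]],
                             node_b = labels[kb[sel]],
                             stringsAsFactors = FALSE),
          n_edges = extent,
          n_nodes = length(unique(c(ka[sel], kb[sel]))),
          direction = dir,
          p_value = p_comp,
          significant = p_comp < alpha
        )
      }
    }
    out[[dir]] <- comps
  }
  structure(out, class = "nbs_result", n_edges_tested = length(tested),
            initial_p = initial_p, n_perm = n_perm, alpha = alpha)
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("NBS (initial p < %g, %d permutations, %d edges tested)\n",
              attr(x, "initial_p"), attr(x, "n_perm"),
              attr(x, "n_edges_tested")))
  for (dir in names(x)) {
    cat(sprintf("  %s: %d component(s)\n", dir, length(x[[dir]])))
    for (comp in x[[dir]]) {
      cat(sprintf("    %d edges / %d nodes, p = %.4g%s\n", comp$n_edges,
                  comp$n_nodes, comp$p_value,
                  if (comp$significant) " *" else ""))
    }
  }
  invisible(x)
}

#' Write an NBS result as JSON
#'
#' @param x `nbs_result` from [nbs_compare()].
#' @param path Output file.
#' @export
write_nbs_json <- function(x, path) {
  payload <- list(
    initial_p = attr(x, "initial_p"),
    n_perm = attr(x, "n_perm"),
    alpha = attr(x, "alpha"),
    n_edges_tested = attr(x, "n_edges_tested"),
    components = lapply(names(x), function(dir) {
      lapply(x[[dir]], function(comp) {
        list(direction = comp$direction, n_edges = comp$n_edges,
             n_nodes = comp$n_nodes, p_value = comp$p_value,
             significant = comp$significant,
             edges = comp$edges)
      })
    })
  )
  names(payload$components) <- names(x)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
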