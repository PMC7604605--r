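# Hub identification from betweenness centrality.

#' Identify group-level betweenness hubs
#'
#' Averages nodal betweenness across the subjects of a group and declares
#' a node a hub when its group-mean betweenness is at least one standard
#' deviation above the average betweenness over all nodes (mean and SD
#' taken across nodes, sample SD with `n - 1` denominator). The returned
#' table reports each hub's mean betweenness and mean strength, sorted by
#' descending betweenness with the node label as tie-break.
#'
#' An alternative `mode = "vote"` applies the criterion within each
#' subject and keeps nodes that are hubs in at least `vote_fraction` of
#' subjects.
#'
#' @param betweenness Numeric matrix, subjects x nodes, of nodal
#'   betweenness values (column names are node labels).
#' @param strength Optional matching matrix of nodal strengths; when
#'   given, mean strength is reported alongside.
#' @param n_sd Number of standard deviations above the mean required
#'   (default 1).
#' @param mode `"group_mean"` (default) or `"vote"`.
#' @param vote_fraction Minimum fraction of subjects for `"vote"` mode
#'   (default 0.5).
#' @return data.frame of class `hub_table` with columns `node`,
#'   `mean_betweenness`, `mean_strength` (NA when `strength` missing).
#'   Attribute `degenerate` is `TRUE` when the across-node SD is zero, in
#'   which case no node can qualify and the table is empty.
#' @export
identify_hubs <- function(betweenness, strength = NULL, n_sd = 1,
                          mode = c("group_mean", "vote"),
                          vote_fraction = 0.5) {
  mode <- match.arg(mode)
  betweenness <- as.matrix(betweenness)
  if (nrow(betweenness) < 1L) stop("need at least one subject")
  nodes <- colnames(betweenness) %||% as.character(seq_len(ncol(betweenness)))
  mean_b <- colMeans(betweenness)
  degenerate <- FALSE
  if (mode == "group_mean") {
    sd_b <- stats::sd(mean_b)
    if (sd_b == 0) {
      degenerate <- TRUE
      is_hub <- rep(FALSE, length(mean_b))
    } else {
      is_hub <- mean_b >= mean(mean_b) + n_sd * sd_b
    }
  } else {
    votes <- apply(betweenness, 1, function(b) {
      s <- stats::sd(b)
      if (s == 0) rep(FALSE, length(b)) else b >= mean(b) + n_sd * s
    })
    is_hub <- rowMeans(votes) >= vote_fraction
  }
  mean_s <- if (is.null(strength)) rep(NA_real_, length(mean_b))
            else colMeans(as.matrix(strength))
  out <- data.frame(node = nodes, mean_betweenness = mean_b,
                    mean_strength = mean_s,
                    row.names = NULL)[is_hub, , drop = FALSE]
  out <- out[order(-out$mean_betweenness, out$node), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("hub_table", "data.frame"),
            degenerate = degenerate, n_sd = n_sd, mode = mode)
}

#' Write a hub table as TSV
#'
#' Splits the `"STG.L"`-style node label into region and hemisphere
#' columns, matching the usual hub-table layout.
#'
#' @param x `hub_table` from [identify_hubs()].
#' @param path Output file.
#' @export
write_hub_table <- function(x, path) {
  parts <- strsplit(x$node, ".", fixed = TRUE)
  df <- data.frame(
    region = vapply(parts, `[`, "", 1L),
    hemisphere = vapply(parts, function(p) if (length(p) > 1L) p[2L] else "",
                        ""),
    mean_betweenness = x$mean_betweenness,
    mean_strength = x$mean_strength
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
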