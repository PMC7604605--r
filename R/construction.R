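#' Streamline summary container
#'
#' Per-subject tractography summary sufficient to build a weighted
#' connectome: streamline counts and mean fiber lengths per region pair,
#' and gray-matter volumes per region.
#'
#' @param edges data.frame with columns `node_a`, `node_b` (node labels,
#'   `"STG.L"` style), `count` (streamlines, integer >= 0) and
#'   `mean_length_mm` (mean fiber length, mm, required where `count > 0`).
#' @param volumes data.frame with columns `node` (label) and `volume_mm3`.
#' @return Object of class `streamline_summary`.
#' @export
streamline_summary <- function(edges, volumes) {
  stopifnot(all(c("node_a", "node_b", "count", "mean_length_mm") %in%
                  names(edges)),
            all(c("node", "volume_mm3") %in% names(volumes)))
  if (any(edges$count < 0)) stop("streamline counts must be nonnegative")
  if (any(volumes$volume_mm3 <= 0)) stop("region volumes must be positive")
  structure(list(edges = edges, volumes = volumes),
            class = "streamline_summary")
}

#' Build a weighted connectome from a streamline summary
#'
#' Pairs with fewer than `min_streamlines` streamlines are set to zero to
#' suppress spurious connections; the threshold is applied to the raw count
#' before any correction. Retained pairs are weighted by the corrected
#' streamline density
#' \deqn{w_{ij} = \frac{2}{V_i + V_j} \cdot \frac{n_{ij}}{\bar l_{ij}},}
#' where \eqn{n_{ij}} is the streamline count, \eqn{\bar l_{ij}} the mean
#' fiber length (mm) and \eqn{V_i, V_j} the region volumes (mm^3). The
#' correction compensates the bias of raw counts toward large, close
#' regions. Alternative corrections are exposed through `correction`.
#'
#' @param summary `streamline_summary` object.
#' @param atlas Atlas data.frame; every edge label must appear in
#'   `atlas$label`.
#' @param min_streamlines Minimum raw streamline count to retain a pair
#'   (default 3).
#' @param correction One of `"length_volume"` (default, formula above),
#'   `"length"` (`n/l`), or `"raw"` (count only).
#' @param subject_id Identifier for the resulting connectome.
#' @return `connectome` object (symmetric, zero diagonal).
#' @export
build_connectome <- function(summary, atlas, min_streamlines = 3,
                             correction = c("length_volume", "length", "raw"),
                             subject_id = "subject") {
  correction <- match.arg(correction)
  stopifnot(inherits(summary, "streamline_summary"), min_streamlines >= 0)
  edges <- summary$edges
  vols <- summary$volumes
  unknown <- setdiff(c(edges$node_a, edges$node_b, vols$node), atlas$label)
  if (length(unknown) > 0L) {
    stop("unknown node label(s): ", paste(unique(unknown), collapse = ", "))
  }
  n <- nrow(atlas)
  w <- matrix(0, n, n, dimnames = list(atlas$label, atlas$label))
  keep <- edges$count >= min_streamlines & edges$count > 0 &
    edges$node_a != edges$node_b
  edges <- edges[keep, , drop = FALSE]
  if (nrow(edges) > 0L) {
    ia <- match(edges$node_a, atlas$label)
    ib <- match(edges$node_b, atlas$label)
    val <- as.numeric(edges$count)
    if (correction != "raw") {
      if (anyNA(edges$mean_length_mm) || any(edges$mean_length_mm <= 0)) {
        bad <- which(is.na(edges$mean_length_mm) | edges$mean_length_mm <= 0)[1]
        stop("missing or nonpositive mean length for retained pair ",
             edges$node_a[bad], "-", edges$node_b[bad])
      }
      val <- val / edges$mean_length_mm
    }
    if (correction == "length_volume") {
      va <- vols$volume_mm3[match(edges$node_a, vols$node)]
      vb <- vols$volume_mm3[match(edges$node_b, vols$node)]
      if (anyNA(va) || anyNA(vb)) {
        bad <- which(is.na(va) | is.na(vb))[1]
        stop("missing region volume for retained pair ",
             edges$node_a[bad], "-", edges$node_b[bad])
      }
      val <- val * 2 / (va + vb)
    }
    w[cbind(ia, ib)] <- val
    w[cbind(ib, ia)] <- val
  }
  connectome(w, atlas, subject_id = subject_id)
}

#' Read a streamline summary from its two TSV files
#'
#' @param edge_path TSV with columns `node_a`, `node_b`, `count`,
#'   `mean_length_mm`.
#' @param node_path TSV with columns `node`, `volume_mm3`.
#' @return `streamline_summary` object.
#' @export
read_streamline_summary <- function(edge_path, node_path) {
  streamline_summary(utils::read.delim(edge_path, stringsAsFactors = FALSE),
                     utils::read.delim(node_path, stringsAsFactors = FALSE))
}

#' Write a streamline summary to two TSV files
#'
#' @param summary `streamline_summary` object.
#' @inheritParams read_streamline_summary
#' @export
write_streamline_summary <- function(summary, edge_path, node_path) {
  utils::write.table(summary$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(summary$volumes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(summary)
}
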