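#' The default 82-region parcellation
#'
#' Loads the bundled atlas of 82 gray-matter regions of interest: 68
#' cortical areas (34 Desikan-Killiany regions per hemisphere) plus 14
#' subcortical gray-matter structures (7 per hemisphere). Nodes are ordered
#' with all left-hemisphere regions first, then the right hemisphere, each
#' hemisphere in the same fixed region order, so that node indices are
#' deterministic across subjects.
#'
#' @return A data.frame with one row per region and columns `index`
#'   (0-based node position), `name`, `abbreviation`, `hemisphere`
#'   (`"L"`/`"R"`) and `tissue_class` (`"cortical"`/`"subcortical"`),
#'   plus a `label` column of the form `"STG.L"` used to tag matrix rows.
#' @export
#' @examples
#' atlas <- load_default_atlas()
#' nrow(atlas)           # 82
#' table(atlas$hemisphere)
load_default_atlas <- function() {
  path <- system.file("extdata", "atlas_dk82.tsv", package = "strucnet",
                      mustWork = TRUE)
  read_atlas(path)
}

#' Read an atlas table from TSV
#'
#' @param path TSV file with columns `index`, `name`, `abbreviation`,
#'   `hemisphere`, `tissue_class`.
#' @return Atlas data.frame as in [load_default_atlas()].
#' @export
read_atlas <- function(path) {
  atlas <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("index", "name", "abbreviation", "hemisphere", "tissue_class")
  missing <- setdiff(required, names(atlas))
  if (length(missing) > 0L) {
    stop("atlas table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(atlas[, c("abbreviation", "hemisphere")])) {
    stop("atlas abbreviations must be unique within a hemisphere")
  }
  atlas$label <- paste(atlas$abbreviation, atlas$hemisphere, sep = ".")
  atlas
}

#' Construct a connectome object
#'
#' A connectome is one subject's symmetric, nonnegative, zero-diagonal
#' weighted connectivity matrix together with its node table. Weights are
#' dimensionless connection strengths (e.g. volume- and length-corrected
#' streamline densities).
#'
#' @param weights Square numeric matrix of connection strengths `w_ij`.
#' @param atlas Node table as returned by [load_default_atlas()]; its row
#'   count must equal `nrow(weights)`.
#' @param subject_id Identifier stored with the matrix.
#' @param validate If `TRUE` (default) fail on any structural violation.
#' @return An object of class `connectome`: a list with elements `weights`
#'   (labelled matrix), `atlas` and `subject_id`.
#' @export
connectome <- function(weights, atlas, subject_id = "subject", validate = TRUE) {
  weights <- as.matrix(weights)
  if (nrow(weights) != nrow(atlas)) {
    stop("weights dimension (", nrow(weights), ") does not match atlas size (",
         nrow(atlas), ")")
  }
  dimnames(weights) <- list(atlas$label, atlas$label)
  obj <- structure(list(weights = weights, atlas = atlas,
                        subject_id = subject_id),
                   class = "connectome")
  if (validate) {
    bad <- validate_connectome(obj)
    if (length(bad) > 0L) {
      stop("invalid connectome: ", paste(bad, collapse = "; "))
    }
  }
  obj
}

#' @export
print.connectome <- function(x, ...) {
  nz <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat("connectome '", x$subject_id, "': ", nrow(x$weights), " nodes, ",
      nz, " edges (density ", signif(connectome_density(x), 3), ")\n",
      sep = "")
  invisible(x)
}

#' Validate a connectome's structural invariants
#'
#' Checks symmetry, zero diagonal, nonnegativity and dimension consistency.
#' Violations are reported, not raised, so callers can decide how strict to
#' be (e.g. when screening externally supplied matrices).
#'
#' @param x `connectome` object or bare numeric matrix.
#' @param tol Absolute tolerance for the symmetry and diagonal checks.
#' @return Character vector of human-readable violation descriptions;
#'   empty when the connectome is valid.
#' @export
validate_connectome <- function(x, tol = 1e-12) {
  w <- if (inherits(x, "connectome")) x$weights else as.matrix(x)
  out <- character(0)
  if (nrow(w) != ncol(w)) {
    out <- c(out, sprintf("matrix is not square (%d x %d)", nrow(w), ncol(w)))
    return(out)
  }
  if (inherits(x, "connectome") && nrow(w) != nrow(x$atlas)) {
    out <- c(out, "matrix dimension does not match the node table")
  }
  if (anyNA(w)) {
    out <- c(out, "matrix contains missing values")
  } else {
    asym <- which(abs(w - t(w)) > tol, arr.ind = TRUE)
    asym <- asym[asym[, 1] < asym[, 2], , drop = FALSE]
    if (nrow(asym) > 0L) {
      out <- c(out, sprintf("asymmetric at %d node pair(s), e.g. [%d,%d]",
                            nrow(asym), asym[1, 1], asym[1, 2]))
    }
    if (any(abs(diag(w)) > tol)) {
      out <- c(out, "diagonal has nonzero entries")
    }
    if (any(w < 0)) {
      out <- c(out, sprintf("%d negative weight(s)", sum(w < 0)))
    }
  }
  out
}

#' @rdname connectome_density
#' @export
n_nodes <- function(x) nrow(x$weights)

#' Density of a connectome
#'
#' Fraction of the `N(N-1)/2` distinct node pairs with a nonzero weight.
#'
#' @param x `connectome` object.
#' @return Scalar in `[0, 1]`.
#' @export
connectome_density <- function(x) {
  w <- x$weights
  ut <- upper.tri(w)
  sum(w[ut] > 0) / sum(ut)
}
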