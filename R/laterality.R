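# fMRI laterality index of the frontal language area.

#' Laterality index from left/right activated voxel counts
#'
#' \eqn{LI = (L - R)/(L + R)}, ranging from -1 (fully right-lateralized)
#' to 1 (fully left-lateralized), where `L` and `R` are the numbers of
#' activated voxels in homologous left- and right-hemisphere regions of
#' interest.
#'
#' @param L,R Nonnegative voxel counts (vectorized).
#' @return Numeric in `[-1, 1]`.
#' @export
laterality_index <- function(L, R) {
  if (any(L < 0) || any(R < 0)) stop("voxel counts must be nonnegative")
  if (any(L + R == 0)) stop("laterality index undefined when L + R = 0")
  (L - R) / (L + R)
}

#' Classify hemispheric language lateralization
#'
#' `"typical"` (left-lateralized) when `LI >= 0.2`, `"atypical"`
#' otherwise.
#'
#' @param li Laterality index values in `[-1, 1]`.
#' @return Character vector of `"typical"` / `"atypical"`.
#' @export
classify_lateralization <- function(li) {
  if (any(li < -1 | li > 1)) stop("laterality index must lie in [-1, 1]")
  ifelse(li >= 0.2, "typical", "atypical")
}

#' Cohort lateralization summary
#'
#' Computes per-subject laterality indices and classifications and
#' summarizes the cohort: counts and percentages per class (percentages
#' rounded to one decimal) and mean +/- SD of LI within each class.
#'
#' @param records data.frame with columns `subject_id`, `left_voxels`,
#'   `right_voxels`.
#' @return List with `records` (input plus `li` and `classification`
#'   columns) and `summary` (one row per class: `classification`, `n`,
#'   `percent`, `mean_li`, `sd_li`).
#' @export
cohort_lateralization_summary <- function(records) {
  stopifnot(all(c("subject_id", "left_voxels", "right_voxels") %in%
                  names(records)), nrow(records) >= 1L)
  records$li <- laterality_index(records$left_voxels, records$right_voxels)
  records$classification <- classify_lateralization(records$li)
  classes <- c("typical", "atypical")
  n <- vapply(classes, function(cl) sum(records$classification == cl), 0L)
  summary <- data.frame(
    classification = classes,
    n = n,
    percent = round(100 * n / nrow(records), 1),
    mean_li = vapply(classes, function(cl) {
      v <- records$li[records$classification == cl]
      if (length(v)) mean(v) else NA_real_
    }, 0),
    sd_li = vapply(classes, function(cl) {
      v <- records$li[records$classification == cl]
      if (length(v) > 1L) stats::sd(v) else NA_real_
    }, 0),
    row.names = NULL
  )
  list(records = records, summary = summary)
}
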