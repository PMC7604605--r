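# Permutation inference for a general linear model with nuisance
# covariates (Freedman-Lane scheme) and max-statistic FWE correction.

#' Cohort design table
#'
#' @param subject_id Character vector of subject identifiers.
#' @param group Two-level factor or character; the *second* level is the
#'   tested group (positive statistics mean higher values in that group).
#'   `"control"`/`"patient"` labels are ordered control first.
#' @param age Numeric, years.
#' @param sex Binary: numeric 0/1, or factor/character (coded 0/1 by
#'   alphabetical level order, e.g. `F = 0`, `M = 1`).
#' @return data.frame of class `cohort_design` with columns `subject_id`,
#'   `group` (factor), `age`, `sex` (numeric 0/1).
#' @export
cohort_design <- function(subject_id, group, age, sex) {
  if (!is.factor(group)) {
    lev <- unique(as.character(group))
    if (setequal(lev, c("control", "patient"))) lev <- c("control", "patient")
    group <- factor(as.character(group), levels = sort(lev))
    if (all(c("control", "patient") %in% levels(group))) {
      group <- factor(group, levels = c("control", "patient"))
    }
  }
  if (nlevels(group) != 2L) stop("group must have exactly two levels")
  if (!is.numeric(sex)) sex <- as.numeric(factor(as.character(sex))) - 1
  d <- data.frame(subject_id = as.character(subject_id), group = group,
                  age = as.numeric(age), sex = as.numeric(sex),
                  stringsAsFactors = FALSE)
  if (anyNA(d)) stop("cohort design contains missing values")
  class(d) <- c("cohort_design", "data.frame")
  d
}

# Full and reduced design matrices for y ~ group + age + sex.
design_matrices <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  if (any(table(design$group) < 2L)) {
    stop("need at least 2 subjects per group")
  }
  g <- as.numeric(design$group) - 1
  X <- cbind(intercept = 1, group = g, age = design$age, sex = design$sex)
  list(X = X, Z = X[, -2L, drop = FALSE], cidx = 2L)
}

# t statistics for the column `cidx` of X, for each column of Y.
glm_tstats <- function(X, Y, cidx) {
  n <- nrow(X)
  p <- ncol(X)
  XtXi <- chol2inv(chol(crossprod(X)))
  B <- XtXi %*% crossprod(X, Y)
  res <- Y - X %*% B
  df <- n - p
  sigma2 <- colSums(res^2) / df
  se <- sqrt(sigma2 * XtXi[cidx, cidx])
  list(t = drop(B[cidx, ] / se), sigma2 = sigma2, df = df)
}

# Residual variance indistinguishable from zero at the response's own
# scale means the t statistic is pure rounding noise.
is_degenerate <- function(t, sigma2, values) {
  scale <- colMeans(as.matrix(values)^2)
  !is.finite(t) | sigma2 <= 1e-12 * pmax(scale, .Machine$double.xmin)
}

# Signed statistic used for tail-specific comparisons: larger = more
# extreme in the requested direction.
tail_stat <- function(t, tail) {
  switch(tail, greater = t, less = -t, two.sided = abs(t))
}

#' Permutation test of a group difference with covariates
#'
#' Fits `value ~ group + age + sex` and tests the group contrast by
#' permutation, holding the nuisance covariates fixed via the
#' Freedman-Lane scheme: the residuals of the reduced (covariates-only)
#' model are permuted and added back to its fitted values, and the full
#' model is refit to each surrogate response. The p-value uses the add-one
#' estimator \eqn{p = (1 + \#\{t^* \ge t\})/(1 + n_{perm})}, so it is
#' never exactly zero and the test is valid at any permutation count.
#'
#' @param values Numeric vector, one value per subject (same order as
#'   `design`).
#' @param design [cohort_design()] table.
#' @param n_perm Number of permutations (default 10000).
#' @param tail `"greater"` (tested group higher), `"less"`, or
#'   `"two.sided"`.
#' @param seed Optional integer for a reproducible permutation stream.
#' @return List of class `permutation_test` with `observed_stat` (GLM t
#'   for the group contrast), `p_uncorrected`, `n_perm`, `tail`, `df`.
#' @export
permutation_glm <- function(values, design, n_perm = 10000,
                            tail = c("greater", "less", "two.sided"),
                            seed = NULL) {
  tail <- match.arg(tail)
  values <- as.numeric(values)
  dm <- design_matrices(design)
  n <- nrow(dm$X)
  if (length(values) != n) stop("one value per design row is required")
  if (anyNA(values)) stop("values contain missing entries")
  obs <- glm_tstats(dm$X, cbind(values), dm$cidx)
  if (is_degenerate(obs$t, obs$sigma2, values)) {
    stop("degenerate test: zero residual variance")
  }
  red <- stats::lm.fit(dm$Z, values)
  fit_red <- red$fitted.values
  res_red <- red$residuals
  t_perm <- with_seed(seed, {
    idx <- replicate(n_perm, sample.int(n))
    Ystar <- fit_red + matrix(res_red[idx], n, n_perm)
    glm_tstats(dm$X, Ystar, dm$cidx)$t
  })
  s_obs <- tail_stat(obs$t, tail)
  p <- (1 + sum(tail_stat(t_perm, tail) >= s_obs)) / (1 + n_perm)
  structure(list(observed_stat = obs$t, p_uncorrected = p,
                 n_perm = n_perm, tail = tail, df = obs$df),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("permutation GLM: t = %.4f, p = %.4g (%s, %d permutations)\n",
              x$observed_stat, x$p_uncorrected, x$tail, x$n_perm))
  invisible(x)
}

#' Nodewise permutation comparison with max-statistic FWE correction
#'
#' Runs the Freedman-Lane permutation GLM of [permutation_glm()] at every
#' node with a single shared permutation stream, and corrects for the
#' family of nodal tests by the permutation distribution of the maximum
#' statistic: the FWE-corrected p of node `i` is the proportion of
#' permutations whose maximum (tail-signed) statistic across all nodes
#' meets or exceeds node `i`'s observed statistic. Corrected p-values are
#' therefore never smaller than uncorrected ones.
#'
#' @param values Numeric matrix, subjects x nodes (column names become
#'   node labels).
#' @param design [cohort_design()] table.
#' @param on_degenerate What to do with nodes whose residual variance is
#'   zero (e.g. a metric that is identically zero in every subject):
#'   `"error"` (default) or `"omit"`, which excludes them from the
#'   max-statistic family and reports `NA` for them.
#' @inheritParams permutation_glm
#' @return data.frame with one row per node: `node`, `t_observed`,
#'   `p_uncorrected`, `p_fwe`, `tail`.
#' @export
nodal_comparison <- function(values, design, n_perm = 10000,
                             tail = c("greater", "less", "two.sided"),
                             seed = NULL,
                             on_degenerate = c("error", "omit")) {
  tail <- match.arg(tail)
  on_degenerate <- match.arg(on_degenerate)
  values <- as.matrix(values)
  dm <- design_matrices(design)
  n <- nrow(dm$X)
  if (nrow(values) != n) stop("values must have one row per subject")
  if (anyNA(values)) stop("values contain missing entries")
  all_nodes <- colnames(values) %||% as.character(seq_len(ncol(values)))
  obs_all <- glm_tstats(dm$X, values, dm$cidx)
  degen <- is_degenerate(obs_all$t, obs_all$sigma2, values)
  if (any(degen)) {
    if (on_degenerate == "error") {
      stop("degenerate test: zero residual variance at ",
           sum(degen), " node(s)")
    }
    values <- values[, !degen, drop = FALSE]
    if (ncol(values) == 0L) stop("all nodes are degenerate")
  }
  obs <- glm_tstats(dm$X, values, dm$cidx)
  red <- stats::lm.fit(dm$Z, values)
  fit_red <- as.matrix(red$fitted.values)
  res_red <- as.matrix(red$residuals)
  q <- ncol(values)
  s_obs <- tail_stat(obs$t, tail)
  exceed_unc <- numeric(q)
  exceed_fwe <- numeric(q)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n)
      s_perm <- tail_stat(
        glm_tstats(dm$X, fit_red + res_red[idx, , drop = FALSE], dm$cidx)$t,
        tail)
      exceed_unc <- exceed_unc + (s_perm >= s_obs)
      exceed_fwe <- exceed_fwe + (max(s_perm) >= s_obs)
    }
  })
  res <- data.frame(
    node = all_nodes,
    t_observed = NA_real_,
    p_uncorrected = NA_real_,
    p_fwe = NA_real_,
    tail = tail,
    row.names = NULL
  )
  kept <- if (any(degen)) !degen else rep(TRUE, q)
  res$t_observed[kept] <- obs$t
  res$p_uncorrected[kept] <- (1 + exceed_unc) / (1 + n_perm)
  res$p_fwe[kept] <- (1 + exceed_fwe) / (1 + n_perm)
  res
}
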