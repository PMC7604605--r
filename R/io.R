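# Tabular IO and the end-to-end pipeline.

#' Read a connectome from a labelled square matrix file
#'
#' Accepts TSV (default) or CSV (by extension), with node labels
#' (`"STG.L"` style) as both header row and first column. Labels must
#' match the atlas exactly as a set; rows/columns are reordered to atlas
#' order if needed.
#'
#' @param path Matrix file.
#' @param atlas Atlas data.frame (default: the bundled 82-region atlas).
#' @param subject_id Identifier; defaults to the file name without
#'   extension.
#' @return `connectome` object.
#' @export
read_connectome <- function(path, atlas = load_default_atlas(),
                            subject_id = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                           check.names = FALSE)
  w <- as.matrix(raw)
  if (nrow(w) != ncol(w)) {
    stop("connectome file ", path, " is not square: ", nrow(w), " x ", ncol(w))
  }
  if (!setequal(rownames(w), atlas$label) ||
      !setequal(colnames(w), atlas$label)) {
    bad <- setdiff(unique(c(rownames(w), colnames(w))), atlas$label)
    stop("node labels in ", path, " do not match the atlas",
         if (length(bad)) paste0("; unknown: ",
                                 paste(utils::head(bad, 5), collapse = ", "))
         else "")
  }
  w <- w[atlas$label, atlas$label]
  if (is.null(subject_id)) {
    subject_id <- sub("\\.(tsv|csv|txt)$", "", basename(path),
                      ignore.case = TRUE)
  }
  connectome(w, atlas, subject_id = subject_id)
}

#' Write a connectome as a labelled TSV matrix
#'
#' Full-precision round-trip partner of [read_connectome()].
#'
#' @param x `connectome` object.
#' @param path Output file (TSV, or CSV when the extension is `.csv`).
#' @export
write_connectome <- function(x, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  w <- x$weights
  df <- data.frame(node = rownames(w),
                   format(w, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE)
  names(df)[1] <- ""
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table
#'
#' @param path TSV/CSV with columns `subject_id`, `group`, `age`, `sex`.
#' @return [cohort_design()] table.
#' @export
read_cohort <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- utils::read.table(path, sep = sep, header = TRUE,
                         stringsAsFactors = FALSE)
  cohort_design(d$subject_id, d$group, d$age, d$sex)
}

default_run_config <- function() {
  list(
    n_perm = 10000, alpha = 0.05, initial_p = c(0.005, 0.05),
    n_random = 100, tails = c("less", "greater"),
    include_vulnerability = TRUE, edge_inclusion = 0.5,
    min_streamlines = 3
  )
}

#' Run the full group-analysis pipeline
#'
#' Orchestrates the whole analysis on disk: load or simulate a cohort of
#' connectomes, compute per-subject nodal and global metrics (including
#' small-worldness when `n_random > 0`), compare every global metric and
#' every nodal metric between groups with the covariate-adjusted
#' permutation GLM (nodal tests FWE-corrected), run the network-based
#' statistic at each configured initial threshold, build per-group hub
#' tables, and write a machine-readable manifest.
#'
#' @param config A YAML file path or a list with entries:
#'   \describe{
#'     \item{seed}{integer, required; all stage seeds derive from it.}
#'     \item{output_dir}{output directory, created if absent.}
#'     \item{simulate}{optional list of [simulation_config()] arguments
#'       (everything except `seed`); when present the cohort is simulated.}
#'     \item{connectome_dir, cohort, atlas}{alternative file inputs: a
#'       directory of per-subject matrix files named `<subject_id>.tsv`, a
#'       cohort table, and an optional atlas TSV.}
#'     \item{analysis}{optional overrides of `n_perm`, `alpha`,
#'       `initial_p`, `n_random`, `tails`, `include_vulnerability`,
#'       `edge_inclusion`.}
#'     \item{laterality}{optional CSV of `subject_id`, `left_voxels`,
#'       `right_voxels` to summarize.}
#'   }
#' @return Invisibly, a list with the in-memory results and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config error: a seed is required")
  if (is.null(config$output_dir)) stop("config error: output_dir is required")
  seed <- as.integer(config$seed)
  an <- utils::modifyList(default_run_config(), config$analysis %||% list())
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$simulate)) {
    cfg <- do.call(simulation_config,
                   c(config$simulate, list(seed = seed)))
    sim <- simulate_cohort(cfg)
    connectomes <- sim$connectomes
    design <- sim$design
    atlas <- sim$atlas
  } else {
    for (key in c("connectome_dir", "cohort")) {
      if (is.null(config[[key]])) stop("config error: missing ", key)
      if (!file.exists(config[[key]])) {
        stop("config error: ", key, " path does not exist: ", config[[key]])
      }
    }
    atlas <- if (!is.null(config$atlas)) read_atlas(config$atlas)
             else load_default_atlas()
    design <- read_cohort(config$cohort)
    connectomes <- lapply(design$subject_id, function(sid) {
      path <- file.path(config$connectome_dir, paste0(sid, ".tsv"))
      if (!file.exists(path)) stop("missing connectome file for subject ",
                                   sid, ": ", path)
      read_connectome(path, atlas, subject_id = sid)
    })
  }
  n_subj <- length(connectomes)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- per-subject metrics ------------------------------------------------
  metrics <- run_stage("metrics", {
    nodal <- do.call(rbind, lapply(connectomes, nodal_metrics,
                                   include_vulnerability = an$include_vulnerability))
    global <- do.call(rbind, lapply(seq_along(connectomes), function(s) {
      global_metrics(connectomes[[s]], n_random = an$n_random,
                     seed = (seed + 101L + s) %% .Machine$integer.max)
    }))
    list(nodal = nodal, global = global)
  })
  write_metrics_tsv(metrics$nodal, metrics$global,
                    file.path(out_dir, "subject_metrics.tsv"))

  # --- group comparisons --------------------------------------------------
  global_cmp <- run_stage("global_comparison", {
    vars <- setdiff(names(metrics$global), "subject_id")
    do.call(rbind, lapply(vars, function(v) {
      do.call(rbind, lapply(an$tails, function(tl) {
        r <- permutation_glm(metrics$global[[v]], design, n_perm = an$n_perm,
                             tail = tl, seed = (seed + 211L) %% .Machine$integer.max)
        data.frame(metric = v, tail = tl, t_observed = r$observed_stat,
                   p_uncorrected = r$p_uncorrected)
      }))
    }))
  })
  utils::write.table(global_cmp, file.path(out_dir, "global_comparison.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  nodal_cmp <- run_stage("nodal_comparison", {
    vars <- setdiff(names(metrics$nodal), c("subject_id", "node", "degree"))
    if (!an$include_vulnerability) vars <- setdiff(vars, "vulnerability")
    do.call(rbind, lapply(vars, function(v) {
      m <- matrix(metrics$nodal[[v]], nrow = n_subj, byrow = TRUE,
                  dimnames = list(design$subject_id, atlas$label))
      do.call(rbind, lapply(an$tails, function(tl) {
        r <- nodal_comparison(m, design, n_perm = an$n_perm, tail = tl,
                              seed = (seed + 307L) %% .Machine$integer.max,
                              on_degenerate = "omit")
        cbind(metric = v, r)
      }))
    }))
  })
  utils::write.table(nodal_cmp, file.path(out_dir, "nodal_comparison.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- network-based statistic -------------------------------------------
  nbs_results <- run_stage("nbs", {
    lapply(an$initial_p, function(p0) {
      r <- nbs_compare(connectomes, design, initial_p = p0,
                       n_perm = an$n_perm, alpha = an$alpha,
                       edge_inclusion = an$edge_inclusion,
                       seed = (seed + 401L) %% .Machine$integer.max)
      write_nbs_json(r, file.path(out_dir,
                                  sprintf("nbs_initial_p_%g.json", p0)))
      r
    })
  })

  # --- hubs ---------------------------------------------------------------
  hub_tables <- run_stage("hubs", {
    bet <- matrix(metrics$nodal$betweenness, nrow = n_subj, byrow = TRUE,
                  dimnames = list(design$subject_id, atlas$label))
    str <- matrix(metrics$nodal$strength, nrow = n_subj, byrow = TRUE,
                  dimnames = list(design$subject_id, atlas$label))
    out <- lapply(levels(design$group), function(gl) {
      sel <- design$group == gl
      h <- identify_hubs(bet[sel, , drop = FALSE], str[sel, , drop = FALSE])
      write_hub_table(h, file.path(out_dir, paste0("hubs_", gl, ".tsv")))
      h
    })
    stats::setNames(out, levels(design$group))
  })

  # --- laterality (optional) ---------------------------------------------
  laterality <- NULL
  if (!is.null(config$laterality)) {
    laterality <- run_stage("laterality", {
      rec <- utils::read.csv(config$laterality, stringsAsFactors = FALSE)
      res <- cohort_lateralization_summary(rec)
      utils::write.csv(res$records,
                       file.path(out_dir, "laterality_records.csv"),
                       row.names = FALSE)
      utils::write.csv(res$summary,
                       file.path(out_dir, "laterality_summary.csv"),
                       row.names = FALSE)
      res
    })
  }

  # --- manifest -----------------------------------------------------------
  config_echo <- config
  manifest <- list(
    package = "strucnet",
    version = as.character(utils::packageVersion("strucnet")),
    seed = seed,
    n_subjects = n_subj,
    config = config_echo,
    config_hash = unname(tools::md5sum({
      tf <- tempfile()
      writeLines(yaml::as.yaml(config_echo), tf)
      tf
    })),
    outputs = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(metrics = metrics, global_comparison = global_cmp,
                 nodal_comparison = nodal_cmp, nbs = nbs_results,
                 hubs = hub_tables, laterality = laterality,
                 design = design, output_dir = out_dir))
}
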