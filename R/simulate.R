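# Synthetic connectome cohorts: a shared small-world backbone with
# log-normal weights, multiplicative subject noise, planted group effects
# on a connected edge set, and age/sex covariates.

#' Configuration for a synthetic connectome cohort
#'
#' Defaults emulate the cohort the analysis is designed for: 27 controls
#' and 14 patients on an 82-node small-world backbone (ring lattice with
#' k = 8 neighbors rewired with probability 0.1), heavy-tailed log-normal
#' edge weights scaled so that a whole-brain streamline summary lands near
#' 7,000-8,000 streamlines, multiplicative log-normal subject noise, a
#' 30% weight attenuation planted on a connected 8-edge set in patients,
#' ages near 25 +/- 4 (controls) and 27 +/- 7 (patients) years, and a
#' roughly balanced sex ratio.
#'
#' @param n_controls,n_patients Group sizes.
#' @param n_nodes Number of nodes (82 uses the bundled atlas).
#' @param backbone `"smallworld"` (Watts-Strogatz ring lattice) or
#'   `"random"` (uniform Erdos-Renyi).
#' @param k Ring-lattice neighbor count (even; `"smallworld"` only).
#' @param rewire_p Rewiring probability (`"smallworld"` only).
#' @param density Edge density (`"random"` only).
#' @param weight_meanlog,weight_sdlog Log-normal backbone weight law.
#' @param subject_sdlog SD of the per-subject, per-edge multiplicative
#'   log-normal noise.
#' @param effect_factor Multiplier applied to patient weights on the
#'   effect edges (0.7 = 30% attenuation; 1 = null cohort).
#' @param n_effect_edges Size of the planted connected effect set (used
#'   when `effect_edges` is `NULL` and `effect_factor != 1`).
#' @param effect_edges Optional explicit data.frame (`node_a`, `node_b`
#'   labels) of effect edges; must be backbone edges.
#' @param age_mean_control,age_sd_control,age_mean_patient,age_sd_patient
#'   Age distributions (years, truncated at 18).
#' @param female_p_control,female_p_patient Probability of sex code 1.
#' @param age_slope Optional per-year multiplicative trend on all weights,
#'   `exp(age_slope * (age - 26))`; 0 disables.
#' @param seed Mandatory integer seed.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_controls = 27, n_patients = 14,
                              n_nodes = 82,
                              backbone = c("smallworld", "random"),
                              k = 8, rewire_p = 0.1, density = 0.1,
                              weight_meanlog = log(5.5e-5),
                              weight_sdlog = 0.5,
                              subject_sdlog = 0.2,
                              effect_factor = 0.7, n_effect_edges = 8,
                              effect_edges = NULL,
                              age_mean_control = 25, age_sd_control = 4,
                              age_mean_patient = 27.4, age_sd_patient = 7,
                              female_p_control = 0.556,
                              female_p_patient = 0.571,
                              age_slope = 0, seed) {
  backbone <- match.arg(backbone)
  stopifnot(n_controls >= 1, n_patients >= 1, n_nodes >= 4,
            k %% 2 == 0, k >= 2, rewire_p >= 0, rewire_p <= 1,
            weight_sdlog >= 0, subject_sdlog >= 0, effect_factor > 0,
            n_effect_edges >= 1)
  if (missing(seed)) stop("a seed is required")
  cfg <- as.list(environment())
  class(cfg) <- "simulation_config"
  cfg
}

default_node_table <- function(n_nodes) {
  if (n_nodes == 82L) return(load_default_atlas())
  half <- ceiling(n_nodes / 2)
  hemi <- rep(c("L", "R"), c(half, n_nodes - half))
  abbr <- sprintf("N%02d", c(seq_len(half), seq_len(n_nodes - half)))
  atlas <- data.frame(index = seq_len(n_nodes) - 1L,
                      name = paste("Synthetic region", abbr, hemi),
                      abbreviation = abbr, hemisphere = hemi,
                      tissue_class = "cortical")
  atlas$label <- paste(atlas$abbreviation, atlas$hemisphere, sep = ".")
  atlas
}

# Grow a connected edge set of the requested size by randomly extending a
# node front along backbone edges.
pick_connected_edges <- function(el, n_edges, n_nodes) {
  if (nrow(el) < n_edges) stop("backbone has fewer edges than the effect set")
  adj <- vector("list", n_nodes)
  for (e in seq_len(nrow(el))) {
    adj[[el[e, 1]]] <- c(adj[[el[e, 1]]], e)
    adj[[el[e, 2]]] <- c(adj[[el[e, 2]]], e)
  }
  start <- sample.int(n_nodes, 1)
  while (length(adj[[start]]) == 0L) start <- sample.int(n_nodes, 1)
  nodes <- start
  chosen <- integer(0)
  while (length(chosen) < n_edges) {
    cand <- setdiff(unique(unlist(adj[nodes])), chosen)
    if (length(cand) == 0L) stop("could not grow a connected effect set; backbone component too small")
    e <- if (length(cand) == 1L) cand else sample(cand, 1)
    chosen <- c(chosen, e)
    nodes <- unique(c(nodes, el[e, ]))
  }
  chosen
}

#' Simulate a two-group cohort of weighted connectomes
#'
#' All subjects share one backbone topology with fixed log-normal edge
#' weights; each subject's weights are the backbone weights times
#' independent multiplicative log-normal noise. Patients additionally have
#' their weights multiplied by `effect_factor` on the planted effect
#' edges. The exact modified edges are returned as ground truth.
#'
#' @param cfg [simulation_config()].
#' @return List with `connectomes` (list of `connectome`), `design`
#'   ([cohort_design()] table), `ground_truth` (list: `effect_edges`
#'   data.frame of node labels, `effect_factor`), `atlas` and `config`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  atlas <- default_node_table(cfg$n_nodes)
  with_seed(cfg$seed, {
    g <- if (cfg$backbone == "smallworld") {
      igraph::sample_smallworld(1, cfg$n_nodes, cfg$k / 2, cfg$rewire_p)
    } else {
      igraph::sample_gnp(cfg$n_nodes, cfg$density)
    }
    g <- igraph::simplify(g)
    el <- igraph::as_edgelist(g, names = FALSE)
    m <- nrow(el)
    if (m < 2L) stop("backbone has too few edges; raise density or k")
    w_back <- stats::rlnorm(m, cfg$weight_meanlog, cfg$weight_sdlog)

    if (!is.null(cfg$effect_edges)) {
      ia <- match(cfg$effect_edges$node_a, atlas$label)
      ib <- match(cfg$effect_edges$node_b, atlas$label)
      if (anyNA(ia) || anyNA(ib)) stop("effect edges use unknown node labels")
      key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
      eidx <- match(paste(pmin(ia, ib), pmax(ia, ib)), key)
      if (anyNA(eidx)) stop("effect edge(s) not present in the backbone")
    } else if (cfg$effect_factor != 1) {
      eidx <- pick_connected_edges(el, cfg$n_effect_edges, cfg$n_nodes)
    } else {
      eidx <- integer(0)
    }

    n_total <- cfg$n_controls + cfg$n_patients
    group <- rep(c("control", "patient"), c(cfg$n_controls, cfg$n_patients))
    age <- pmax(18, c(
      stats::rnorm(cfg$n_controls, cfg$age_mean_control, cfg$age_sd_control),
      stats::rnorm(cfg$n_patients, cfg$age_mean_patient, cfg$age_sd_patient)))
    sex <- stats::rbinom(n_total, 1,
                         ifelse(group == "control", cfg$female_p_control,
                                cfg$female_p_patient))
    ids <- sprintf("%s%02d", ifelse(group == "control", "ctrl", "pat"),
                   c(seq_len(cfg$n_controls), seq_len(cfg$n_patients)))
    design <- cohort_design(ids, group, age, sex)

    connectomes <- vector("list", n_total)
    for (s in seq_len(n_total)) {
      w_s <- w_back * stats::rlnorm(m, 0, cfg$subject_sdlog)
      if (group[s] == "patient" && length(eidx) > 0L) {
        w_s[eidx] <- w_s[eidx] * cfg$effect_factor
      }
      if (cfg$age_slope != 0) {
        w_s <- w_s * exp(cfg$age_slope * (age[s] - 26))
      }
      w <- matrix(0, cfg$n_nodes, cfg$n_nodes,
                  dimnames = list(atlas$label, atlas$label))
      w[el] <- w_s
      w[el[, c(2, 1)]] <- w_s
      connectomes[[s]] <- connectome(w, atlas, subject_id = ids[s])
    }
    ground_truth <- list(
      effect_edges = if (length(eidx) > 0L) {
        data.frame(node_a = atlas$label[el[eidx, 1]],
                   node_b = atlas$label[el[eidx, 2]],
                   stringsAsFactors = FALSE)
      } else {
        data.frame(node_a = character(0), node_b = character(0))
      },
      effect_factor = cfg$effect_factor
    )
    list(connectomes = connectomes, design = design,
         ground_truth = ground_truth, atlas = atlas, config = cfg)
  })
}

#' Emit a streamline summary consistent with a connectome
#'
#' Inverts the length/volume weight correction: draws region volumes
#' (log-normal around 8,000 mm^3) and pair mean fiber lengths (uniform
#' 20-100 mm), then sets each pair's streamline count to
#' `round(w * l * (V_i + V_j) / 2)`. Rebuilding a connectome from the
#' result with [build_connectome()] reproduces the input weights up to
#' count rounding; pairs whose implied count falls below the streamline
#' threshold reconstruct to zero, exactly as real sub-threshold
#' connections would.
#'
#' @param x `connectome` object.
#' @param volume_meanlog,volume_sdlog Region-volume law (mm^3).
#' @param length_range Range of pair mean fiber lengths (mm).
#' @param seed Optional integer seed.
#' @return `streamline_summary` object.
#' @export
simulate_streamline_summary <- function(x, volume_meanlog = log(8000),
                                        volume_sdlog = 0.25,
                                        length_range = c(20, 100),
                                        seed = NULL) {
  w <- as_weight_matrix(x)
  labels <- rownames(w)
  with_seed(seed, {
    vols <- data.frame(node = labels,
                       volume_mm3 = stats::rlnorm(nrow(w), volume_meanlog,
                                                  volume_sdlog),
                       stringsAsFactors = FALSE)
    ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
    lens <- stats::runif(nrow(ut), length_range[1], length_range[2])
    va <- vols$volume_mm3[ut[, 1]]
    vb <- vols$volume_mm3[ut[, 2]]
    counts <- round(w[ut] * lens * (va + vb) / 2)
    edges <- data.frame(node_a = labels[ut[, 1]], node_b = labels[ut[, 2]],
                        count = as.integer(counts), mean_length_mm = lens,
                        stringsAsFactors = FALSE)
    streamline_summary(edges, vols)
  })
}
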