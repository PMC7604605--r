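test_that("simulated cohorts are deterministic functions of the seed", {
  cfg <- simulation_config(n_controls = 3, n_patients = 3, n_nodes = 30,
                           k = 4, seed = 5)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(lapply(s1$connectomes, `[[`, "weights"),
                   lapply(s2$connectomes, `[[`, "weights"))
  expect_identical(s1$design, s2$design)
  s3 <- simulate_cohort(simulation_config(n_controls = 3, n_patients = 3,
                                          n_nodes = 30, k = 4, seed = 6))
  expect_false(identical(s1$connectomes[[1]]$weights,
                         s3$connectomes[[1]]$weights))
})

test_that("every simulated connectome is structurally valid and shares topology", {
  sim <- simulate_cohort(simulation_config(n_controls = 4, n_patients = 3,
                                           seed = 19))
  for (cn in sim$connectomes) {
    expect_length(validate_connectome(cn), 0)
  }
  # shared backbone: identical support across subjects
  supports <- lapply(sim$connectomes, function(cn) cn$weights > 0)
  for (s in supports[-1]) expect_identical(s, supports[[1]])
  expect_equal(nrow(sim$design), 7)
  expect_equal(as.character(sim$design$group),
               rep(c("control", "patient"), c(4, 3)))
})

test_that("an attenuation factor of one is a null cohort with empty ground truth", {
  sim <- simulate_cohort(simulation_config(n_controls = 3, n_patients = 3,
                                           n_nodes = 20, k = 4,
                                           effect_factor = 1, seed = 23))
  expect_equal(nrow(sim$ground_truth$effect_edges), 0)
})

test_that("the planted attenuation shows up at the configured strength", {
  sim <- simulate_cohort(simulation_config(n_controls = 20, n_patients = 20,
                                           effect_factor = 0.7, seed = 29))
  gt <- sim$ground_truth$effect_edges
  expect_equal(nrow(gt), 8)
  # planted edges form one connected subgraph
  labels <- rownames(sim$connectomes[[1]]$weights)
  comp <- flood_fill_components(match(gt$node_a, labels),
                                match(gt$node_b, labels), length(labels))
  expect_equal(length(unique(comp)), 1)
  # group-mean weight ratio on effect edges near the attenuation factor
  g <- as.character(sim$design$group)
  mean_w <- function(grp) {
    ws <- sapply(sim$connectomes[g == grp], function(cn)
      mean(cn$weights[cbind(gt$node_a, gt$node_b)]))
    mean(ws)
  }
  ratio <- mean_w("patient") / mean_w("control")
  expect_lt(abs(ratio - 0.7), 0.08)
  # off-effect edges are unchanged between groups on average
  off <- which(sim$connectomes[[1]]$weights > 0, arr.ind = TRUE)
  off <- off[off[, 1] < off[, 2], ]
  keyed <- paste(labels[off[, 1]], labels[off[, 2]])
  off <- off[!(keyed %in% paste(gt$node_a, gt$node_b)) &
               !(keyed %in% paste(gt$node_b, gt$node_a)), ]
  mean_off <- function(grp) {
    mean(sapply(sim$connectomes[g == grp], function(cn)
      mean(cn$weights[off])))
  }
  expect_lt(abs(mean_off("patient") / mean_off("control") - 1), 0.08)
})

test_that("explicit effect edges are honored and validated", {
  base <- simulate_cohort(simulation_config(n_controls = 2, n_patients = 2,
                                            n_nodes = 20, k = 4,
                                            effect_factor = 1, seed = 31))
  w <- base$connectomes[[1]]$weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)[1:3, ]
  labels <- rownames(w)
  eff <- data.frame(node_a = labels[idx[, 1]], node_b = labels[idx[, 2]])
  sim <- simulate_cohort(simulation_config(n_controls = 2, n_patients = 2,
                                           n_nodes = 20, k = 4,
                                           effect_factor = 0.5,
                                           effect_edges = eff, seed = 31))
  expect_equal(sort(paste(sim$ground_truth$effect_edges$node_a,
                          sim$ground_truth$effect_edges$node_b)),
               sort(paste(eff$node_a, eff$node_b)))
  zi <- which(upper.tri(w) & w == 0, arr.ind = TRUE)[1, ]
  bogus <- data.frame(node_a = labels[zi[1]], node_b = labels[zi[2]])
  expect_error(simulate_cohort(simulation_config(
    n_controls = 2, n_patients = 2, n_nodes = 20, k = 4,
    effect_factor = 0.5, effect_edges = bogus, seed = 31)),
    "not present in the backbone")
})

test_that("streamline summaries invert the weight correction up to rounding", {
  sim <- simulate_cohort(simulation_config(n_controls = 1, n_patients = 1,
                                           seed = 37))
  cn <- sim$connectomes[[1]]
  sls <- simulate_streamline_summary(cn, seed = 11)
  expect_length(validate_connectome(cn), 0)
  rebuilt <- build_connectome(sls, sim$atlas)
  w0 <- cn$weights
  w1 <- rebuilt$weights
  # pairs retained after rounding reproduce the weight within the count
  # rounding bound of 0.5 / count
  counts <- matrix(0, nrow(w0), ncol(w0), dimnames = dimnames(w0))
  counts[cbind(sls$edges$node_a, sls$edges$node_b)] <- sls$edges$count
  counts <- counts + t(counts)
  kept <- counts >= 3
  expect_true(all(abs(w1[kept] - w0[kept]) / w0[kept] <=
                    0.5 / (counts[kept] - 0.5) + 1e-12))
  # pairs whose implied count falls below the threshold reconstruct to zero
  expect_true(all(w1[!kept] == 0))
  # zero-weight pairs emit no streamlines at all
  expect_false(any(paste(sls$edges$node_a, sls$edges$node_b) %in%
                     paste(rownames(w0)[which(w0 == 0, arr.ind = TRUE)[, 1]],
                           colnames(w0)[which(w0 == 0, arr.ind = TRUE)[, 2]])))
})
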