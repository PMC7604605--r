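sim_small_cohort <- function(effect_factor, seed, n_controls = 14,
                             n_patients = 10, n_nodes = 30) {
  simulate_cohort(simulation_config(
    n_controls = n_controls, n_patients = n_patients, n_nodes = n_nodes,
    k = 4, rewire_p = 0.1, effect_factor = effect_factor,
    n_effect_edges = 6, seed = seed))
}

test_that("an initial p of 1 yields one component spanning all tested edges", {
  sim <- sim_small_cohort(effect_factor = 1, seed = 61)
  r <- nbs_compare(sim$connectomes, sim$design, initial_p = 1 - 1e-12,
                   n_perm = 20, seed = 2)
  # the shared backbone is connected, so every tested edge joins one component
  expect_length(r$decrease, 1)
  expect_equal(r$decrease[[1]]$n_edges, attr(r, "n_edges_tested"))
})

test_that("lowering the initial threshold never grows a component", {
  sim <- sim_small_cohort(effect_factor = 0.7, seed = 62)
  r_strict <- nbs_compare(sim$connectomes, sim$design, initial_p = 0.005,
                          n_perm = 50, seed = 3)
  r_loose <- nbs_compare(sim$connectomes, sim$design, initial_p = 0.05,
                         n_perm = 50, seed = 3)
  n_strict <- sum(vapply(r_strict$decrease, `[[`, 0, "n_edges"))
  n_loose <- sum(vapply(r_loose$decrease, `[[`, 0, "n_edges"))
  expect_lte(n_strict, n_loose) # supra-threshold edge sets are nested
  # and every strict supra-threshold edge is also loose supra-threshold
  key <- function(res) unlist(lapply(res, function(comp)
    paste(pmin(comp$edges$node_a, comp$edges$node_b),
          pmax(comp$edges$node_a, comp$edges$node_b))))
  expect_true(all(key(r_strict$decrease) %in% key(r_loose$decrease)))
})

test_that("component extraction agrees with a flood-fill oracle", {
  set.seed(77)
  for (rep in 1:20) {
    n <- 15
    m <- sample(4:20, 1)
    ia <- sample(n, m, replace = TRUE)
    ib <- sample(n, m, replace = TRUE)
    keep <- ia != ib
    ia <- ia[keep]; ib <- ib[keep]
    if (length(ia) == 0) next
    got <- strucnet:::edge_components(ia, ib, n)
    want <- flood_fill_components(ia, ib, n)
    # same partition up to component relabeling
    expect_equal(unname(table(table(got))), unname(table(table(want))))
    expect_true(all(outer(got, got, "==") == outer(want, want, "==")))
    expect_equal(strucnet:::max_component_extent(ia, ib, n),
                 max(tabulate(want)))
  }
})

test_that("a planted connected attenuation is recovered as a significant component", {
  sim <- sim_small_cohort(effect_factor = 0.7, seed = 63, n_controls = 27,
                          n_patients = 14)
  r <- nbs_compare(sim$connectomes, sim$design, initial_p = 0.005,
                   n_perm = 200, seed = 4)
  expect_gte(length(r$decrease), 1)
  top <- r$decrease[[1]]
  expect_true(top$significant)
  key <- function(df) paste(pmin(df$node_a, df$node_b),
                            pmax(df$node_a, df$node_b))
  recovered <- sum(key(sim$ground_truth$effect_edges) %in% key(top$edges))
  expect_gte(recovered, 5) # at least 5 of the 6 planted edges
  expect_equal(top$n_nodes, length(unique(unlist(top$edges))))
})

test_that("NBS results are reproducible and empty results are not errors", {
  sim <- sim_small_cohort(effect_factor = 1, seed = 64)
  r1 <- nbs_compare(sim$connectomes, sim$design, initial_p = 0.001,
                    n_perm = 50, seed = 5)
  r2 <- nbs_compare(sim$connectomes, sim$design, initial_p = 0.001,
                    n_perm = 50, seed = 5)
  expect_identical(r1, r2)
  # absurdly strict inclusion keeps no edge: empty result, not an error
  r_none <- nbs_compare(sim$connectomes, sim$design, initial_p = 0.005,
                        n_perm = 10, edge_inclusion = 1.1, seed = 6)
  expect_equal(attr(r_none, "n_edges_tested"), 0L)
  expect_length(r_none$decrease, 0)
})

test_that("NBS JSON output carries components with node labels", {
  sim <- sim_small_cohort(effect_factor = 0.7, seed = 65)
  r <- nbs_compare(sim$connectomes, sim$design, initial_p = 0.01,
                   n_perm = 50, seed = 7)
  path <- withr::local_tempfile(fileext = ".json")
  write_nbs_json(r, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$initial_p, 0.01)
  expect_named(back$components, c("decrease", "increase"))
  if (length(back$components$decrease) > 0) {
    comp <- back$components$decrease[[1]]
    expect_equal(comp$n_edges, length(comp$edges))
  }
})
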