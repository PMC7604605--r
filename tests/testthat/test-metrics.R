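test_that("canonical closed forms hold exactly on unit-weight graphs", {
  tri <- triangle_w()
  expect_equal(unname(nodal_strength(tri)), rep(2, 3))
  expect_equal(unname(local_clustering(tri)), rep(1, 3))
  expect_equal(global_efficiency(tri), 1)
  expect_equal(characteristic_path_length(tri), 1)
  expect_equal(clustering_coefficient(tri), 1)

  p3 <- path3_w()
  expect_equal(unname(local_clustering(p3)), rep(0, 3))
  expect_equal(unname(betweenness_centrality(p3)), c(0, 1, 0))

  star <- star_w(3)
  expect_equal(unname(nodal_efficiency(star)), c(1, 2/3, 2/3, 2/3))
  expect_equal(global_efficiency(star), 0.75)
  expect_equal(characteristic_path_length(star), 4/3)
  expect_equal(unname(vulnerability(star))[1], 1) # center removal disconnects
  expect_equal(local_efficiency(star), 0)         # leaf neighborhoods are single nodes

  k4 <- complete_w(4)
  expect_equal(unname(betweenness_centrality(k4)), rep(0, 4))
  v4 <- unname(vulnerability(k4))
  expect_true(all(abs(v4 - v4[1]) < 1e-12)) # symmetry
  expect_equal(local_efficiency(complete_w(3)), 1)
})

test_that("edge lengths are reciprocal weights and absent for zero weights", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 4
  w[2, 3] <- w[3, 2] <- 1
  len <- edge_lengths(w)
  expect_equal(len[1, 2], 0.25)
  expect_equal(len[2, 3], 1)
  expect_equal(len[1, 3], Inf)
  expect_equal(len[1, 1], Inf)
})

test_that("every metric matches the brute-force oracle on random small graphs", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    w <- random_weight_matrix(n, p = runif(1, 0.3, 0.7))
    if (max(w) == 0) next
    paths <- oracle_paths(w)
    expect_equal(unname(nodal_strength(w)), oracle_strength(w),
                 tolerance = 1e-10)
    expect_equal(unname(shortest_path_lengths(w)), unname(paths$L),
                 tolerance = 1e-10)
    expect_equal(unname(nodal_efficiency(w)),
                 oracle_nodal_efficiency(w, paths), tolerance = 1e-10)
    expect_equal(unname(local_clustering(w)), oracle_clustering(w),
                 tolerance = 1e-10)
    expect_equal(unname(betweenness_centrality(w)),
                 oracle_betweenness(w, paths), tolerance = 1e-10)
    expect_equal(local_efficiency(w), oracle_local_efficiency(w),
                 tolerance = 1e-10)
    if (global_efficiency(w) > 0) {
      expect_equal(unname(vulnerability(w)), oracle_vulnerability(w),
                   tolerance = 1e-10)
    }
  }
})

test_that("aggregate identities tie global metrics to their nodal parts", {
  set.seed(5)
  for (rep in 1:10) {
    w <- random_weight_matrix(8, p = 0.5)
    expect_equal(global_efficiency(w), mean(nodal_efficiency(w)),
                 tolerance = 1e-14)
    expect_equal(clustering_coefficient(w), mean(local_clustering(w)),
                 tolerance = 1e-14)
    eg <- global_efficiency(w)
    if (eg > 0) {
      expect_equal(characteristic_path_length(w) * eg, 1, tolerance = 1e-14)
    }
  }
})

test_that("metric ranges respect their definitions", {
  set.seed(31)
  for (rep in 1:10) {
    w <- random_weight_matrix(8, p = 0.4, wmin = 0.1, wmax = 5)
    expect_true(all(local_clustering(w) >= 0 & local_clustering(w) <= 1))
    expect_true(all(betweenness_centrality(w) >= 0 &
                      betweenness_centrality(w) <= 1))
    expect_true(all(nodal_strength(w) >= 0))
    if (global_efficiency(w) > 0) {
      expect_true(all(vulnerability(w) <= 1))
    }
  }
})

test_that("metrics are invariant under node relabeling", {
  set.seed(17)
  w <- random_weight_matrix(8, p = 0.5)
  perm <- sample(8)
  wp <- w[perm, perm]
  expect_equal(unname(nodal_strength(wp)), unname(nodal_strength(w))[perm])
  expect_equal(unname(nodal_efficiency(wp)),
               unname(nodal_efficiency(w))[perm], tolerance = 1e-12)
  expect_equal(unname(local_clustering(wp)),
               unname(local_clustering(w))[perm], tolerance = 1e-12)
  expect_equal(unname(betweenness_centrality(wp)),
               unname(betweenness_centrality(w))[perm], tolerance = 1e-12)
  expect_equal(global_efficiency(wp), global_efficiency(w),
               tolerance = 1e-12)
  expect_equal(local_efficiency(wp), local_efficiency(w), tolerance = 1e-12)
})

test_that("degenerate networks are handled by the stated conventions", {
  empty <- matrix(0, 4, 4)
  expect_equal(global_efficiency(empty), 0)
  expect_equal(unname(nodal_efficiency(empty)), rep(0, 4))
  expect_equal(characteristic_path_length(empty), Inf)
  expect_error(vulnerability(empty), "zero global efficiency")
  # two components: cross-component pairs contribute 0 to efficiency
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1
  w[3, 4] <- w[4, 3] <- 1
  expect_equal(unname(nodal_efficiency(w)), rep(1/3, 4))
})

test_that("nodal and global metric tables are assembled and written tidily", {
  cn <- toy_connectome(complete_w(4), subject_id = "s1")
  nm <- nodal_metrics(cn)
  expect_equal(nrow(nm), 4)
  expect_equal(nm$node, toy_atlas(4)$label)
  expect_equal(nm$degree, rep(3, 4))
  gm <- global_metrics(cn)
  expect_equal(gm$global_efficiency, 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  long <- write_metrics_tsv(nm, gm, path)
  back <- read.delim(path)
  expect_equal(nrow(back), nrow(long))
  expect_true(all(c("subject_id", "node", "metric", "value") %in% names(back)))
  expect_true("GLOBAL" %in% back$node)
  expect_equal(back$value[back$node == "GLOBAL" &
                            back$metric == "global_efficiency"], 1)
})
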