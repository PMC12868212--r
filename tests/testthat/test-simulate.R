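test_that("generated snapshots are symmetric, binary, zero-diagonal and balanced", {
  g <- generate_dynamic_sbm(sbm_config(n = 50, k = 3, p_in = 0.4, p_out = 0.05,
                                       n_snapshots = 3, rewire = 0.05, seed = 2))
  for (t in 0:2) {
    A <- as.matrix(snapshot(g, t)$adjacency)
    expect_equal(A, t(A))
    expect_equal(diag(A), rep(0, 50))
    expect_true(all(A %in% c(0, 1)))
  }
  expect_equal(as.numeric(table(snapshot(g, 0)$labels)), c(17, 17, 16))
  # balanced case: all blocks equal
  gb <- generate_dynamic_sbm(sbm_config(n = 40, k = 4, n_snapshots = 1, seed = 1))
  expect_equal(as.numeric(table(snapshot(gb, 0)$labels)), rep(10, 4))
})

test_that("zero rewiring and zero drift reproduce identical snapshots", {
  g <- generate_dynamic_sbm(sbm_config(n = 30, k = 2, p_in = 0.4, p_out = 0.05,
                                       n_snapshots = 4, rewire = 0, seed = 5))
  A0 <- as.matrix(snapshot(g, 0)$adjacency)
  for (t in 1:3) expect_equal(as.matrix(snapshot(g, t)$adjacency), A0)
})

test_that("intra-block edge counts concentrate around the binomial mean", {
  g <- generate_dynamic_sbm(sbm_config(n = 200, k = 4, p_in = 0.3, p_out = 0.02,
                                       n_snapshots = 1, rewire = 0, seed = 3))
  A <- as.matrix(snapshot(g, 0)$adjacency)
  lab <- snapshot(g, 0)$labels
  intra <- sum(A[outer(lab, lab, "==")]) / 2
  n_pairs <- 4 * choose(50, 2)
  mu <- n_pairs * 0.3
  sdv <- sqrt(n_pairs * 0.3 * 0.7)
  expect_lt(abs(intra - mu), 3 * sdv)
})

test_that("generation is a deterministic function of the seed", {
  g1 <- generate_dynamic_sbm(sbm_config(n = 40, k = 2, n_snapshots = 3, seed = 9))
  g2 <- generate_dynamic_sbm(sbm_config(n = 40, k = 2, n_snapshots = 3, seed = 9))
  for (t in 0:2) {
    expect_identical(as.matrix(snapshot(g1, t)$adjacency),
                     as.matrix(snapshot(g2, t)$adjacency))
  }
})

test_that("rewiring preserves the edge count and moves the requested fraction", {
  snap <- random_snapshot(40, p = 0.2, seed = 4)
  m <- sum(snap$adjacency) / 2
  for (p in c(0.02, 0.05, 0.10)) {
    rw <- rewire_snapshot(snap, p, seed = 7)
    expect_equal(sum(rw$adjacency) / 2, m)
    changed <- sum(abs(as.matrix(rw$adjacency) - as.matrix(snap$adjacency))) / 2
    expect_equal(changed, 2 * floor(p * m))   # removed + inserted
  }
  expect_identical(rewire_snapshot(snap, 0), snap)
  expect_error(rewire_snapshot(snap, 1), "\\[0, 1\\)")
})

test_that("rewiring a near-complete graph fails loudly", {
  A <- complete_adjacency(6)
  A[1, 2] <- A[2, 1] <- 0
  expect_error(rewire_snapshot(graph_snapshot(A), 0.5, seed = 1), "dense")
})

test_that("explicit edge perturbations change exactly the listed pairs", {
  snap <- random_snapshot(10, p = 0.3, seed = 8)
  edits <- data.frame(i = c(1, 2, 3), j = c(4, 5, 6), delta_w = c(0.5, 0.8, 1.0))
  pert <- apply_edge_perturbations(snap, edits)
  D <- as.matrix(pert$adjacency) - as.matrix(snap$adjacency)
  expect_equal(sum(D[upper.tri(D)] != 0), 3)
  expect_equal(D[1, 4], 0.5); expect_equal(D[2, 5], 0.8); expect_equal(D[3, 6], 1.0)
  expect_equal(D, t(D))
  # Laplacian recomputed from the perturbed snapshot reflects the edits
  dL <- as.matrix(build_laplacian(pert)) - as.matrix(build_laplacian(snap))
  expect_equal(dL[1, 4], -0.5)
  expect_equal(dL[1, 1], 0.5)
  # no-op and invalid edits
  expect_equal(as.matrix(apply_edge_perturbations(snap, data.frame(i = 1, j = 4, delta_w = 0))$adjacency),
               as.matrix(snap$adjacency))
  expect_error(apply_edge_perturbations(snap, data.frame(i = 1, j = 4, delta_w = -99)),
               "negative")
  expect_error(apply_edge_perturbations(snap, data.frame(i = 2, j = 2, delta_w = 1)),
               "distinct")
})

test_that("feature noise has the requested distribution and determinism", {
  X <- matrix(0, 500, 200)
  expect_identical(inject_feature_noise(X, 0), X)
  N1 <- inject_feature_noise(X, 0.1, seed = 3)
  N2 <- inject_feature_noise(X, 0.1, seed = 3)
  expect_identical(N1, N2)
  expect_gt(stats::sd(N1), 0.099)
  expect_lt(stats::sd(N1), 0.101)
})

test_that("membership drift relabels nodes and rewires their edges", {
  g <- generate_dynamic_sbm(sbm_config(n = 60, k = 3, p_in = 0.5, p_out = 0.02,
                                       n_snapshots = 3, rewire = 0, drift = 0.1,
                                       seed = 13))
  l0 <- snapshot(g, 0)$labels
  l2 <- snapshot(g, 2)$labels
  expect_gt(sum(l0 != l2), 0)
  expect_true(all(l2 %in% 0:2))
})
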