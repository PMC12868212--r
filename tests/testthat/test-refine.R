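refine_fixture <- function(n = 10, d = 3, seed = 1) {
  snap <- random_snapshot(n, p = 0.4, seed = seed)
  basis <- spectral_basis(build_laplacian(snap), n)
  set.seed(seed + 100)
  list(snap = snap, basis = basis, X = matrix(rnorm(n * d), n),
       eta = sort(runif(n, -0.5, 1.5)))
}

test_that("refinement is the identity when nothing is penalised", {
  fx <- refine_fixture()
  expect_equal(stability_refine(fx$X, fx$basis, fx$eta, lambda = 0), fx$X)
  expect_equal(stability_refine(fx$X, fx$basis, rep(-0.2, 10), lambda = 5), fx$X,
               tolerance = 1e-12)
  expect_error(stability_refine(fx$X, fx$basis, fx$eta, lambda = -1), "lambda")
})

test_that("a unit-index mode is halved at unit penalty", {
  fx <- refine_fixture()
  eta <- rep(-1, 10); eta[4] <- 1
  Z <- stability_refine(fx$X, fx$basis, eta, lambda = 1)
  co_before <- crossprod(fx$basis$vectors, fx$X)
  co_after <- crossprod(fx$basis$vectors, Z)
  expect_equal(co_after[4, ], co_before[4, ] / 2, tolerance = 1e-10)
  expect_equal(co_after[-4, ], co_before[-4, ], tolerance = 1e-10)
})

test_that("closed-form shrinkage matches a generic numerical minimiser", {
  for (seed in 1:3) {
    fx <- refine_fixture(n = 10, d = 2, seed = seed)
    basis <- spectral_basis(build_laplacian(fx$snap), 6)
    lambda <- 0.8
    obj <- function(zvec) {
      Z <- matrix(zvec, 10)
      co <- crossprod(basis$vectors, Z)
      sum((Z - fx$X)^2) + lambda * sum(pmax(0, fx$eta[1:6]) * rowSums(co^2))
    }
    opt <- stats::optim(as.numeric(fx$X), obj, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-14))
    Z_closed <- stability_refine(fx$X, basis, fx$eta[1:6], lambda)
    expect_equal(matrix(opt$par, 10), Z_closed, tolerance = 1e-6)
  }
})

test_that("refinement is non-expansive and unstable energy decreases in lambda", {
  fx <- refine_fixture(n = 12, d = 4, seed = 5)
  pos <- pmax(0, fx$eta[1:12])
  energy <- function(Z) {
    co <- crossprod(fx$basis$vectors, Z)
    sum(pos * rowSums(co^2))
  }
  prev <- Inf
  for (lambda in c(0, 0.5, 1, 5, 50, 1e6)) {
    Z <- stability_refine(fx$X, fx$basis, fx$eta, lambda)
    expect_lte(norm(Z, "F"), norm(fx$X, "F") + 1e-10)
    en <- energy(Z)
    expect_lte(en, prev + 1e-12)
    prev <- en
  }
  expect_lt(prev, 1e-9)   # energy -> 0 as lambda -> infinity
})

test_that("modularity reproduces the closed-form reference partitions", {
  A2 <- two_triangles_adjacency()
  expect_equal(modularity_score(A2, c(0, 0, 0, 1, 1, 1)), 0.5)
  expect_equal(modularity_score(A2, rep(0, 6)), 0)
  expect_equal(modularity_score(complete_adjacency(4), c(0, 0, 1, 1)), -1 / 6)
  expect_warning(q0 <- modularity_score(matrix(0, 3, 3), c(0, 1, 2)), "empty")
  expect_equal(q0, 0)
})

test_that("modularity agrees with igraph on weighted random graphs", {
  for (seed in 1:5) {
    snap <- random_snapshot(20, p = 0.3, seed = seed)
    A <- as.matrix(snap$adjacency) * matrix(runif(400, 0.5, 2), 20)[1:20, 1:20]
    A <- (A + t(A)) / 2
    part <- sample(0:3, 20, replace = TRUE)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected", weighted = TRUE)
    expect_equal(modularity_score(A, part),
                 igraph::modularity(g, part + 1, weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
  }
})

test_that("exhaustive enumeration bounds the greedy modularity on tiny graphs", {
  fixtures <- list(path3_adjacency(), complete_adjacency(4),
                   two_triangles_adjacency(),
                   as.matrix(random_snapshot(7, 0.35, seed = 3)$adjacency),
                   as.matrix(random_snapshot(8, 0.3, seed = 4)$adjacency))
  for (A in fixtures) {
    n <- nrow(A)
    if (sum(A) == 0) next
    parts <- all_partitions(n)
    qs <- vapply(parts, function(p) modularity_score(A, p), numeric(1))
    q_best <- max(qs)
    snap <- graph_snapshot(A)
    det <- detect_communities(snap, matrix(rnorm(n * 3), n),
                              refinement_config(blend_beta = 1), seed = 1)
    expect_lte(det$Q, q_best + 1e-12)
    # two disjoint triangles: the greedy on the graph itself finds the optimum
    if (identical(dim(A), c(6L, 6L)) && isTRUE(all.equal(A, two_triangles_adjacency()))) {
      expect_equal(det$Q, 0.5)
      expect_equal(q_best, 0.5)
    }
  }
})

test_that("well-separated cliques are recovered exactly", {
  A <- two_cliques_adjacency(5)
  snap <- graph_snapshot(A)
  emb <- rbind(matrix(rnorm(5 * 2, mean = 3), 5),
               matrix(rnorm(5 * 2, mean = -3), 5))
  det <- detect_communities(snap, emb, seed = 1)
  expect_equal(adjusted_rand_index(rep(0:1, each = 5), det$membership), 1)
  # greedy never ends below the all-singletons baseline
  expect_gte(det$Q, modularity_score(A, seq_len(10)))
})

test_that("planted three-block graphs are recovered from spectral embeddings", {
  aris <- sapply(1:5, function(seed) {
    g <- generate_dynamic_sbm(sbm_config(n = 60, k = 3, p_in = 0.5, p_out = 0.02,
                                         n_snapshots = 1, rewire = 0, seed = seed))
    snap <- snapshot(g, 0)
    basis <- spectral_basis(build_laplacian(snap), 4)
    emb <- basis$vectors[, -1] * sqrt(60)
    det <- detect_communities(snap, emb, seed = seed)
    adjusted_rand_index(snap$labels, det$membership)
  })
  expect_gte(mean(aris), 0.95)
})

test_that("clustering is invariant to node order and embedding scale", {
  g <- generate_dynamic_sbm(sbm_config(n = 40, k = 2, p_in = 0.5, p_out = 0.05,
                                       n_snapshots = 1, rewire = 0, seed = 6))
  snap <- snapshot(g, 0)
  basis <- spectral_basis(build_laplacian(snap), 3)
  emb <- basis$vectors[, -1] * sqrt(40)
  base <- detect_communities(snap, emb, seed = 1)$membership
  scaled <- detect_communities(snap, emb * 37, seed = 1)$membership
  expect_equal(adjusted_rand_index(base, scaled), 1)
  perm <- sample(40)
  snap_p <- graph_snapshot(as.matrix(snap$adjacency)[perm, perm])
  perm_m <- detect_communities(snap_p, emb[perm, ], seed = 1)$membership
  expect_equal(adjusted_rand_index(base[perm], perm_m), 1)
})

test_that("all-zero embedding rows fall back to adjacency with a warning", {
  A <- two_cliques_adjacency(4)
  emb <- rbind(matrix(rnorm(4 * 2, mean = 2), 4), matrix(0, 4, 2))
  expect_warning(det <- detect_communities(graph_snapshot(A), emb, seed = 1),
                 "zero")
  expect_equal(adjusted_rand_index(rep(0:1, each = 4), det$membership), 1)
})

test_that("the assignment solver matches brute-force enumeration", {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  for (seed in 1:6) {
    set.seed(seed)
    k <- sample(2:5, 1)
    cost <- matrix(rnorm(k * k), k)
    sol <- fraccomm:::solve_assignment(cost)
    best <- min(vapply(perms(seq_len(k)),
                       function(p) sum(cost[cbind(seq_len(k), p)]), numeric(1)))
    expect_equal(sum(cost[cbind(seq_len(k), sol)]), best, tolerance = 1e-12)
  }
})

test_that("temporal label matching inverts permutations and mints fresh labels", {
  tl <- function(l0, l1) {
    community_timeline(
      tibble::tibble(node = as.character(rep(seq_along(l0), 2)),
                     snapshot = rep(0:1, each = length(l0)),
                     community = c(l0, l1)),
      tibble::tibble(snapshot = 0:1, modularity = c(0.3, 0.3)))
  }
  # identical partitions: identity relabelling
  m1 <- match_communities_over_time(tl(c(0, 0, 1, 1, 2), c(0, 0, 1, 1, 2)))
  expect_equal(m1$assignments$community[6:10], c(0, 0, 1, 1, 2))
  # permuted labels: permutation exactly inverted
  m2 <- match_communities_over_time(tl(c(0, 0, 1, 1, 2), c(2, 2, 0, 0, 1)))
  expect_equal(m2$assignments$community[6:10], c(0, 0, 1, 1, 2))
  # a community present only at t + 1 gets a label unused at t
  m3 <- match_communities_over_time(tl(c(0, 0, 0, 1, 1), c(0, 0, 2, 1, 1)))
  relabeled <- m3$assignments$community[6:10]
  expect_equal(relabeled[c(1, 2, 4, 5)], c(0, 0, 1, 1))
  expect_false(relabeled[3] %in% c(0, 1))
})
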