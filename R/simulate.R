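#' Configuration of the dynamic stochastic block model generator
#'
#' The benchmark generator: `k` planted communities over `n` nodes, edges
#' drawn independently with probability `p_in` inside and `p_out` between
#' blocks, evolved over `n_snapshots` time slices by rewiring a proportion
#' `rewire` of edges at each step (and optionally letting a fraction `drift`
#' of nodes switch community).  Block sizes are balanced (they differ by at
#' most one when `k` does not divide `n`).
#'
#' @param n number of nodes.
#' @param k number of planted communities.
#' @param p_in,p_out within/between-block edge probabilities in `[0, 1]`.
#'   Assortative structure needs `p_in > p_out`; `p_in = p_out` gives a null
#'   model in which the planted labels carry no signal.
#' @param n_snapshots number of time slices `T`.
#' @param rewire proportion of edges rewired per step, in `[0, 1)`.
#' @param drift fraction of nodes re-assigned to a random community per step
#'   (their incident edges are redrawn); 0 disables membership drift.
#' @param feature_dim if positive, emit Gaussian node features with
#'   community-dependent means (see `feature_sep`).
#' @param feature_sep separation of community feature centroids, in units of
#'   the unit noise standard deviation.
#' @param seed integer seed; the whole generation is a deterministic function
#'   of the configuration.
#' @export
sbm_config <- function(n = 200L, k = 4L, p_in = 0.3, p_out = 0.02,
                       n_snapshots = 5L, rewire = 0.05, drift = 0,
                       feature_dim = 0L, feature_sep = 2, seed = 1L) {
  stopifnot(n >= k, k >= 1, p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1,
            n_snapshots >= 1, rewire >= 0, rewire < 1, drift >= 0, drift <= 1)
  structure(list(n = as.integer(n), k = as.integer(k), p_in = p_in,
                 p_out = p_out, n_snapshots = as.integer(n_snapshots),
                 rewire = rewire, drift = drift,
                 feature_dim = as.integer(feature_dim),
                 feature_sep = feature_sep, seed = as.integer(seed)),
            class = "sbm_config")
}

balanced_blocks <- function(n, k) {
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(k) - 1L, times = sizes)
}

#' Generate a dynamic stochastic block model graph
#'
#' Snapshot 0 is drawn from the planted-partition model; each subsequent
#' snapshot is the previous one with a proportion `rewire` of edges rewired
#' uniformly (edge count preserved, no self-loops or duplicates) and, if
#' `drift > 0`, a fraction of nodes moved to a random other community with
#' their incident edges redrawn under the block probabilities.  Per-snapshot
#' ground-truth labels travel with the graph; adjacency is binary (unit
#' weights), symmetric, zero-diagonal.
#'
#' @param config an [sbm_config()].
#' @return a `dynamic_graph` whose snapshots carry `labels` (and `features`
#'   when `feature_dim > 0`).
#' @export
generate_dynamic_sbm <- function(config) {
  stopifnot(inherits(config, "sbm_config"))
  set.seed(config$seed)
  n <- config$n
  labels <- balanced_blocks(n, config$k)
  A <- sample_planted_partition(n, labels, config$p_in, config$p_out)
  features <- NULL
  if (config$feature_dim > 0) {
    centers <- matrix(stats::rnorm(config$k * config$feature_dim), config$k) *
      config$feature_sep
    features <- centers[labels + 1L, , drop = FALSE] +
      matrix(stats::rnorm(n * config$feature_dim), n)
  }
  snaps <- vector("list", config$n_snapshots)
  snaps[[1]] <- graph_snapshot(A, index = 0L, features = features, labels = labels)
  for (t in seq_len(config$n_snapshots - 1L)) {
    prev <- snaps[[t]]
    lab <- prev$labels
    A_t <- prev$adjacency
    if (config$drift > 0) {
      moved <- drift_memberships(A_t, lab, config$drift, config$p_in, config$p_out)
      A_t <- moved$A
      lab <- moved$labels
    }
    snap <- graph_snapshot(A_t, index = t, features = features, labels = lab)
    snaps[[t + 1L]] <- rewire_snapshot(snap, config$rewire,
                                       seed = config$seed + 104729L * t)
  }
  structure(list(snapshots = snaps, node_ids = as.character(seq_len(n) - 1L),
                 n = n, n_snapshots = config$n_snapshots),
            class = "dynamic_graph")
}

sample_planted_partition <- function(n, labels, p_in, p_out) {
  pairs <- utils::combn(n, 2)
  same <- labels[pairs[1, ]] == labels[pairs[2, ]]
  p <- ifelse(same, p_in, p_out)
  on <- stats::runif(ncol(pairs)) < p
  Matrix::sparseMatrix(i = pairs[1, on], j = pairs[2, on], x = 1,
                       dims = c(n, n), symmetric = FALSE) |>
    (\(S) S + Matrix::t(S))()
}

drift_memberships <- function(A, labels, drift, p_in, p_out) {
  n <- nrow(A)
  k <- length(unique(labels))
  n_move <- floor(drift * n)
  if (n_move == 0) return(list(A = A, labels = labels))
  movers <- sample.int(n, n_move)
  A <- as.matrix(A)
  for (v in movers) {
    new_lab <- sample(setdiff(unique(labels), labels[v]), 1)
    labels[v] <- new_lab
    p <- ifelse(labels == labels[v], p_in, p_out)
    row <- as.numeric(stats::runif(n) < p)
    row[v] <- 0
    A[v, ] <- row
    A[, v] <- row
  }
  list(A = methods::as(Matrix::Matrix(A, sparse = TRUE), "CsparseMatrix"),
       labels = labels)
}

#' Rewire a proportion of edges in a snapshot
#'
#' Removes `floor(p * m)` uniformly chosen edges and inserts the same number
#' uniformly at random among the remaining non-edges (no self-loops, no
#' duplicates, never back into a slot just vacated), so the total edge count
#' is invariant and exactly `floor(p * m)` edges move.  Inserted edges have unit weight.
#' Degrees are not preserved; a temporal perturbation, not a null-model swap.
#'
#' @param snapshot a [graph_snapshot()].
#' @param p proportion of edges to rewire, `0 <= p < 1`.
#' @param seed integer seed.
#' @return the perturbed `graph_snapshot` (same index, features, labels).
#' @export
rewire_snapshot <- function(snapshot, p, seed = 1L) {
  if (p < 0 || p >= 1) stop("rewire proportion must be in [0, 1)", call. = FALSE)
  if (p == 0) return(snapshot)
  set.seed(seed)
  A <- snapshot$adjacency
  n <- nrow(A)
  tr <- Matrix::which(Matrix::triu(A, k = 1) != 0, arr.ind = TRUE)
  m <- nrow(tr)
  n_rw <- floor(p * m)
  if (n_rw == 0) return(snapshot)
  max_pairs <- n * (n - 1) / 2
  if (max_pairs - m < n_rw) {
    stop("graph too dense: not enough non-edges to rewire into", call. = FALSE)
  }
  drop_idx <- sample.int(m, n_rw)
  A2 <- as.matrix(A)
  blocked <- matrix(FALSE, n, n)          # removed slots stay vacant
  for (e in drop_idx) {
    A2[tr[e, 1], tr[e, 2]] <- A2[tr[e, 2], tr[e, 1]] <- 0
    blocked[tr[e, 1], tr[e, 2]] <- blocked[tr[e, 2], tr[e, 1]] <- TRUE
  }
  inserted <- 0L
  while (inserted < n_rw) {
    i <- sample.int(n, 1)
    j <- sample.int(n, 1)
    if (i == j || A2[i, j] != 0 || blocked[i, j]) next
    A2[i, j] <- A2[j, i] <- 1
    inserted <- inserted + 1L
  }
  graph_snapshot(A2, index = snapshot$index, features = snapshot$features,
                 labels = snapshot$labels)
}

#' Apply explicit edge perturbations
#'
#' Adds `delta_w` to the (undirected) weight of each listed node pair and
#' rebuilds the snapshot; the Laplacian computed from it reflects the edits.
#'
#' @param snapshot a [graph_snapshot()].
#' @param edits data frame with columns `i`, `j` (1-based node indices,
#'   `i != j`) and `delta_w`; resulting weights must stay non-negative.
#' @return the perturbed `graph_snapshot`.
#' @export
apply_edge_perturbations <- function(snapshot, edits) {
  edits <- as.data.frame(edits)
  stopifnot(all(c("i", "j", "delta_w") %in% names(edits)))
  if (any(edits$i == edits$j)) stop("edits must reference distinct nodes", call. = FALSE)
  A <- as.matrix(snapshot$adjacency)
  for (row in seq_len(nrow(edits))) {
    i <- edits$i[row]; j <- edits$j[row]; dw <- edits$delta_w[row]
    new_w <- A[i, j] + dw
    if (new_w < 0) {
      stop(sprintf("perturbation drives weight of edge (%d, %d) negative", i, j),
           call. = FALSE)
    }
    A[i, j] <- A[j, i] <- new_w
  }
  graph_snapshot(A, index = snapshot$index, features = snapshot$features,
                 labels = snapshot$labels)
}

#' Add Gaussian noise to a feature matrix
#'
#' @param X numeric matrix.
#' @param sigma noise standard deviation, `>= 0`.
#' @param seed integer seed.
#' @return `X` plus independent `N(0, sigma^2)` noise.
#' @export
inject_feature_noise <- function(X, sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(X)
  set.seed(seed)
  X + matrix(stats::rnorm(length(X), sd = sigma), nrow(X))
}
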