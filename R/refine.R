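#' Stability-aware embedding refinement
#'
#' Shrinks the energy that filtered embeddings carry in unstable eigenmodes.
#' Solves, in closed form, the convex programme
#' `min_Z ||Z - X_hat||_F^2 + lambda * sum_k max(0, eta_k) ||u_k^T Z||^2`:
#' the penalty is a surrogate for maximising the stability margin, active
#' exactly on the modes whose hallucination index is positive.  Per mode the
#' solution is ridge shrinkage `z_k = x_k / (1 + lambda * max(0, eta_k))`;
#' the off-basis residual is untouched.  With `lambda = 0`, or when no mode
#' is unstable, the refinement is the identity.
#'
#' @param X_hat filtered `n x d` embedding matrix.
#' @param basis the [spectral_basis()] the indices were computed on.
#' @param eta hallucination indices: the tibble from
#'   [hallucination_indices()] or a numeric vector of length `r`.
#' @param lambda penalty weight, `>= 0`.
#' @return refined `n x d` matrix.
#' @export
stability_refine <- function(X_hat, basis, eta, lambda) {
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  eta_vec <- if (is.data.frame(eta)) eta$eta else as.numeric(eta)
  if (length(eta_vec) != basis$r) stop("eta must have one entry per retained mode", call. = FALSE)
  X_hat <- as.matrix(X_hat)
  g <- 1 / (1 + lambda * pmax(0, eta_vec))
  U <- basis$vectors
  coef <- crossprod(U, X_hat)
  U %*% (g * coef) + (X_hat - U %*% coef)
}

#' Newman-Girvan modularity of a partition
#'
#' `Q = sum_c [ e_c / m - (d_c / 2m)^2 ]` where `m` is the total edge weight,
#' `e_c` the intra-community weight and `d_c` the community degree sum: the
#' excess of intra-community weight over the degree-preserving random null
#' model.  An empty graph has `Q` defined as 0 (with a warning).
#'
#' @param A symmetric adjacency matrix (zero diagonal).
#' @param partition membership vector of length `n` (any label type).
#' @return scalar `Q` in `[-1, 1]`.
#' @export
modularity_score <- function(A, partition) {
  n <- nrow(A)
  if (length(partition) != n) stop("partition length must equal n", call. = FALSE)
  m <- sum(A) / 2
  if (m == 0) {
    warning("modularity of an empty graph is defined as 0", call. = FALSE)
    return(0)
  }
  deg <- as.numeric(Matrix::rowSums(A))
  Q <- 0
  for (cc in unique(partition)) {
    idx <- which(partition == cc)
    e_c <- sum(A[idx, idx]) / 2
    d_c <- sum(deg[idx])
    Q <- Q + e_c / m - (d_c / (2 * m))^2
  }
  Q
}

#' Clustering configuration for the refinement stage
#'
#' @param lambda refinement penalty weight (see [stability_refine()]).
#' @param knn_k neighbours in the cosine-similarity graph.
#' @param blend_beta weight of the observed adjacency in the blended graph
#'   `beta * A_norm + (1 - beta) * S_norm`.
#' @param method community algorithm on the blended graph: `"fast_greedy"`
#'   (deterministic CNM agglomeration, the default) or `"louvain"`.
#' @export
refinement_config <- function(lambda = 1, knn_k = 10L, blend_beta = 0.5,
                              method = c("fast_greedy", "louvain")) {
  method <- match.arg(method)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  if (blend_beta < 0 || blend_beta > 1) stop("blend_beta must be in [0, 1]", call. = FALSE)
  structure(list(lambda = lambda, knn_k = as.integer(knn_k),
                 blend_beta = blend_beta, method = method),
            class = "refinement_config")
}

#' Extract communities from stabilised embeddings
#'
#' Bridges embeddings and modularity optimisation: builds a cosine-similarity
#' k-nearest-neighbour graph over embedding rows (negative similarities
#' clipped at zero), max-normalises both it and the observed adjacency,
#' blends them as `beta * A + (1 - beta) * S`, and runs greedy agglomerative
#' modularity maximisation (CNM) on the blend.  The reported modularity `Q`
#' is always evaluated on the observed adjacency.  Deterministic for a given
#' input; labels are 0-based, contiguous, in order of first appearance.
#'
#' Nodes with an all-zero embedding row contribute no similarity edges and
#' are clustered through the adjacency term alone (with a warning).
#'
#' @param snapshot a [graph_snapshot()].
#' @param embeddings `n x d` matrix of (refined) node embeddings.
#' @param config a [refinement_config()].
#' @param seed integer seed (the default method is deterministic; the seed
#'   guards optional stochastic methods).
#' @return list with `membership` (0-based integer vector) and `Q`.
#' @export
detect_communities <- function(snapshot, embeddings, config = refinement_config(),
                               seed = 1L) {
  A <- snapshot$adjacency
  n <- nrow(A)
  embeddings <- as.matrix(embeddings)
  if (nrow(embeddings) != n) stop("embeddings must have one row per node", call. = FALSE)
  rn <- sqrt(rowSums(embeddings^2))
  zero_rows <- rn < 1e-12
  if (any(zero_rows)) {
    warning(sprintf("%d all-zero embedding row(s); those nodes are clustered by adjacency only",
                    sum(zero_rows)), call. = FALSE)
  }
  Xn <- embeddings / ifelse(rn > 0, rn, 1)
  S <- tcrossprod(Xn)
  S[S < 0] <- 0
  diag(S) <- 0
  k <- min(config$knn_k, n - 1L)
  # keep each node's k strongest similarities, then symmetrise by max
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    if (zero_rows[i]) next
    ord <- order(S[i, ], decreasing = TRUE)[seq_len(k)]
    keep[i, ord] <- TRUE
  }
  keep <- keep | t(keep)
  S[!keep] <- 0
  S <- pmax(S, t(S))
  A_d <- as.matrix(A)
  a_max <- max(A_d)
  s_max <- max(S)
  blended <- config$blend_beta * (if (a_max > 0) A_d / a_max else A_d) +
    (1 - config$blend_beta) * (if (s_max > 0) S / s_max else S)
  set.seed(seed)
  g <- igraph::graph_from_adjacency_matrix(blended, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) == 0) {
    membership <- seq_len(n)                 # all singletons
  } else {
    cl <- switch(config$method,
      fast_greedy = igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight),
      louvain = igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
    )
    membership <- igraph::membership(cl)
  }
  membership <- relabel_first_seen(as.integer(membership))
  Q <- if (sum(A) > 0) modularity_score(A, membership) else 0
  list(membership = membership, Q = Q)
}

relabel_first_seen <- function(labels) {
  u <- unique(labels)
  match(labels, u) - 1L
}

# ---- temporal label matching ------------------------------------------------

#' Solve the linear assignment problem (Hungarian algorithm)
#'
#' Minimum-cost perfect matching on a square cost matrix via the
#' shortest-augmenting-path Hungarian method with dual potentials, O(k^3).
#'
#' @param cost square numeric cost matrix.
#' @return integer vector `p` with `p[i]` the column assigned to row `i`.
#' @keywords internal
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  k <- nrow(cost)
  if (ncol(cost) != k) stop("cost matrix must be square", call. = FALSE)
  INF <- sum(abs(cost)) + 1
  u <- numeric(k + 1)
  v <- numeric(k + 1)
  p <- integer(k + 1)       # p[j]: row matched to column j (1-based, 0 = none)
  way <- integer(k + 1)
  for (i in seq_len(k)) {
    p[1] <- i
    j0 <- 1L                # column 1 used as the virtual start (index offset)
    minv <- rep(INF, k + 1)
    used <- rep(FALSE, k + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- INF
      j1 <- 0L
      for (j in 2:(k + 1)) {
        if (used[j]) next
        cur <- cost[i0, j - 1] - u[i0 + 0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in 1:(k + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assignment <- integer(k)
  for (j in 2:(k + 1)) if (p[j] > 0) assignment[p[j]] <- j - 1L
  assignment
}

#' Align community labels across snapshots
#'
#' Relabels each snapshot's communities to maximise node overlap with the
#' previous (already aligned) snapshot, by optimal assignment on the
#' contingency matrix.  Communities with no counterpart at the previous step
#' receive fresh labels.  Node-level memberships are unchanged up to
#' renaming.
#'
#' @param timeline a `community_timeline` (see [community_timeline()]).
#' @return the timeline with aligned labels and `matched = TRUE`.
#' @export
match_communities_over_time <- function(timeline) {
  asg <- timeline$assignments
  ts <- sort(unique(asg$snapshot))
  if (length(ts) < 2) {
    timeline$matched <- TRUE
    return(timeline)
  }
  get_labels <- function(t) asg$community[asg$snapshot == t]
  prev <- get_labels(ts[1])
  for (ti in ts[-1]) {
    cur <- get_labels(ti)
    map <- match_labels(prev, cur)
    cur_new <- map[cur + 1L]
    asg$community[asg$snapshot == ti] <- cur_new
    prev <- cur_new
  }
  timeline$assignments <- asg
  timeline$matched <- TRUE
  timeline
}

# Map labels of `cur` onto labels of `prev` maximising overlap; unmatched
# current communities get fresh labels above everything used at `prev`.
match_labels <- function(prev, cur) {
  lp <- sort(unique(prev))
  lc <- sort(unique(cur))
  Cmat <- table(factor(cur, levels = lc), factor(prev, levels = lp))
  k <- max(length(lp), length(lc))
  cost <- matrix(0, k, k)
  cost[seq_along(lc), seq_along(lp)] <- -as.matrix(Cmat)
  sol <- solve_assignment(cost)
  map <- integer(length(lc))
  fresh <- max(lp) + 1L
  for (i in seq_along(lc)) {
    j <- sol[i]
    if (j <= length(lp) && Cmat[i, j] > 0) {
      map[i] <- lp[j]
    } else {
      map[i] <- fresh
      fresh <- fresh + 1L
    }
  }
  stats::setNames(map, lc)[match(lc, lc)]
}

#' Per-snapshot community assignments with quality scores
#'
#' Container for the output of the community stage: a tidy assignment table
#' and per-snapshot modularity.
#'
#' @param assignments tibble `node`, `snapshot`, `community`.
#' @param quality tibble `snapshot`, `modularity`.
#' @param matched whether labels have been aligned across snapshots.
#' @export
community_timeline <- function(assignments, quality, matched = FALSE) {
  structure(list(assignments = tibble::as_tibble(assignments),
                 quality = tibble::as_tibble(quality), matched = matched),
            class = "community_timeline")
}

#' @export
print.community_timeline <- function(x, ...) {
  ncomm <- x$assignments |>
    dplyr::group_by(.data$snapshot) |>
    dplyr::summarise(k = dplyr::n_distinct(.data$community))
  cat(sprintf("<community_timeline> %d snapshots, %s communities, mean Q = %.3f%s\n",
              nrow(x$quality), paste(ncomm$k, collapse = "/"),
              mean(x$quality$modularity),
              if (x$matched) ", labels aligned" else ""))
  invisible(x)
}

#' @export
as_tibble.community_timeline <- function(x, ...) x$assignments
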