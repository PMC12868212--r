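# Small graphs and brute-force oracles used across the suite.

path3_adjacency <- function() {
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 1
  A[2, 3] <- A[3, 2] <- 1
  A
}

complete_adjacency <- function(n) {
  A <- matrix(1, n, n) - diag(n)
  A
}

two_triangles_adjacency <- function() {
  A <- matrix(0, 6, 6)
  for (p in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))) {
    A[p[1], p[2]] <- A[p[2], p[1]] <- 1
  }
  A
}

two_cliques_adjacency <- function(size = 5) {
  n <- 2 * size
  A <- matrix(0, n, n)
  A[seq_len(size), seq_len(size)] <- 1
  A[(size + 1):n, (size + 1):n] <- 1
  diag(A) <- 0
  A
}

random_snapshot <- function(n, p = 0.2, seed = 1) {
  set.seed(seed)
  A <- matrix(0, n, n)
  on <- stats::runif(n * (n - 1) / 2) < p
  A[upper.tri(A)][on] <- 1
  A <- A + t(A)
  graph_snapshot(A)
}

# All set partitions of 1..n as membership vectors (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, k) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(k + 1)) recurse(c(prefix, lab), max(k, lab))
  }
  recurse(integer(0), 0L)
  out
}

# Pair-counting ARI straight from the definition.
brute_ari <- function(truth, pred) {
  n <- length(truth)
  a <- b <- cd <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    st <- truth[i] == truth[j]
    sp <- pred[i] == pred[j]
    if (st && sp) a <- a + 1
    if (st != sp) b <- b + 1
    cd <- cd + 1
  }
  # expected index from marginal pair counts
  nt <- table(truth); np <- table(pred)
  pt <- sum(choose(nt, 2)); pp <- sum(choose(np, 2))
  expected <- pt * pp / cd
  maxi <- (pt + pp) / 2
  if (maxi == expected) return(0)
  (a - expected) / (maxi - expected)
}

# Entropy-based NMI from explicit cluster loops (geometric normalisation).
brute_nmi <- function(truth, pred) {
  n <- length(truth)
  I <- 0
  for (t in unique(truth)) for (p in unique(pred)) {
    nij <- sum(truth == t & pred == p)
    if (nij == 0) next
    ni <- sum(truth == t); nj <- sum(pred == p)
    I <- I + (nij / n) * log(nij * n / (ni * nj))
  }
  H <- function(x) {
    p <- table(x) / length(x)
    -sum(p * log(p))
  }
  ht <- H(truth); hp <- H(pred)
  if (ht == 0 || hp == 0) return(0)
  I / sqrt(ht * hp)
}

# Connected-component count by breadth-first search.
brute_components <- function(A) {
  n <- nrow(A)
  seen <- rep(FALSE, n)
  comps <- 0
  for (s in seq_len(n)) {
    if (seen[s]) next
    comps <- comps + 1
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      queue <- c(queue, which(A[v, ] != 0 & !seen))
    }
  }
  comps
}

write_edge_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
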