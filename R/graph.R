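#' Construct a single graph snapshot
#'
#' A snapshot holds the symmetric, non-negatively weighted adjacency matrix of
#' one time slice of a dynamic graph, together with optional node features and
#' community labels.  The diagonal must be zero (self-loops carry no meaning
#' for the graph Laplacian and are dropped upstream with a warning).
#'
#' @param adjacency symmetric numeric matrix (dense or `Matrix` sparse) with
#'   zero diagonal and non-negative weights.
#' @param index 0-based snapshot index.
#' @param features optional `n x d` numeric matrix of node features.
#' @param labels optional integer vector of length `n` with community labels.
#' @return an object of class `graph_snapshot`.
#' @export
graph_snapshot <- function(adjacency, index = 0L, features = NULL, labels = NULL) {
  A <- methods::as(methods::as(Matrix::Matrix(adjacency, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  n <- nrow(A)
  if (ncol(A) != n) stop("adjacency must be square", call. = FALSE)
  if (max(abs(A - Matrix::t(A))) > 1e-12) stop("adjacency must be symmetric", call. = FALSE)
  if (any(Matrix::diag(A) != 0)) stop("adjacency must have zero diagonal", call. = FALSE)
  if (length(A@x) && min(A@x) < 0) stop("edge weights must be non-negative", call. = FALSE)
  if (!is.null(features)) {
    features <- as.matrix(features)
    if (nrow(features) != n) stop("features must have one row per node", call. = FALSE)
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n) stop("labels must have length n", call. = FALSE)
  }
  structure(
    list(adjacency = A, index = as.integer(index), features = features, labels = labels),
    class = "graph_snapshot"
  )
}

#' @export
print.graph_snapshot <- function(x, ...) {
  cat(sprintf(
    "<graph_snapshot t=%d>  %d nodes, %d edges, total weight %.4g\n",
    x$index, nrow(x$adjacency), length(x$adjacency@x) / 2, sum(x$adjacency) / 2
  ))
  invisible(x)
}

snapshot_n <- function(snapshot) nrow(snapshot$adjacency)

#' Degree vector of a snapshot
#' @param snapshot a `graph_snapshot`.
#' @return numeric vector of weighted degrees (adjacency row sums).
#' @export
snapshot_degrees <- function(snapshot) as.numeric(Matrix::rowSums(snapshot$adjacency))

#' Assemble a dynamic graph from a temporal edge table
#'
#' The tidy entry point: takes a data frame of temporal edges with columns
#' `src`, `dst`, `t` and optionally `w` (weight, default 1) and builds the
#' sequence of snapshots over the union node set.  Edges are undirected;
#' duplicate rows and both orientations of a pair are summed into a single
#' symmetric weight.  Self-loops are dropped with a warning.  Snapshot indices
#' must be non-negative integers; indices absent from the table within
#' `0..max(t)` become empty snapshots so the sequence stays contiguous.
#'
#' @param edges data frame with columns `src`, `dst`, `t` and optional `w`.
#' @param node_ids optional character vector fixing the node universe and its
#'   internal order; defaults to first-seen order over the edge table.
#' @param features optional feature matrix, rows aligned with `node_ids`
#'   (recycled to every snapshot).
#' @param labels optional data frame `node`, `t`, `community` of ground-truth
#'   labels per snapshot.
#' @return a `dynamic_graph`: a fixed node set with `T` snapshots.
#' @export
dynamic_graph <- function(edges, node_ids = NULL, features = NULL, labels = NULL) {
  edges <- as.data.frame(edges)
  req <- c("src", "dst", "t")
  if (!all(req %in% names(edges))) {
    stop("edges must have columns src, dst, t", call. = FALSE)
  }
  if (!"w" %in% names(edges)) edges$w <- 1
  if (any(!is.finite(edges$w)) || any(edges$w < 0)) {
    stop("edge weights must be finite and non-negative", call. = FALSE)
  }
  tt <- edges$t
  if (any(tt < 0) || any(tt != floor(tt))) {
    stop("snapshot indices t must be non-negative integers", call. = FALSE)
  }
  edges$src <- as.character(edges$src)
  edges$dst <- as.character(edges$dst)
  loops <- edges$src == edges$dst
  if (any(loops)) {
    warning(sprintf("dropping %d self-loop edge(s)", sum(loops)), call. = FALSE)
    edges <- edges[!loops, , drop = FALSE]
  }
  seen <- unique(c(rbind(edges$src, edges$dst)))
  if (is.null(node_ids)) {
    node_ids <- seen
  } else {
    node_ids <- as.character(node_ids)
    missing_ids <- setdiff(seen, node_ids)
    if (length(missing_ids)) {
      stop(sprintf("edge table references unknown node id(s): %s",
                   paste(utils::head(missing_ids, 5), collapse = ", ")), call. = FALSE)
    }
  }
  n <- length(node_ids)
  idx <- stats::setNames(seq_len(n), node_ids)
  T_len <- if (nrow(edges)) max(edges$t) + 1L else 1L
  snapshots <- vector("list", T_len)
  for (t in seq_len(T_len) - 1L) {
    sel <- edges$t == t
    if (any(sel)) {
      i <- idx[edges$src[sel]]
      j <- idx[edges$dst[sel]]
      S <- Matrix::sparseMatrix(i = i, j = j, x = edges$w[sel], dims = c(n, n))
      A <- S + Matrix::t(S)
    } else {
      A <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(), dims = c(n, n))
    }
    lab_t <- NULL
    if (!is.null(labels)) {
      labels <- as.data.frame(labels)
      lt <- labels[labels$t == t, , drop = FALSE]
      if (nrow(lt)) {
        lab_t <- rep(NA_integer_, n)
        lab_t[idx[as.character(lt$node)]] <- as.integer(lt$community)
      }
    }
    snapshots[[t + 1L]] <- graph_snapshot(A, index = t, features = features, labels = lab_t)
  }
  structure(
    list(snapshots = snapshots, node_ids = node_ids, n = n, n_snapshots = T_len),
    class = "dynamic_graph"
  )
}

#' @export
print.dynamic_graph <- function(x, ...) {
  m <- vapply(x$snapshots, function(s) length(s$adjacency@x) / 2, numeric(1))
  cat(sprintf("<dynamic_graph>  %d nodes, %d snapshots, edges per snapshot: %s\n",
              x$n, x$n_snapshots, paste(m, collapse = ", ")))
  invisible(x)
}

#' Number of snapshots in a dynamic graph
#' @param graph a `dynamic_graph`.
#' @export
n_snapshots <- function(graph) graph$n_snapshots

#' Extract one snapshot
#' @param graph a `dynamic_graph`.
#' @param t 0-based snapshot index.
#' @export
snapshot <- function(graph, t) {
  if (t < 0 || t >= graph$n_snapshots) stop("snapshot index out of range", call. = FALSE)
  graph$snapshots[[t + 1L]]
}

replace_snapshot <- function(graph, t, snap) {
  graph$snapshots[[t + 1L]] <- snap
  graph
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Temporal edge table of a dynamic graph
#'
#' Returns one row per undirected edge per snapshot (`src`, `dst`, `t`, `w`),
#' using external node ids and upper-triangle orientation, the inverse of
#' [dynamic_graph()] up to row order.
#'
#' @param x a `dynamic_graph`.
#' @param ... unused.
#' @export
as_tibble.dynamic_graph <- function(x, ...) {
  rows <- lapply(seq_len(x$n_snapshots) - 1L, function(t) {
    A <- snapshot(x, t)$adjacency
    tr <- Matrix::which(Matrix::triu(A, k = 1) != 0, arr.ind = TRUE)
    if (!nrow(tr)) return(NULL)
    tibble::tibble(
      src = x$node_ids[tr[, 1]],
      dst = x$node_ids[tr[, 2]],
      t = t,
      w = A[tr]
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) out <- tibble::tibble(src = character(), dst = character(),
                                        t = integer(), w = numeric())
  out
}

#' Ground-truth labels of a dynamic graph as a tidy table
#' @param graph a `dynamic_graph` whose snapshots carry labels.
#' @return tibble with columns `node`, `t`, `community` (rows only for
#'   labelled snapshots).
#' @export
graph_labels <- function(graph) {
  rows <- lapply(seq_len(graph$n_snapshots) - 1L, function(t) {
    lab <- snapshot(graph, t)$labels
    if (is.null(lab)) return(NULL)
    tibble::tibble(node = graph$node_ids, t = t, community = lab)
  })
  dplyr::bind_rows(rows)
}

# ---- on-disk formats --------------------------------------------------------

#' Read a temporal edge list file
#'
#' Plain-text format, one interaction per line: `src dst t [w]`, separated by
#' whitespace or tabs.  Lines starting with `#` and blank lines are skipped.
#'
#' @param path file path.
#' @return a `dynamic_graph` (undirected, duplicate lines and reversed pairs
#'   summed, missing intermediate snapshots empty).
#' @export
read_temporal_edgelist <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lns <- which(keep)
  parts <- strsplit(trimws(lines[keep]), "[ \t]+")
  n_fields <- lengths(parts)
  bad <- which(n_fields < 3)
  if (length(bad)) {
    stop(sprintf("malformed edge line %d: expected 'src dst t [w]', got %s",
                 lns[bad[1]], shQuote(lines[lns[bad[1]]])), call. = FALSE)
  }
  src <- vapply(parts, `[[`, character(1), 1)
  dst <- vapply(parts, `[[`, character(1), 2)
  t_raw <- vapply(parts, `[[`, character(1), 3)
  t <- suppressWarnings(as.numeric(t_raw))
  bad_t <- which(!is.finite(t) | t < 0 | t != floor(t))
  if (length(bad_t)) {
    stop(sprintf("malformed edge line %d: snapshot index %s is not a non-negative integer",
                 lns[bad_t[1]], shQuote(t_raw[bad_t[1]])), call. = FALSE)
  }
  w <- rep(1, length(src))
  has_w <- n_fields >= 4
  if (any(has_w)) {
    w_raw <- vapply(parts[has_w], `[[`, character(1), 4)
    w[has_w] <- suppressWarnings(as.numeric(w_raw))
  }
  bad_w <- which(!is.finite(w) | w < 0)
  if (length(bad_w)) {
    stop(sprintf("invalid edge weight on line %d: weights must be finite and non-negative",
                 lns[bad_w[1]]), call. = FALSE)
  }
  dynamic_graph(data.frame(src = src, dst = dst, t = as.integer(t), w = w))
}

#' Write a dynamic graph as a temporal edge list
#' @param graph a `dynamic_graph`.
#' @param path output file path.
#' @export
write_temporal_edgelist <- function(graph, path) {
  tbl <- as_tibble(graph)
  utils::write.table(tbl, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read node features (CSV with header; first column is the node id)
#' @param path file path.
#' @param node_ids character vector giving the internal node order.
#' @return numeric matrix with `length(node_ids)` rows.
#' @export
read_node_features <- function(path, node_ids) {
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- as.character(df[[1]])
  X <- as.matrix(df[, -1, drop = FALSE])
  miss <- setdiff(node_ids, ids)
  if (length(miss)) stop(sprintf("features missing for node(s): %s",
                                 paste(utils::head(miss, 5), collapse = ", ")), call. = FALSE)
  X <- X[match(node_ids, ids), , drop = FALSE]
  rownames(X) <- node_ids
  X
}

#' Read ground-truth labels (TSV: node t community)
#' @param path file path.
#' @return tibble `node`, `t`, `community`.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, header = FALSE, col.names = c("node", "t", "community"),
                          colClasses = c("character", "integer", "integer"))
  tibble::as_tibble(df)
}

#' Write per-snapshot community assignments (TSV: node snapshot community)
#' @param assignments tibble with columns `node`, `snapshot`, `community`.
#' @param path output file path.
#' @export
write_assignments <- function(assignments, path) {
  utils::write.table(assignments[, c("node", "snapshot", "community")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- Laplacians -------------------------------------------------------------

#' Graph Laplacian of a snapshot
#'
#' Builds `L = D - A` (default) or the symmetric-normalised variant
#' `I - D^{-1/2} A D^{-1/2}`; rows and columns of isolated nodes are zero in
#' the normalised form.  Both variants are symmetric positive semidefinite and
#' the multiplicity of the zero eigenvalue equals the number of connected
#' components.
#'
#' @param snapshot a `graph_snapshot` (or a bare symmetric adjacency matrix).
#' @param variant `"unnormalized"` (the default) or `"normalized"`.
#' @return a sparse symmetric matrix.
#' @export
build_laplacian <- function(snapshot, variant = c("unnormalized", "normalized")) {
  variant <- match.arg(variant)
  A <- if (inherits(snapshot, "graph_snapshot")) snapshot$adjacency else
    methods::as(Matrix::Matrix(snapshot, sparse = TRUE), "CsparseMatrix")
  d <- as.numeric(Matrix::rowSums(A))
  if (variant == "unnormalized") {
    L <- Matrix::Diagonal(x = d) - A
  } else {
    inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
    Dm <- Matrix::Diagonal(x = inv_sqrt)
    # isolated nodes: I - D^{-1/2} A D^{-1/2} would leave a 1 on the diagonal;
    # zero those rows instead so they stay in the Laplacian null space
    I_adj <- Matrix::Diagonal(x = as.numeric(d > 0))
    L <- I_adj - Dm %*% A %*% Dm
  }
  methods::as(methods::as(L, "generalMatrix"), "CsparseMatrix")
}

#' Normalised adjacency used as the coupling template
#'
#' `D^{-1/2} A D^{-1/2}`; its spectrum lies in `[-1, 1]`, which keeps the
#' coupling gain of the node dynamics bounded independently of degree.
#' @param snapshot a `graph_snapshot`.
#' @return sparse symmetric matrix.
#' @export
normalized_adjacency <- function(snapshot) {
  A <- snapshot$adjacency
  d <- as.numeric(Matrix::rowSums(A))
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  Dm <- Matrix::Diagonal(x = inv_sqrt)
  methods::as(methods::as(Dm %*% A %*% Dm, "generalMatrix"), "CsparseMatrix")
}
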