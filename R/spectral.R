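#' Leading Laplacian eigenpairs
#'
#' Computes the `r` smallest eigenvalues and eigenvectors of a symmetric
#' positive semidefinite graph Laplacian: the graph Fourier basis restricted
#' to its smoothest modes.  Small eigenvalues carry community-scale structure
#' (the zero eigenvalue spans one constant vector per connected component);
#' large eigenvalues carry high-frequency, noise-amplifying modes.
#'
#' For `n <= dense_limit` a full dense symmetric eigendecomposition is used;
#' above that a Lanczos-type iteration ([igraph::arpack()]) with a
#' deterministic, seed-derived start vector computes the `r` smallest pairs
#' via the spectral shift `sigma*I - L` (Gershgorin bound `sigma`).
#' Eigenvalues are returned in ascending order with ties kept in index order,
#' and each eigenvector's sign is fixed so that its largest-magnitude entry is
#' positive, making the basis reproducible across solvers.
#'
#' @param L symmetric PSD matrix (dense or sparse).
#' @param r number of smallest eigenpairs, `1 <= r <= n`.
#' @param method `"auto"` (default), `"dense"` or `"iterative"`.
#' @param dense_limit node count up to which the dense path is used under
#'   `"auto"` (default 2000).
#' @param seed integer seed for the iterative start vector.
#' @return a `spectral_basis`: list with `values` (ascending, length `r`),
#'   `vectors` (`n x r`, orthonormal columns), `r`, `n` and `method`.
#' @export
spectral_basis <- function(L, r, method = c("auto", "dense", "iterative"),
                           dense_limit = 2000L, seed = 1L) {
  method <- match.arg(method)
  n <- nrow(L)
  if (ncol(L) != n) stop("L must be square", call. = FALSE)
  asym <- max(abs(L - Matrix::t(L)))
  if (asym > 1e-8) stop("L must be symmetric", call. = FALSE)
  if (r < 1 || r > n) stop("r must satisfy 1 <= r <= n", call. = FALSE)
  if (method == "auto") method <- if (n <= dense_limit) "dense" else "iterative"

  if (method == "dense") {
    eig <- eigen(as.matrix(Matrix::symmpart(L)), symmetric = TRUE)
    ord <- rev(seq_len(n))[seq_len(r)]        # eigen() returns descending
    values <- eig$values[ord]
    vectors <- eig$vectors[, ord, drop = FALSE]
  } else {
    Ls <- methods::as(Matrix::symmpart(L), "CsparseMatrix")
    sigma <- max(Matrix::rowSums(abs(Ls)))    # Gershgorin upper bound on the spectrum
    set.seed(seed)
    start <- stats::rnorm(n)
    res <- igraph::arpack(
      function(x, extra) as.numeric(sigma * x - Ls %*% x),
      sym = TRUE,
      options = list(n = n, nev = r, ncv = min(n, max(2L * r + 1L, 20L)),
                     which = "LA", maxiter = 3000L, start = start)
    )
    values <- sigma - res$values
    vectors <- matrix(res$vectors, nrow = n)
    ord <- order(values)
    values <- values[ord]
    vectors <- vectors[, ord, drop = FALSE]
  }
  if (values[1] < -1e-10) {
    stop(sprintf("L is not PSD: smallest eigenvalue %.3e", values[1]), call. = FALSE)
  }
  vectors <- fix_eigenvector_signs(vectors)
  structure(list(values = values, vectors = vectors, r = as.integer(r),
                 n = as.integer(n), method = method),
            class = "spectral_basis")
}

fix_eigenvector_signs <- function(V) {
  for (k in seq_len(ncol(V))) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  V
}

#' @export
print.spectral_basis <- function(x, ...) {
  cat(sprintf("<spectral_basis> r=%d of n=%d (%s)  lambda: %s%s\n",
              x$r, x$n, x$method,
              paste(signif(utils::head(x$values, 5), 4), collapse = ", "),
              if (x$r > 5) ", ..." else ""))
  invisible(x)
}

#' Spectral filter kernels
#'
#' A kernel maps Laplacian eigenvalues to attenuation factors
#' `phi(lambda)` in `[0, 1]`.  Families: `"exponential"` (`exp(-tau *
#' lambda)`, a smooth low-pass decay, non-increasing in `lambda`), `"cutoff"`
#' (keep the first `cutoff` modes, zero the rest) and `"polynomial"`
#' (evaluate `coefficients` in `lambda`; values are validated, not clamped).
#'
#' @param family kernel family.
#' @param tau decay rate `>= 0` for the exponential family.
#' @param cutoff number of leading (smoothest) modes kept by the cutoff family.
#' @param coefficients polynomial coefficients, constant term first.
#' @return a `filter_kernel`.
#' @export
filter_kernel <- function(family = c("exponential", "cutoff", "polynomial"),
                          tau = 1, cutoff = NULL, coefficients = NULL) {
  family <- match.arg(family)
  if (family == "exponential" && tau < 0) stop("tau must be >= 0", call. = FALSE)
  if (family == "cutoff" && (is.null(cutoff) || cutoff < 1)) {
    stop("cutoff family needs a positive cutoff index", call. = FALSE)
  }
  if (family == "polynomial" && is.null(coefficients)) {
    stop("polynomial family needs coefficients", call. = FALSE)
  }
  structure(list(family = family, tau = tau, cutoff = cutoff,
                 coefficients = coefficients),
            class = "filter_kernel")
}

kernel_values <- function(kernel, lambda, mode_index = seq_along(lambda)) {
  phi <- switch(kernel$family,
    exponential = exp(-kernel$tau * lambda),
    cutoff = as.numeric(mode_index <= kernel$cutoff),
    polynomial = {
      acc <- 0
      for (i in seq_along(kernel$coefficients)) {
        acc <- acc + kernel$coefficients[i] * lambda^(i - 1)
      }
      acc
    }
  )
  if (any(phi < -1e-12) || any(phi > 1 + 1e-12)) {
    stop("filter kernel values must lie in [0, 1]", call. = FALSE)
  }
  pmin(pmax(phi, 0), 1)
}

#' Apply a spectral filter to node states
#'
#' Graph-Fourier filtering `X_hat = U diag(phi(lambda)) U^T X`, optionally
#' adding back the residual component of `X` outside the span of the retained
#' basis (`passthrough`, on by default: a rank-`r` filter should not destroy
#' signal the basis cannot represent).  Modes flagged in `zero_modes` (e.g.
#' those with positive hallucination index) are hard-zeroed on top of the
#' kernel attenuation.
#'
#' With `r = n`, `phi == 1` and no zeroing the operation is the identity.
#' With `phi <= 1` and passthrough off it is non-expansive in Frobenius norm.
#'
#' @param X `n x d` node-state matrix.
#' @param basis a [spectral_basis()].
#' @param kernel a [filter_kernel()].
#' @param passthrough keep the off-basis residual (default `TRUE`).
#' @param zero_modes optional logical vector (length `r`) of modes to zero.
#' @return the filtered `n x d` matrix.
#' @export
apply_spectral_filter <- function(X, basis, kernel, passthrough = TRUE,
                                  zero_modes = NULL) {
  X <- as.matrix(X)
  if (nrow(X) != basis$n) stop("X rows must match the basis dimension", call. = FALSE)
  phi <- kernel_values(kernel, basis$values)
  if (!is.null(zero_modes)) {
    if (length(zero_modes) != basis$r) stop("zero_modes must have length r", call. = FALSE)
    phi[zero_modes] <- 0
  }
  U <- basis$vectors
  coef <- crossprod(U, X)
  out <- U %*% (phi * coef)
  if (passthrough) out <- out + (X - U %*% coef)
  out
}

#' Hallucination indices of the retained eigenmodes
#'
#' The per-mode stability score `eta_k = lambda_k * F - c_k`, where `F` is the
#' forcing gain of the coupled dynamics and `c_k` the leakage felt by mode
#' `k`.  Modes with `eta_k > 0` are flagged unstable: their forcing outweighs
#' their damping, so they can amplify noise into spurious ("hallucinated")
#' community structure.  The constant mode (`lambda = 0`) is always stable.
#'
#' @param basis a [spectral_basis()], or a numeric vector of eigenvalues.
#' @param F forcing gain, `>= 0`.  A convenient default at the pipeline level
#'   is `L_f * ||W||_2` (activation Lipschitz constant times coupling norm).
#' @param leakage per-mode leakage: positive scalar or length-`r` vector.  For
#'   a general diagonal leakage matrix use [mode_leakage()].
#' @return tibble with columns `mode`, `lambda`, `eta`, `unstable`.
#' @export
hallucination_indices <- function(basis, F, leakage) {
  lambda <- if (inherits(basis, "spectral_basis")) basis$values else as.numeric(basis)
  if (F < 0) stop("forcing gain F must be >= 0", call. = FALSE)
  r <- length(lambda)
  ck <- if (length(leakage) == 1) rep(leakage, r) else as.numeric(leakage)
  if (length(ck) != r) stop("leakage must be scalar or length r", call. = FALSE)
  if (any(ck <= 0)) stop("leakage must be positive", call. = FALSE)
  eta <- lambda * F - ck
  tibble::tibble(mode = seq_len(r), lambda = lambda, eta = eta,
                 unstable = eta > 0)
}

#' Largest hallucination index
#' @param eta result of [hallucination_indices()] (or a numeric vector).
#' @export
eta_max <- function(eta) {
  if (is.data.frame(eta)) max(eta$eta) else max(eta)
}

#' Per-mode leakage seen by a spectral basis
#'
#' For a diagonal leakage matrix `C`, mode `k` feels the Rayleigh quotient
#' `c_k = u_k^T C u_k`.  For `C = c I` this is just `c`.
#'
#' @param basis a [spectral_basis()].
#' @param C diagonal leakage (scalar, vector or diagonal matrix).
#' @return numeric vector of length `r`.
#' @export
mode_leakage <- function(basis, C) {
  cvec <- leakage_vector(C, basis$n)
  if (length(unique(cvec)) == 1) return(rep(cvec[1], basis$r))
  as.numeric(colSums(basis$vectors^2 * cvec))
}
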