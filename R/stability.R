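sym_part <- function(M) (M + t(M)) / 2

spectral_norm <- function(M) {
  if (!length(M) || all(M == 0)) return(0)
  max(svd(as.matrix(M), nu = 0, nv = 0)$d)
}

lambda_min_sym <- function(M) min(eigen(sym_part(as.matrix(M)), symmetric = TRUE,
                                        only.values = TRUE)$values)
lambda_max_sym <- function(M) max(eigen(sym_part(as.matrix(M)), symmetric = TRUE,
                                        only.values = TRUE)$values)

as_leakage_matrix <- function(C, n) {
  if (is.matrix(C) || inherits(C, "Matrix")) as.matrix(C) else diag(leakage_vector(C, n), n)
}

#' Solve the Lyapunov equation of the coupled error dynamics
#'
#' For the linearised error dynamics `D^alpha e = A e` with
#' `A = -(C - F * W_sym)` (leakage minus gained coupling, `W_sym = (W +
#' W^T)/2`), computes the symmetric positive definite `P` solving
#' `A^T P + P A = -2 I`.  `A` must be Hurwitz; otherwise no PD solution
#' exists and an error reports the offending eigenvalue.
#'
#' The solve is a Bartels-Stewart-type reduction through the
#' eigendecomposition of `A` (exact for diagonalisable `A` — always the case
#' here since `W` is symmetrised, making `A` symmetric whenever `C` is
#' diagonal), with a Kronecker-vectorisation fallback for small
#' ill-conditioned systems.  The residual `||A^T P + P A + 2I||_F` and
#' positive definiteness are verified before returning.
#'
#' @param C leakage (scalar, positive vector, diagonal or full matrix).
#' @param W coupling matrix (`0` for uncoupled dynamics).
#' @param F forcing gain multiplying the coupling.
#' @param A optionally the system matrix directly (overrides `C`, `W`, `F`).
#' @return symmetric positive definite matrix `P`.
#' @export
solve_lyapunov_P <- function(C, W = 0, F = 1, A = NULL) {
  if (is.null(A)) {
    n <- if (is.matrix(C) || inherits(C, "Matrix")) nrow(C) else
      max(length(C), if (is.matrix(W) || inherits(W, "Matrix")) nrow(W) else 1L)
    Cm <- as_leakage_matrix(C, n)
    Wm <- if (is.numeric(W) && length(W) == 1 && W == 0) matrix(0, n, n) else as.matrix(W)
    A <- -(Cm - F * sym_part(Wm))
  } else {
    A <- as.matrix(A)
  }
  n <- nrow(A)
  ev <- eigen(A)
  re_max <- max(Re(ev$values))
  if (re_max >= 0) {
    stop(sprintf("system matrix is not Hurwitz: eigenvalue with Re = %.6g", re_max),
         call. = FALSE)
  }
  P <- tryCatch({
    V <- ev$vectors
    G <- -2 * (t(V) %*% V) / outer(ev$values, ev$values, `+`)
    Vi <- solve(V)
    sym_part(Re(t(Vi) %*% G %*% Vi))
  }, error = function(e) NULL)
  resid <- if (is.null(P)) Inf else norm(t(A) %*% P + P %*% A + 2 * diag(n), "F")
  if (resid > 1e-8) {
    if (n > 200L) {
      stop("Lyapunov solve failed: eigenbasis path inaccurate and system too large for the vectorised fallback",
           call. = FALSE)
    }
    # vec(A^T P + P A) = (I (x) A^T + A^T (x) I) vec(P)
    K <- diag(n) %x% t(A) + t(A) %x% diag(n)
    P <- sym_part(matrix(solve(K, as.numeric(-2 * diag(n))), n, n))
    resid <- norm(t(A) %*% P + P %*% A + 2 * diag(n), "F")
    if (resid > 1e-8) {
      stop(sprintf("Lyapunov solve failed: residual %.3e", resid), call. = FALSE)
    }
  }
  pmin_eig <- lambda_min_sym(P)
  if (pmin_eig <= 0) {
    stop(sprintf("Lyapunov matrix is not positive definite (lambda_min = %.3e)", pmin_eig),
         call. = FALSE)
  }
  P
}

#' Spectral stability margin
#'
#' `rho = lambda_min(sym(P C)) - F * ||P W||_2`: how much symmetrised damping
#' exceeds the worst-case gained coupling.  Positive `rho` certifies a region
#' of attraction for the error dynamics and bounds the Mittag-Leffler decay
#' rate (see [error_bound()]); negative `rho` flags a potentially unstable
#' system.
#'
#' @param P symmetric positive definite Lyapunov matrix.
#' @param C leakage matrix (scalar/vector/diagonal accepted).
#' @param W coupling matrix.
#' @param F forcing gain.
#' @return scalar margin `rho` (may be negative).
#' @export
stability_margin <- function(P, C, W = 0, F = 1) {
  P <- as.matrix(P)
  n <- nrow(P)
  Cm <- as_leakage_matrix(C, n)
  Wm <- if (is.numeric(W) && length(W) == 1 && W == 0) matrix(0, n, n) else as.matrix(W)
  if (!all(dim(Cm) == n) || !all(dim(Wm) == n)) stop("shape mismatch", call. = FALSE)
  lambda_min_sym(P %*% Cm) - F * spectral_norm(P %*% Wm)
}

#' Closed-form stability margin in the commuting case
#'
#' When `C = c I` and `W = s * A_hat` with `A_hat` symmetric, the margin of
#' [stability_margin()] with `P = I` has the closed form
#' `min_k (c - F |s| |mu_k|)` over the eigenvalues `mu_k` of `A_hat`.  This is
#' the cheap differentiable proxy used at scale and inside the training loss.
#'
#' @param c scalar leakage.
#' @param s coupling scale.
#' @param mu eigenvalues of the (symmetric) coupling template.
#' @param F forcing gain.
#' @param extra_damping additional leakage added to every mode (e.g. the
#'   truncation damping of the fractional operator, [gl_truncation_damping()]).
#' @return scalar margin.
#' @export
stability_margin_proxy <- function(c, s, mu, F = 1, extra_damping = 0) {
  min((c + extra_damping) - F * abs(s) * abs(mu))
}

#' Verify the matrix stability condition
#'
#' Checks the positive definite form
#' `P C + C^T P - F (P W + W^T P) >= rho I`, i.e. that the symmetrised damped
#' part dominates the gained coupling with margin at least `rho`.
#'
#' @inheritParams stability_margin
#' @param rho required margin, `>= 0`.
#' @return list with `holds` (logical) and `slack` (`lambda_min` of the left
#'   side minus `rho`).
#' @export
verify_stability_condition <- function(P, C, W = 0, F = 1, rho = 0) {
  P <- as.matrix(P)
  n <- nrow(P)
  if (rho < 0) stop("rho must be >= 0", call. = FALSE)
  Cm <- as_leakage_matrix(C, n)
  Wm <- if (is.numeric(W) && length(W) == 1 && W == 0) matrix(0, n, n) else as.matrix(W)
  M <- P %*% Cm + t(Cm) %*% P - F * (P %*% Wm + t(Wm) %*% P)
  lmin <- lambda_min_sym(M)
  list(holds = lmin >= rho, slack = lmin - rho)
}

#' Mittag-Leffler error bound
#'
#' The fractional-order ultimate bound on the deviation of the dynamics from
#' a hallucination-free reference trajectory:
#' `||e(t)|| <= ||e(0)|| E_alpha(-rho t^alpha) + lambda_max(P) u_bar / rho`,
#' valid when the stability margin `rho` is positive and the disturbance is
#' bounded by `u_bar`.  At `alpha = 1` the transient term is the familiar
#' exponential `exp(-rho t)`; for `alpha < 1` it decays faster initially but
#' carries an algebraic tail, the signature of long-memory dynamics.
#'
#' @param e0_norm initial error norm, `>= 0`.
#' @param rho stability margin, `> 0`.
#' @param P Lyapunov matrix (used through `lambda_max(P)`).
#' @param u_bar disturbance bound, `>= 0`.
#' @param alpha fractional order.
#' @param t evaluation times (vectorised, `>= 0`).
#' @return numeric vector of bounds.
#' @export
error_bound <- function(e0_norm, rho, P, u_bar, alpha, t) {
  if (rho <= 0) stop("error bound requires rho > 0", call. = FALSE)
  if (e0_norm < 0 || u_bar < 0) stop("norms must be non-negative", call. = FALSE)
  lamP <- lambda_max_sym(as.matrix(P))
  e0_norm * mittag_leffler(alpha, -rho * t^alpha) + lamP * u_bar / rho
}

#' Quadratic Lyapunov function along an error trajectory
#'
#' `V_t = e_t^T P e_t`, non-negative for positive definite `P`; along stable
#' dynamics `V(t)` decays after the transient.
#'
#' @param errors matrix with one error vector per row, or a list of vectors.
#' @param P symmetric positive definite matrix.
#' @return numeric vector `V(t)`.
#' @export
lyapunov_trace <- function(errors, P) {
  P <- as.matrix(P)
  if (is.list(errors)) errors <- do.call(rbind, lapply(errors, as.numeric))
  errors <- as.matrix(errors)
  if (ncol(errors) != nrow(P)) stop("error vectors must match dim(P)", call. = FALSE)
  as.numeric(rowSums((errors %*% P) * errors))
}

#' Write a per-snapshot stability report as JSON
#'
#' Serialises a list of per-snapshot stability summaries (as produced by the
#' pipeline) to the report schema
#' `{snapshot, rho, rho_method, eta, eta_max, u_bar, V_trace}`.
#'
#' @param report list of per-snapshot entries, or the `reports` element of a
#'   pipeline result.
#' @param path output file.
#' @export
write_stability_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(path)
}

#' Simulate the linear error dynamics under bounded disturbance
#'
#' Integrates `D^alpha e = -(C - F W) e + du(t)` with the truncated GL scheme
#' (full memory), drawing at each step a disturbance of norm at most `u_bar`
#' (uniform direction, uniform magnitude), and returns the error-norm and
#' Lyapunov-function traces together with the certified Mittag-Leffler bound
#' evaluated at the sample times.  The workhorse behind the bound-validity
#' and Lyapunov-decay analyses.
#'
#' @param C,W,F system matrices and gain as in [solve_lyapunov_P()].
#' @param e0 initial error vector.
#' @param u_bar disturbance norm bound (`0` for the undisturbed decay).
#' @param alpha fractional order.
#' @param dt step size.
#' @param n_steps number of steps.
#' @param seed integer seed for the disturbance draws.
#' @return list with `times`, `errors` (matrix, one row per time),
#'   `norms`, `V` (with `P` from the Lyapunov solve), `bound`, `rho`, `P`.
#' @export
simulate_error_dynamics <- function(C, W = 0, F = 1, e0, u_bar = 0,
                                    alpha = 1, dt = 0.01, n_steps = 500L,
                                    seed = 1L) {
  e0 <- as.numeric(e0)
  n <- length(e0)
  Cm <- as_leakage_matrix(C, n)
  Wm <- if (is.numeric(W) && length(W) == 1 && W == 0) matrix(0, n, n) else as.matrix(W)
  A <- -(Cm - F * sym_part(Wm))
  P <- solve_lyapunov_P(A = A)
  rho <- stability_margin(P, Cm, Wm, F)
  set.seed(seed)
  forcing <- function(step) {
    dir <- stats::rnorm(n)
    matrix(dir / sqrt(sum(dir^2)) * stats::runif(1, 0, u_bar), ncol = 1)
  }
  sim <- simulate_fractional(matrix(e0, ncol = 1), C = Cm, W = F * sym_part(Wm),
                             alpha = alpha, dt = dt, n_steps = n_steps,
                             horizon = n_steps, activation = "identity",
                             forcing = if (u_bar > 0) forcing else NULL)
  errs <- do.call(rbind, lapply(sim$states, function(s) as.numeric(s[, 1])))
  norms <- sqrt(rowSums(errs^2))
  bound <- if (rho > 0) {
    error_bound(sqrt(sum(e0^2)), rho, P, u_bar, alpha, sim$times)
  } else rep(NA_real_, length(sim$times))
  list(times = sim$times, errors = errs, norms = norms,
       V = lyapunov_trace(errs, P), bound = bound, rho = rho, P = P)
}
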