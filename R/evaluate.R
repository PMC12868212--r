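#' Adjusted Rand index
#'
#' Chance-corrected pair-counting agreement between two partitions of the
#' same items (permutation-model expectation subtracted, maximum 1 for
#' identical partitions).  Label names are irrelevant on either side.
#'
#' @param truth,pred label vectors of equal length.
#' @return scalar ARI (`<= 1`; 0 expected for unrelated partitions).
#' @export
adjusted_rand_index <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("label vectors must have equal length", call. = FALSE)
  if (anyNA(truth) || anyNA(pred)) stop("labels must not contain NA", call. = FALSE)
  mclust::adjustedRandIndex(truth, pred)
}

#' Normalised mutual information
#'
#' `I(T; P) / sqrt(H(T) H(P))` from the label contingency table (geometric
#' normalisation).  When either partition has zero entropy (a single
#' cluster), the score is 0 by convention unless both partitions are the
#' same single cluster, in which case agreement is perfect but reported as 0
#' as well (the quantity is undefined; a message notes the convention).
#'
#' @param truth,pred label vectors of equal length.
#' @return scalar NMI in `[0, 1]`.
#' @export
normalized_mutual_information <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("label vectors must have equal length", call. = FALSE)
  n <- length(truth)
  tab <- table(truth, pred)
  pij <- tab / n
  pi_ <- rowSums(pij)
  p_j <- colSums(pij)
  H_t <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  H_p <- -sum(p_j[p_j > 0] * log(p_j[p_j > 0]))
  if (H_t == 0 || H_p == 0) {
    message("zero-entropy partition: NMI reported as 0 by convention")
    return(0)
  }
  nz <- pij > 0
  I <- sum(pij[nz] * log(pij[nz] / (pi_[row(pij)[nz]] * p_j[col(pij)[nz]])))
  I / sqrt(H_t * H_p)
}

#' Run mean with t-based confidence half-width
#'
#' The run-averaging protocol: for `n` repeated runs report the sample mean
#' and the 95% (by default) confidence half-width
#' `delta = t_{1-(1-conf)/2, n-1} * sd / sqrt(n)`.
#'
#' @param values numeric vector of length `>= 2`.
#' @param conf confidence level (default 0.95).
#' @return one-row tibble with `mean`, `sd`, `delta`, `n`.
#' @export
mean_ci <- function(values, conf = 0.95) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) stop("mean_ci needs at least 2 values", call. = FALSE)
  s <- stats::sd(values)
  delta <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * s / sqrt(n)
  tibble::tibble(mean = mean(values), sd = s, delta = delta, n = n)
}

#' Compare a predicted timeline with ground-truth labels
#'
#' Joins predictions and truth on node and snapshot and scores each snapshot
#' with ARI and NMI, plus the across-snapshot averages.
#'
#' @param timeline a `community_timeline` (or its assignment tibble).
#' @param truth tibble `node`, `t`, `community` (as from [graph_labels()]).
#' @return list with `per_snapshot` (tibble `snapshot`, `ari`, `nmi`) and
#'   `summary` (one-row tibble of means).
#' @export
evaluate_timeline <- function(timeline, truth) {
  pred <- if (inherits(timeline, "community_timeline")) timeline$assignments else
    tibble::as_tibble(timeline)
  truth <- tibble::as_tibble(truth)
  truth$node <- as.character(truth$node)
  pred$node <- as.character(pred$node)
  joined <- dplyr::inner_join(pred, truth,
                              by = c("node", snapshot = "t"),
                              suffix = c("_pred", "_true"))
  if (!nrow(joined)) stop("no (node, snapshot) overlap between prediction and truth", call. = FALSE)
  per <- joined |>
    dplyr::group_by(.data$snapshot) |>
    dplyr::summarise(
      ari = adjusted_rand_index(.data$community_true, .data$community_pred),
      nmi = normalized_mutual_information(.data$community_true, .data$community_pred),
      .groups = "drop"
    )
  list(per_snapshot = per,
       summary = tibble::tibble(ari = mean(per$ari), nmi = mean(per$nmi)))
}
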