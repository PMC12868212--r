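#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the fitted parameters
#' @param x a `fraccomm_fit`.
#' @param ... unused.
#' @return tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.fraccomm_fit <- function(x, ...) {
  tibble::tibble(term = c("s", "c", "tau"),
                 estimate = c(x$params$s, x$params$c, x$params$tau))
}

#' One-row fit summary
#' @param x a `fraccomm_fit`.
#' @param ... unused.
#' @export
glance.fraccomm_fit <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  tibble::tibble(epochs = x$epochs_run, loss = last$loss, rho = last$rho,
                 eta_max = last$eta_max,
                 mean_modularity = mean(x$stability$modularity),
                 converged = x$converged)
}

#' Tidy per-snapshot stability diagnostics of a detection
#' @param x a `fraccomm_detection`.
#' @param ... unused.
#' @export
tidy.fraccomm_detection <- function(x, ...) x$stability

#' One-row detection summary
#' @param x a `fraccomm_detection`.
#' @param ... unused.
#' @export
glance.fraccomm_detection <- function(x, ...) {
  tibble::tibble(snapshots = nrow(x$stability),
                 mean_rho = mean(x$stability$rho),
                 max_eta_max = max(x$stability$eta_max),
                 mean_modularity = mean(x$stability$modularity))
}

#' Training-trace curves
#'
#' Loss, stability margin, largest hallucination index and modularity per
#' epoch, faceted on a free y scale.
#'
#' @param object a `fraccomm_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.fraccomm_fit <- function(object, ...) {
  long <- object$trace |>
    dplyr::select("epoch", "loss", "rho", "eta_max", "modularity") |>
    tidyr::pivot_longer(-"epoch", names_to = "quantity", values_to = "value") |>
    dplyr::filter(is.finite(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training diagnostics") +
    ggplot2::theme_minimal()
}

#' Per-snapshot stability and quality of a detection
#' @param object a `fraccomm_detection`.
#' @param ... unused.
#' @export
autoplot.fraccomm_detection <- function(object, ...) {
  long <- object$stability |>
    dplyr::select("snapshot", "rho", "eta_max", "modularity") |>
    tidyr::pivot_longer(-"snapshot", names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$snapshot, y = .data$value)) +
    ggplot2::geom_line(colour = "#31a354") +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "snapshot", y = NULL,
                  title = "Per-snapshot stability and modularity") +
    ggplot2::theme_minimal()
}

#' Fractional-order sweep curves
#'
#' Mean stability margin, hallucination index and (when available) ARI as a
#' function of the fractional order, with confidence ribbons.
#'
#' @param object a `fraccomm_sweep` (from [alpha_sweep()]).
#' @param ... unused.
#' @export
autoplot.fraccomm_sweep <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(-"alpha",
                        names_to = c("quantity", ".value"),
                        names_pattern = "(.*)_(mean|delta)$") |>
    dplyr::filter(is.finite(.data$mean))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$alpha, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$delta,
                                      ymax = .data$mean + .data$delta),
                         fill = "grey80") +
    ggplot2::geom_line(colour = "#756bb1") +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "fractional order alpha", y = NULL,
                  title = "Fractional-order sweep") +
    ggplot2::theme_minimal()
}
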