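#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted state model
#'
#' @param x A `state_model` from [kmeans_l1()].
#' @param ... Unused.
#' @return Tibble with one row per clustered sample: `sample`, `state`.
#' @export
tidy.state_model <- function(x, ...) {
  tibble::tibble(sample = seq_along(x$assignments), state = x$assignments)
}

#' One-row summary of a fitted state model
#'
#' @param x A `state_model`.
#' @param ... Unused.
#' @return Tibble with `k`, `objective`, `iterations`, `converged` and the
#'   occupancy fraction of the largest state.
#' @export
glance.state_model <- function(x, ...) {
  tibble::tibble(
    k = x$k, objective = x$objective, iterations = x$iterations,
    converged = x$converged,
    max_occupancy = max(x$sizes) / length(x$assignments))
}

#' Heatmaps of state centroid EC matrices
#'
#' @param object A `state_model` fitted on vectorized EC matrices.
#' @param roi_labels Optional ROI labels for the axes.
#' @param ... Unused.
#' @return A ggplot: one tile panel per state, source ROI on the y axis,
#'   target on the x axis.
#' @export
autoplot.state_model <- function(object, roi_labels = NULL, ...) {
  d <- ncol(object$centroids)
  n <- round((1 + sqrt(1 + 4 * d)) / 2)
  mats <- state_centroid_matrices(object, n)
  labs <- roi_labels %||% as.character(seq_len(n))
  df <- purrr::imap(mats, function(m, i) {
    tibble::tibble(state = paste("State", i),
                   from = rep(labs, times = n),
                   to = rep(labs, each = n),
                   ec = as.vector(m))
  })
  df <- dplyr::bind_rows(df)
  df$from <- factor(df$from, levels = rev(labs))
  df$to <- factor(df$to, levels = labs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$ec)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~state) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "target ROI", y = "source ROI", fill = "EC") +
    ggplot2::theme_minimal()
}

#' Plot cluster-number selection curves
#'
#' @param curves The `curves` tibble from [select_k()].
#' @return A ggplot of silhouette and Calinski-Harabasz versus k (separate
#'   panels, free y scales).
#' @export
plot_selection_curves <- function(curves) {
  long <- tidyr::pivot_longer(curves, c("silhouette", "calinski_harabasz"),
                              names_to = "criterion", values_to = "score")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$score)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~criterion, scales = "free_y") +
    ggplot2::labs(x = "number of states k", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot global metrics across the sparsity grid
#'
#' @param records Tibble of per-subject [global_metrics()] rows with a
#'   `group` column.
#' @return A ggplot of group mean +/- standard error per metric.
#' @export
plot_global_metrics <- function(records) {
  long <- tidyr::pivot_longer(
    records, dplyr::any_of(c("Cp", "Lp", "Eglob", "Eloc", "gamma", "lambda",
                             "sigma")),
    names_to = "metric", values_to = "value")
  summ <- dplyr::summarise(
    dplyr::group_by(long, .data$group, .data$metric, .data$sparsity),
    mean = mean(.data$value), se = stats::sd(.data$value) / sqrt(dplyr::n()),
    .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$sparsity, y = .data$mean,
                                     colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se,
                                      fill = .data$group),
                         alpha = 0.2, colour = NA) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "sparsity", y = NULL) +
    ggplot2::theme_minimal()
}
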