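#' Plot the in-strength distribution of a fit
#'
#' Log-log histogram of transition-matrix column sums; a roughly linear
#' decay is the weighted analogue of a power-law in-degree distribution.
#'
#' @param fit An `mce_fit`.
#' @param n_bins Log-spaced bins (see [in_strength_distribution()]).
#' @return A ggplot object.
#' @export
plot_in_strength <- function(fit, n_bins = 20) {
  h <- in_strength_distribution(fit, n_bins)
  h <- h[h$count > 0, ]
  ggplot2::ggplot(h, ggplot2::aes(x = sqrt(.data$lower * .data$upper),
                                  y = .data$count)) +
    ggplot2::geom_col(width = 0.05) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "in-strength (column sum of P)", y = "genes",
                  title = "In-strength distribution") +
    ggplot2::theme_minimal()
}

#' Histogram of methylation beta values
#'
#' @param beta A beta matrix (genes x samples).
#' @param bins Histogram bins.
#' @return A ggplot object; array-like data shows the familiar peaks near
#'   0.1 and 0.9.
#' @export
plot_beta_distribution <- function(beta, bins = 50) {
  df <- tibble(beta = as.numeric(beta))
  df <- df[!is.na(df$beta), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0) +
    ggplot2::labs(x = "beta value", y = "entries",
                  title = "Methylation beta distribution") +
    ggplot2::theme_minimal()
}

#' Plot a cluster-count entropy curve
#'
#' @param curve A [cluster_entropy_curve()] tibble.
#' @return A ggplot object.
#' @export
plot_entropy_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$k, y = .data$entropy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "clusters (k)", y = "mean cluster-size entropy (nats)",
                  title = "Cluster-count entropy") +
    ggplot2::theme_minimal()
}

#' @describeIn weighted_pagerank Rank-score plot of PageRank scores.
#' @param object A `pagerank_scores` tibble.
#' @param ... Unused.
#' @export
autoplot.pagerank_scores <- function(object, ...) {
  df <- dplyr::arrange(as_tibble(object), dplyr::desc(.data$score))
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$score)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "rank", y = "PageRank score",
                  title = "Weighted PageRank scores") +
    ggplot2::theme_minimal()
}

#' @describeIn markov_flow_entropy Per-gene flow-entropy profile plot.
#' @param object A tibble returned by `markov_flow_entropy()`.
#' @param ... Unused.
#' @export
autoplot.mfe_vector <- function(object, ...) {
  df <- dplyr::arrange(as_tibble(object), dplyr::desc(.data$mfe))
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$mfe)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "gene rank", y = "MFE (nats)",
                  title = "Markov flow entropy profile") +
    ggplot2::theme_minimal()
}
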