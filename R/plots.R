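# Base-graphics views of the main results.

#' Boxplot of per-cell entropy by cluster
#'
#' @param cells Per-cell table from [entropy_by_cluster()] (`$cells`).
#' @param ... Passed to [graphics::boxplot()].
#' @return Invisibly, the boxplot statistics.
#' @export
plot_entropy_clusters <- function(cells, ...) {
  invisible(graphics::boxplot(entropy ~ cluster, data = cells,
                              ylab = "entropy (nats)", xlab = "cluster",
                              main = "transcriptional entropy", ...))
}

#' Line plot of a signal metaprofile
#'
#' @param profile A `Metaprofile`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, NULL.
#' @export
plot_metaprofile <- function(profile, ...) {
  graphics::plot(profile$positions, profile$mean, type = "l",
                 xlab = "position", ylab = "mean signal", ...)
  invisible(NULL)
}

#' Density plot of a spacing distribution with its independence null
#'
#' @param dist A `spacing_distribution`.
#' @param null_W Half-window of the triangular null overlay (defaults to
#'   `dist$window`).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, NULL.
#' @export
plot_spacing_density <- function(dist, null_W = NULL, ...) {
  W <- null_W %||% dist$window
  den <- stats::density(dist$d)
  graphics::plot(den, xlab = "signed distance (bp)",
                 main = sprintf("%s-%s spacing", dist$factor_a,
                                dist$factor_b), ...)
  xs <- seq(-2 * W, 2 * W, length.out = 200)
  graphics::lines(xs, dtri_spacing(xs, W), lty = 2, col = "red")
  invisible(NULL)
}
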