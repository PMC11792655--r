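#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot bootstrap distributions of condition means
#'
#' Accuracy-by-RT scatter of the bootstrapped condition means, colored by
#' label and faceted by group when present.
#'
#' @param object A [bootstrap_condition_means()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.prio_boot <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$mean_accuracy,
                                            y = .data$mean_rt_ms,
                                            colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::labs(x = "accuracy", y = "reaction time (ms)",
                  colour = "label") +
    ggplot2::theme_minimal()
  if ("group" %in% names(object)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$group))
  }
  p
}

#' Plot group-level posterior densities of a DDM parameter
#'
#' @param object A [fit_hddm()] result.
#' @param parameter One of `"v"`, `"a"`, `"z"`, `"t0"`.
#' @param ... Unused.
#' @return A ggplot of posterior densities per cell (and group).
#' @exportS3Method ggplot2::autoplot
autoplot.prio_hddm <- function(object, parameter = "v", ...) {
  parameter <- match.arg(parameter, c("v", "a", "z", "t0"))
  keep <- seq.int(object$burn_in + 1, object$n_samples)
  m <- ddm_to_natural[[parameter]](
    object$draws$mu[[parameter]][keep, , drop = FALSE])
  df <- as_tibble(as.data.frame(m)) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "cell",
                        values_to = "value") |>
    tidyr::separate_wider_delim("cell", ":", names = c("group", "cell"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, colour = .data$cell)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(ggplot2::vars(.data$group), scales = "free") +
    ggplot2::labs(x = sprintf("group-level %s", parameter), y = "density") +
    ggplot2::theme_minimal()
}

#' Plot a time-frequency representation
#'
#' Channel-averaged power (or ERS/ERD) as a time x frequency heat map.
#'
#' @param object A [tf_power()]/[ers_erd()] result.
#' @param channels Channels to average (default all).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.prio_tfr <- function(object, channels = NULL, ...) {
  ci <- if (is.null(channels)) seq_along(object$channels) else {
    match(normalize_channels(channels), object$channels)
  }
  pw <- object$power
  if (object$keep_trials) pw <- apply(pw, c(2, 3, 4), mean)
  m <- apply(pw[ci, , , drop = FALSE], c(2, 3), mean)
  df <- tidyr::expand_grid(freq = object$freqs, time = object$times)
  df$power <- as.vector(t(m)) # m is freq x time; expand_grid is time-fastest
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$freq,
                                   fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "time (ms)", y = "frequency (Hz)",
                  fill = if (isTRUE(object$normalized)) "ERS/ERD" else "power") +
    ggplot2::theme_minimal()
}

#' Plot the point-wise t map with cluster outlines
#'
#' @param object A [cluster_permutation()] result.
#' @param times Optional time axis (ms).
#' @param ... Unused.
#' @return A ggplot tile map of t values; points inside observed clusters
#'   are outlined.
#' @exportS3Method ggplot2::autoplot
autoplot.prio_clusters <- function(object, times = NULL, ...) {
  tmap <- attr(object, "t_map")
  labels <- attr(object, "labels")
  channels <- rownames(tmap) %||% paste0("ch", seq_len(nrow(tmap)))
  times <- times %||% seq_len(ncol(tmap))
  df <- tidyr::expand_grid(channel = channels, time = times)
  df$t <- as.vector(t(tmap)) # tmap is channel x time; expand_grid time-fastest
  df$in_cluster <- as.vector(t(labels)) > 0
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$channel)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$t)) +
    ggplot2::geom_point(data = dplyr::filter(df, .data$in_cluster),
                        size = 0.3, colour = "black") +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "time", y = "channel", fill = "t") +
    ggplot2::theme_minimal()
}

#' Plot canonical loadings
#'
#' @param object A [canonical_correlation()] result.
#' @param ... Unused.
#' @return A ggplot bar chart of structure loadings per block.
#' @exportS3Method ggplot2::autoplot
autoplot.prio_cca <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$loading, y = .data$variable)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$block), scales = "free_y") +
    ggplot2::labs(x = "structure loading", y = NULL) +
    ggplot2::theme_minimal()
}
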