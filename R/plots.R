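#' Plot a video frame
#'
#' @param v A [video_volume()].
#' @param t Frame index.
#' @param points Optional interest-point tibble to overlay.
#' @return A ggplot object.
#' @export
plot_frame <- function(v, t = 1L, points = NULL) {
  d <- dim(v)
  df <- tibble::tibble(x = rep(seq_len(d[2]), each = d[1]),
                       y = rep(seq_len(d[1]), times = d[2]),
                       value = as.vector(v[, , t]))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("frame %d", t), fill = "intensity")
  if (!is.null(points)) {
    pts <- dplyr::filter(points, abs(.data$t - !!t) <= 2)
    if (nrow(pts))
      p <- p + ggplot2::geom_point(data = pts,
                                   ggplot2::aes(.data$x, .data$y),
                                   inherit.aes = FALSE, colour = "red",
                                   shape = 1, size = 3)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Accuracy overview of a protocol run
#'
#' @param object A [run_protocol()] result.
#' @param ... Unused.
#' @return A ggplot object: per-fold accuracies with the overall mean.
#' @method autoplot nas_protocol
#' @export
autoplot.nas_protocol <- function(object, ...) {
  ggplot2::ggplot(object$folds,
                  ggplot2::aes(.data$condition, .data$accuracy,
                               colour = .data$classifier)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18, size = 4) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "held-out accuracy",
                  title = "Leave-one-subject-out accuracy by condition")
}

#' Confusion-matrix heat map
#'
#' @param confusion A confusion matrix from a protocol run (counts, truth in
#'   rows).
#' @return A ggplot object with row-normalized shading.
#' @export
plot_confusion <- function(confusion) {
  df <- as.data.frame(confusion)
  df$frac <- stats::ave(df$Freq, df$truth, FUN = function(v) v / max(sum(v), 1))
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth,
                                   fill = .data$frac)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq), colour = "white") +
    ggplot2::scale_fill_gradient(low = "grey20", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(fill = "row fraction")
}

#' Mosaic of an IC basis rendered as its middle frame
#'
#' @param basis An [fit_ica()] basis.
#' @param n Number of components to show.
#' @param cfg A [scale_config()].
#' @return A ggplot object.
#' @export
plot_ic_mosaic <- function(basis, n = 16L, cfg = scale_config()) {
  cm <- circular_mask(cfg$target[1])
  d <- cfg$target[1]; np <- nrow(cm$order)
  mid <- (cfg$target[2] + 1L) %/% 2L
  n <- min(n, basis$n_ic)
  rows <- lapply(seq_len(n), function(i) {
    fr <- matrix(NA_real_, d, d)
    fr[cm$order] <- basis$components[i, (mid - 1L) * np + seq_len(np)]
    tibble::tibble(ic = i, x = rep(seq_len(d), each = d),
                   y = rep(seq_len(d), times = d), value = as.vector(fr))
  })
  ggplot2::ggplot(dplyr::bind_rows(rows),
                  ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~ic) +
    ggplot2::scale_fill_gradient2(na.value = "transparent") +
    ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::labs(title = "IC middle frames", fill = NULL)
}
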