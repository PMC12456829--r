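#' @title Plotting methods
#' @name plots
#' @description
#' ggplot2 `autoplot()` methods for the main result types: FC and contrast
#' heatmaps, BOLD traces with the stimulation epoch shaded, and the
#' windowed mean-FC trajectory colored by dFC phase.
NULL

#' @rdname plots
#' @param object An `fc_matrix`.
#' @param ... Unused.
#' @method autoplot fc_matrix
#' @export
autoplot.fc_matrix <- function(object, ...) {
  tb <- tidy(object)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$from, y = .data$to,
                                   fill = .data$fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "FC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @rdname plots
#' @method autoplot bold_series
#' @export
autoplot.bold_series <- function(object, ...) {
  tb <- tidy(object)
  p <- ggplot2::ggplot(tb, ggplot2::aes(x = .data$time_s, y = .data$bold,
                                        group = .data$region)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "time (s)", y = "BOLD (%)") +
    ggplot2::theme_minimal()
  proto <- object$protocol
  if (proto$duration_s > 0 && proto$label != "Without") {
    p <- p + ggplot2::annotate("rect",
                               xmin = object$t0_s + proto$onset_s,
                               xmax = object$t0_s + proto$onset_s +
                                 proto$duration_s,
                               ymin = -Inf, ymax = Inf, alpha = 0.15,
                               fill = "orange")
  }
  p
}

#' @rdname plots
#' @method autoplot dfc_stack
#' @export
autoplot.dfc_stack <- function(object, ...) {
  tb <- tidy(object)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$window, y = .data$mean_fc,
                                   color = factor(.data$phase))) +
    ggplot2::geom_line(ggplot2::aes(group = 1)) +
    ggplot2::labs(x = "window", y = "mean FC", color = "phase") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @method autoplot condition_contrast
#' @export
autoplot.condition_contrast <- function(object, ...) {
  tb <- tidy(object)
  tb$t_masked <- ifelse(tb$rejected, tb$t, NA_real_)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$edge_i, y = .data$edge_j,
                                   fill = .data$t_masked)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(na.value = "grey90") +
    ggplot2::labs(x = "region", y = "region", fill = "t (FDR)") +
    ggplot2::theme_minimal()
}

#' Seed dFC propagation map
#'
#' Heatmap of per-window FC with the seed, rows ordered weak-to-strong
#' (bottom to top) by SC weight to the seed.
#'
#' @param map Result of [seed_dfc_map()].
#' @return A ggplot.
#' @export
plot_seed_dfc_map <- function(map) {
  m <- map$map
  tb <- tibble::tibble(
    rank = rep(seq_len(nrow(m)), times = ncol(m)),
    window = rep(seq_len(ncol(m)), each = nrow(m)),
    fc = as.numeric(m))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$window, y = .data$rank,
                                   fill = .data$fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "window", y = "region (weak to strong SC)",
                  fill = "FC to seed") +
    ggplot2::theme_minimal()
}
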