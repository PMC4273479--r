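#' Plot localized CNV calls along the genome
#'
#' One point per analysis window at its adjusted ratio r, colored by call
#' state, faceted by chromosome.
#'
#' @param object A `ght_calls` tibble from [call_localized()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ght_calls
#' @export
autoplot.ght_calls <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                   y = .data$r, color = .data$state)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::scale_color_manual(values = c(gain = "#2166ac", loss = "#b2182b",
                                           neutral = "grey60")) +
    ggplot2::labs(x = "position (bp)", y = "adjusted depth ratio r",
                  color = "call") +
    ggplot2::theme_minimal()
}

#' Plot extended CNV segments over window Z scores
#'
#' Window Z scores as points with segment means overlaid as horizontal
#' bars, colored by extended CNV state, faceted by chromosome.
#'
#' @param object A `cbs_segments` tibble from [call_extended()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cbs_segments
#' @export
autoplot.cbs_segments <- function(object, ...) {
  z <- attr(object, "z")
  segs <- tidy(object)
  thr <- attr(object, "z_threshold")
  p <- ggplot2::ggplot() +
    ggplot2::geom_point(data = z,
                        ggplot2::aes(x = (.data$start + .data$end) / 2,
                                     y = .data$z),
                        size = 0.4, alpha = 0.5, color = "grey40") +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = .data$mean_z, yend = .data$mean_z,
                                       color = .data$state),
                          linewidth = 1.5) +
    ggplot2::geom_hline(yintercept = c(-thr, thr), linetype = "dotted") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::scale_color_manual(values = c(gain = "#b2182b", loss = "#2166ac",
                                           neutral = "grey60")) +
    ggplot2::labs(x = "position (bp)", y = "Z score", color = "segment") +
    ggplot2::theme_minimal()
  p
}

#' Plot the cohort recurrence distribution
#'
#' The exact Poisson-binomial density of the cross-cohort CNV count under
#' independence, with the recurrence cutoff marked and the observed
#' per-window counts as a rug.
#'
#' @param object A `recurrent_cnv` from [flag_recurrent()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot recurrent_cnv
#' @export
autoplot.recurrent_cnv <- function(object, ...) {
  pmf <- tibble::tibble(k = seq_along(object$pmf) - 1L, prob = object$pmf)
  ggplot2::ggplot(pmf, ggplot2::aes(x = .data$k, y = .data$prob)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$cutoff - 0.5, color = "red") +
    ggplot2::geom_rug(data = object$windows, ggplot2::aes(x = .data$k),
                      inherit.aes = FALSE, alpha = 0.2) +
    ggplot2::labs(x = "samples carrying the CNV (k)",
                  y = "null probability P(K = k)",
                  title = paste0("Recurrence cutoff k* = ", object$cutoff)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Depth-vs-GC diagnostic plot
#'
#' Scatter of window depth against GC fraction with a loess trend, the
#' standard diagnostic for GC capture bias before/after correction.
#'
#' @param profile A GC-annotated depth profile.
#' @param covered_only Drop zero-depth windows (default TRUE).
#' @return A ggplot object.
#' @export
plot_gc_bias <- function(profile, covered_only = TRUE) {
  df <- profile
  if (covered_only) df <- dplyr::filter(df, .data$depth > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gc, y = .data$depth)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.4) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         color = "red") +
    ggplot2::labs(x = "GC fraction", y = "window depth") +
    ggplot2::theme_minimal()
}
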