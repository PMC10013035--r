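# ggplot2 quick-look plots for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a BPRSA curve
#'
#' Curve values against the window offset `j`, with the target's global
#' mean as reference line.
#'
#' @param object A `bprsa_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bprsa_curve <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$value)) +
    ggplot2::geom_hline(yintercept = object$target_mean,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "window offset j (samples)", y = "BPRSA value",
      title = sprintf("BPRSA curve (%s, m = %d windows)",
                      object$target_label, object$m)
    )
}

#' Plot detection-limit isolines
#'
#' Critical coupling strength against series length on log-log axes, with
#' the bootstrap 5-95 percent band.
#'
#' @param object An `isoline_result` (rows of several detectors may be
#'   bound together before plotting).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.isoline_result <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$q_crit))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$q_crit,
                                   colour = .data$detector,
                                   fill = .data$detector)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "series length N", y = "critical coupling q",
                  title = "p = 0.05 detection isolines")
}

#' Plot a region-classification map
#'
#' @param object A `region_map` result.
#' @param ... Unused.
#' @return A ggplot object (tile map over the coupling grid, log axes).
#' @export
autoplot.region_map <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$q_yz, y = .data$q_yx,
                               fill = .data$region)) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "coupling y -> z", y = "coupling y -> x",
                  fill = "region",
                  title = "pairwise/conditional classification")
}

#' Plot a causal network's edges
#'
#' Weighted mean G per directed pair, with bootstrap standard-error bars,
#' faceted by sleep stage; resolutions are shown side by side.
#'
#' @param object A `causal_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.causal_network <- function(object, ...) {
  df <- dplyr::mutate(object$edges,
                      edge = paste(.data$source, "→", .data$target))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$edge, y = .data$g_mean,
                                   fill = factor(.data$resolution))) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$g_mean - .data$g_se,
                   ymax = .data$g_mean + .data$g_se),
      position = ggplot2::position_dodge(width = 0.8), width = 0.3
    ) +
    ggplot2::facet_wrap(~stage) +
    ggplot2::labs(x = NULL, y = "conditional G (weighted mean ± SE)",
                  fill = "resolution (s)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom rlang .data
NULL
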