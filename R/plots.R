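#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_ribbon scale_x_log10 scale_y_log10 scale_fill_gradient2 labs
#'   theme_minimal
#' @export
ggplot2::autoplot

#' Plot a contact-probability curve
#'
#' @param object A `pcs_curve`.
#' @param ... Unused.
#' @return A ggplot: P_c(s) on log-log axes (plus the slope panel if the curve
#'   carries a `slope` column from [pcs_slope()]).
#' @export
autoplot.pcs_curve <- function(object, ...) {
  d <- object[object$p > 0, ]
  ggplot(d, aes(x = s_mid, y = p)) +
    geom_line(colour = "grey30") +
    geom_point(size = 0.8) +
    scale_x_log10(labels = function(x) x / 1e6) +
    scale_y_log10() +
    labs(x = "genomic separation s (Mb)", y = expression(P[c](s))) +
    theme_minimal()
}

#' Plot a slope series
#'
#' @param slopes Output of [pcs_slope()].
#' @return A ggplot of the smoothed log-log slope vs separation.
#' @export
plot_pcs_slope <- function(slopes) {
  ggplot(slopes, aes(x = s_mid, y = slope)) +
    geom_line() +
    scale_x_log10(labels = function(x) x / 1e6) +
    labs(x = "genomic separation s (Mb)", y = "d log P / d log s") +
    theme_minimal()
}

aggregate_tile_plot <- function(m, legend) {
  d <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  d$value <- as.vector(m[cbind(d$row, d$col)])
  ggplot(d, aes(x = col, y = row, fill = log2(pmax(value, 1e-6)))) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick",
                         midpoint = 0, name = legend) +
    labs(x = NULL, y = NULL) +
    ggplot2::scale_y_reverse() +
    theme_minimal()
}

#' Plot an aggregate loop map
#'
#' @param object A `loop_aggregate`.
#' @param ... Unused.
#' @return A ggplot heat map of the background-rescaled observed/control
#'   window.
#' @export
autoplot.loop_aggregate <- function(object, ...) {
  aggregate_tile_plot(object$ratio, "log2 obs/ctrl") +
    labs(title = sprintf("loop strength %.2f (n = %d)", object$strength,
                         object$n_loops))
}

#' Plot an aggregate rescaled-TAD map
#'
#' @param object A `tad_aggregate`.
#' @param ... Unused.
#' @return A ggplot heat map of the rescaled observed/expected average.
#' @export
autoplot.tad_aggregate <- function(object, ...) {
  aggregate_tile_plot(object$average, "log2 obs/exp") +
    labs(title = sprintf("TAD strength ratio %.2f (n = %d)", object$strength,
                         object$n_tads))
}

#' Plot a compartment saddle
#'
#' @param object A `saddle_matrix`.
#' @param ... Unused.
#' @return A ggplot heat map of the corrected saddle (group 1 = lowest GC).
#' @export
autoplot.saddle_matrix <- function(object, ...) {
  aggregate_tile_plot(object$saddle / mean(object$saddle), "log2 rel.") +
    labs(title = sprintf("compartment strength %.2f", object$strength))
}

#' Plot an insulation profile aligned at boundaries
#'
#' @param object An `insulation_profile`.
#' @param ... Unused.
#' @return A ggplot of the mean normalized insulation with a +/- 1 SE ribbon.
#' @export
autoplot.insulation_profile <- function(object, ...) {
  d <- object$aligned
  ggplot(d, aes(x = offset_bins * object$resolution / 1e3, y = mean)) +
    geom_ribbon(aes(ymin = mean - se, ymax = mean + se), alpha = 0.25) +
    geom_line() +
    labs(x = "distance from boundary (kb)",
         y = "normalized insulation score") +
    theme_minimal()
}

#' Plot the extruded-loop size distribution
#'
#' @param object A `loop_size_stats`.
#' @param ... Unused.
#' @return A ggplot histogram of post-equilibration loop spans with the mean
#'   marked.
#' @export
autoplot.loop_size_stats <- function(object, ...) {
  d <- object$snapshots[object$snapshots$after_equilibration, ]
  ggplot(d, aes(x = span_bp / 1e3)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$mean_loop_bp / 1e3,
                        colour = "firebrick") +
    labs(x = "extruded loop span (kb)", y = "snapshots") +
    theme_minimal()
}
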