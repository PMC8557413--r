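#' Plot a window profile
#'
#' Mirrors the standard presentation of upstream composition scans: mean
#' statistic per window with a ±SE ribbon, window 1 nearest the feature
#' start, significant windows starred (GC-percent profiles).
#'
#' @param object A `window_profile` tibble from [gc_permutation_test()] or
#'   [skew_profiles()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.window_profile <- function(object, ...) {
  stat <- attr(object, "stat")
  lab <- if (identical(stat, "gc_skew")) "GC skew (C-G)/(C+G)" else "GC (%)"
  has_set <- "set" %in% names(object)
  p <- ggplot2::ggplot(object, ggplot2::aes(
    x = .data$window, y = .data$mean_stat,
    colour = if (has_set) .data$set else NULL,
    fill = if (has_set) .data$set else NULL)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_stat - .data$se_stat,
                                      ymax = .data$mean_stat + .data$se_stat),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "window (1 = nearest the start)", y = lab,
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  if ("significant" %in% names(object) && any(object$significant)) {
    sig <- object[object$significant, ]
    p <- p + ggplot2::geom_point(data = sig, shape = 8, show.legend = FALSE)
  }
  p
}

#' Plot a sliding-window divergence test
#'
#' Window amino-acid ML distances along the gene with the sRNA-region
#' distance marked, visualising the excess conservation of the
#' asRNA-encoding region.
#'
#' @param object A `divergence_window_test`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.divergence_window_test <- function(object, ...) {
  w <- object$windows
  ggplot2::ggplot(w, ggplot2::aes(x = .data$start_codon, y = .data$distance)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::annotate("rect", xmin = object$region_bounds[[1]],
                      xmax = object$region_bounds[[2]],
                      ymin = -Inf, ymax = Inf, alpha = 0.15) +
    ggplot2::geom_hline(yintercept = object$region_distance,
                        linetype = "dashed") +
    ggplot2::labs(x = "window start (codon)",
                  y = "amino-acid ML distance",
                  title = sprintf("region d = %.3f, P = %.3g",
                                  object$region_distance, object$p_value)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
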