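#' Quadrant report of sensor vs camera step timings
#'
#' Scatter of camera overlap (x) against the sensor's signed timing (y).
#' Positive data from either system indicate legal steps; negative data
#' indicate illegal steps. The top-right and bottom-left quadrants hold
#' agreements (legal/legal and illegal/illegal); the top-left quadrant
#' holds camera-illegal steps the sensor missed; the bottom-right quadrant
#' holds camera-legal steps the sensor flagged as illegal. Points on an
#' axis (threshold cases) are counted on the legal side, consistent with
#' the labelling rules.
#'
#' Quadrant membership is taken from the stored `camera_label` and
#' `sensor_verdict`, so the counts always agree with [confusion()].
#'
#' @param pairs A non-empty `step_comparison` data frame.
#' @param file Optional path; when given the plot is saved there (format
#'   from the extension).
#' @return A list of class `quadrant_report` with `counts` (named vector:
#'   `top_right`, `bottom_left`, `top_left`, `bottom_right`) and `plot`
#'   (a ggplot object).
#' @export
quadrant_report <- function(pairs, file = NULL) {
  stopifnot(is.data.frame(pairs))
  if (nrow(pairs) == 0L)
    stop("quadrant report requires at least one paired step")
  cam_legal <- pairs$camera_label %in% c("legal", "threshold")
  sen_legal <- pairs$sensor_verdict == "legal"
  counts <- c(top_right = sum(cam_legal & sen_legal),
              bottom_left = sum(!cam_legal & !sen_legal),
              top_left = sum(!cam_legal & sen_legal),
              bottom_right = sum(cam_legal & !sen_legal))
  df <- data.frame(camera = pairs$camera_overlap,
                   sensor = pairs$sensor_overlap,
                   agreement = ifelse(cam_legal == sen_legal,
                                      "agree", "disagree"))
  rng <- range(c(df$camera, df$sensor, 0))
  pad <- 0.05 * diff(rng) + 1e-3
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$camera,
                                        y = .data$sensor)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$agreement),
                        alpha = 0.6, size = 2) +
    ggplot2::scale_colour_manual(
      values = c(agree = "#2166ac", disagree = "#b2182b")) +
    ggplot2::annotate("text", x = rng[2] + pad, y = rng[2] + pad,
                      label = sprintf("legal/legal: %d",
                                      counts["top_right"]),
                      hjust = 1, vjust = 1, size = 3) +
    ggplot2::annotate("text", x = rng[1] - pad, y = rng[1] - pad,
                      label = sprintf("illegal/illegal: %d",
                                      counts["bottom_left"]),
                      hjust = 0, vjust = 0, size = 3) +
    ggplot2::annotate("text", x = rng[1] - pad, y = rng[2] + pad,
                      label = sprintf("missed: %d", counts["top_left"]),
                      hjust = 0, vjust = 1, size = 3) +
    ggplot2::annotate("text", x = rng[2] + pad, y = rng[1] - pad,
                      label = sprintf("flagged: %d",
                                      counts["bottom_right"]),
                      hjust = 1, vjust = 0, size = 3) +
    ggplot2::labs(x = "camera ground-contact overlap (s)",
                  y = "sensor timing (s)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(file)) ggplot2::ggsave(file, p, width = 6, height = 6)
  out <- list(counts = counts, plot = p)
  class(out) <- "quadrant_report"
  out
}

#' @export
print.quadrant_report <- function(x, ...) {
  cat("<quadrant_report>\n")
  cat(sprintf(
    "  legal/legal %d  illegal/illegal %d  missed %d  flagged %d\n",
    x$counts["top_right"], x$counts["bottom_left"],
    x$counts["top_left"], x$counts["bottom_right"]))
  invisible(x)
}
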