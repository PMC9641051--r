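#' Plot a moment-rotation curve, optionally annotated with its kinetics
#'
#' Draws the sampled moment-rotation data and, when a [process_curve()]
#' result is supplied, marks the neutral-zone bounds (vertical lines) and
#' overlays the neutral-zone and elastic-zone least-squares fit lines.
#'
#' @param curve Curve tibble (`rotation_deg`, `moment_Nm`, optional
#'   `branch`).
#' @param result Optional `kinetics_result` for annotation.
#' @return A ggplot object.
#' @export
plot_moment_rotation <- function(curve, result = NULL) {
  p <- ggplot2::ggplot(curve,
                       ggplot2::aes(x = .data$rotation_deg,
                                    y = .data$moment_Nm)) +
    ggplot2::geom_path(ggplot2::aes(group = if ("branch" %in% names(curve))
      .data$branch else 1), colour = "grey30", linewidth = 0.4) +
    ggplot2::labs(x = "Rotation [deg]", y = "Moment [Nm]") +
    ggplot2::theme_minimal()
  if (!is.null(result)) {
    stopifnot(inherits(result, "kinetics_result"))
    nz <- result$nz_bounds
    band <- result$protocol$ez_band
    limit <- result$protocol$moment_limit
    cv <- result$curve
    seg <- function(sel, slope) {
      x <- cv$rotation_deg[sel]
      y <- cv$moment_Nm[sel]
      x0 <- mean(x); y0 <- mean(y)
      tibble::tibble(x = min(x), xend = max(x),
                     y = y0 + slope * (min(x) - x0),
                     yend = y0 + slope * (max(x) - x0))
    }
    segs <- dplyr::bind_rows(
      nz = seg(cv$rotation_deg >= nz[1] & cv$rotation_deg <= nz[2],
               result$nz_stiffness),
      ez_pos = seg(cv$moment_Nm >= band[1] & cv$moment_Nm <= limit,
                   result$ezs_pos),
      ez_neg = seg(cv$moment_Nm <= -band[1] & cv$moment_Nm >= -limit,
                   result$ezs_neg),
      .id = "zone"
    )
    p <- p +
      ggplot2::geom_vline(xintercept = unname(nz), linetype = "dashed",
                          colour = "steelblue") +
      ggplot2::geom_segment(
        data = segs,
        ggplot2::aes(x = .data$x, xend = .data$xend,
                     y = .data$y, yend = .data$yend, colour = .data$zone),
        linewidth = 0.9, inherit.aes = FALSE) +
      ggplot2::scale_colour_manual(
        values = c(nz = "firebrick", ez_pos = "darkorange",
                   ez_neg = "darkgreen"),
        labels = c(nz = "NZ fit", ez_pos = "EZ fit (+)",
                   ez_neg = "EZ fit (-)"),
        name = NULL)
  }
  p
}

#' Autoplot method for kinetics results
#'
#' @param object A `kinetics_result`.
#' @param ... Unused.
#' @return A ggplot of the analysed branch annotated with the fitted zones.
#' @export
autoplot.kinetics_result <- function(object, ...) {
  plot_moment_rotation(object$curve, object)
}
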