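#' Plot one axial slice of a volume, optionally with a mask outline
#'
#' @param volume A [volume_grid()].
#' @param z Slice index along the third (cranio-caudal) axis.
#' @param mask Optional [roi_mask()]; foreground voxels are outlined.
#' @param limits Colour limits, default `c(0, 30)` percent as commonly used
#'   to window muscle PDFF maps.
#' @return A ggplot object.
#' @export
plot_slice <- function(volume, z = 1, mask = NULL, limits = c(0, 30)) {
  d <- dim(volume$values)
  df <- tidyr::expand_grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$pdff <- as.vector(volume$values[, , z])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$pdff)) +
    ggplot2::scale_fill_viridis_c(limits = limits, oob = scales_squish,
                                  name = "PDFF [%]") +
    ggplot2::coord_fixed(ratio = volume$spacing[2] / volume$spacing[1]) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL, title = paste0("slice z = ", z))
  if (!is.null(mask)) {
    df$fg <- as.vector(mask$values[, , z]) == 1
    p <- p + ggplot2::geom_tile(data = df[df$fg, ], fill = NA,
                                colour = "white", linewidth = 0.1)
  }
  p
}

# minimal squish so scales is not a hard dependency surface
scales_squish <- function(x, range = c(0, 1), ...) {
  pmin(pmax(x, range[1]), range[2])
}

#' Plot a correlation screen
#'
#' Horizontal bar chart of Pearson r per variable, Bonferroni-significant
#' variables highlighted.
#'
#' @param object A [correlation_screen()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pdff_screen <- function(object, ...) {
  df <- object[!is.na(object$r), ]
  df$variable <- factor(df$variable, levels = rev(df$variable))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$variable,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "#b2182b"),
                               name = "Bonferroni\nsignificant") +
    ggplot2::labs(x = "Pearson r", y = NULL,
                  title = paste("Correlation screen vs",
                                unique(df$outcome))) +
    ggplot2::theme_minimal()
}

#' Plot the coefficients of a stepwise model
#'
#' Point-and-interval plot of the selected coefficients (95 % Wald
#' intervals), intercept omitted.
#'
#' @param object A [stepwise_regression()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.stepwise_lm <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$term != "(Intercept)", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std_error,
      xmax = .data$estimate + 1.96 * .data$std_error), height = 0.15) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "coefficient", y = NULL,
                  title = paste("Stepwise model for", object$outcome)) +
    ggplot2::theme_minimal()
}
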