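#' Plot a caudocranial compartment profile
#'
#' @param object An `axial_profile` tibble (see [axial_profile()]).
#' @param ... Unused.
#' @return A ggplot: per-slice compartment volume, caudal to cranial.
#' @export
autoplot.axial_profile <- function(object, ...) {
  dat <- dplyr::filter(object, .data$compartment != "excluded")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$slice,
                                    y = .data$volume_mm3,
                                    colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "slice (caudal to cranial)",
                  y = expression(volume ~ (mm^3)),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-subject percent changes by group
#'
#' Bar chart of a percent-change variable stratified by response group,
#' mirroring the usual cohort summary figure.
#'
#' @param data Cohort tibble.
#' @param variable Percent-change column to plot.
#' @param by Grouping column.
#' @return A ggplot.
#' @export
plot_cohort_changes <- function(data, variable, by = "response") {
  ggplot2::ggplot(data,
                  ggplot2::aes(x = .data[[by]], y = .data[[variable]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = paste(variable, "(% from baseline)")) +
    ggplot2::theme_minimal()
}

#' Plot a fat-fraction slice with compartment outlines
#'
#' Quick-look raster of one slice's fat fraction with the segmentation
#' labels overlaid as colours.
#'
#' @param fw A `fat_water_result`.
#' @param compartments Optional `body_compartments` for the overlay.
#' @param slice Slice index.
#' @return A ggplot.
#' @export
plot_ff_slice <- function(fw, compartments = NULL, slice = 1L) {
  ff <- fw$FF[slice, , ]
  df <- expand.grid(row = seq_len(nrow(ff)), col = seq_len(ncol(ff)))
  df$FF <- as.vector(ff)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$FF)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(compartments)) {
    lab <- compartments$labels[slice, , ]
    df$label <- factor(as.vector(lab), levels = 0:4,
                       labels = names(COMPARTMENT))
    ov <- df[df$label %in% c("SCAT", "VAT"), , drop = FALSE]
    p <- p + ggplot2::geom_point(data = ov,
                                 ggplot2::aes(colour = .data$label),
                                 size = 0.1, alpha = 0.4) +
      ggplot2::scale_colour_manual(values = c(SCAT = "royalblue",
                                              VAT = "red"))
  }
  p
}
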