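#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot group distributions of concordance scores
#'
#' Boxplots with jittered per-patient points for the selected per-lesion
#' variables, split by group.
#'
#' @param object a `cohort_tables` object.
#' @param variables per-lesion columns to show.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_tables <- function(object,
                                   variables = c("dice", "overlap_volume"),
                                   ...) {
  df <- tidyr::pivot_longer(object$records,
                            cols = dplyr::all_of(variables),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.12, height = 0, size = 1.6, alpha = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Paired MRI vs PET volume comparison plot
#'
#' Per-patient MRI-defined and PET-defined volumes connected by a line, the
#' standard display for showing how much the metabolic volume exceeds the
#' contrast-enhanced volume in each group.
#'
#' @param records per-patient records tibble (from [analyze_cohort()] or
#'   [run_cohort()]'s `metrics.csv`) with `volume_mri`, `volume_fby` and
#'   `group` columns.
#' @return A ggplot object.
#' @export
plot_volume_comparison <- function(records) {
  records <- tibble::as_tibble(records)
  records$.pid <- seq_len(nrow(records))
  df <- tidyr::pivot_longer(records,
                            cols = c("volume_mri", "volume_fby"),
                            names_to = "roi", values_to = "volume_ml")
  df$roi <- factor(df$roi, levels = c("volume_mri", "volume_fby"),
                   labels = c("MRI", "PET"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$roi, y = .data$volume_ml)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$.pid), alpha = 0.5) +
    ggplot2::geom_point(ggplot2::aes(color = .data$roi), size = 2) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = NULL, y = "volume (mL)", color = "segmentation") +
    ggplot2::theme_minimal()
}

#' Plot an axial slice with optional mask overlays
#'
#' Quick-look display of one axial (z) slice of a volume with mask contours,
#' for checking segmentations against the underlying image.
#'
#' @param image a [volume_image()] or [suv_map()].
#' @param masks named list of [binary_mask()]s to outline.
#' @param z slice index (1-based); defaults to the middle slice.
#' @return A ggplot object.
#' @export
plot_slice_overlay <- function(image, masks = list(), z = NULL) {
  img <- as_suv_image(image)
  d <- dim(img$values)
  if (is.null(z)) z <- ceiling(d[3] / 2)
  sl <- img$values[, , z]
  df <- expand.grid(x = img$origin[1] + (seq_len(d[1]) - 1) * img$spacing[1],
                    y = img$origin[2] + (seq_len(d[2]) - 1) * img$spacing[2])
  df$value <- as.vector(sl)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = NULL) +
    ggplot2::theme_minimal()
  cols <- grDevices::hcl.colors(max(1L, length(masks)), "Dark 2")
  i <- 0L
  for (nm in names(masks)) {
    i <- i + 1L
    mdf <- df
    mdf$m <- as.vector(masks[[nm]]$values[, , z])
    if (any(mdf$m > 0)) {
      p <- p + ggplot2::geom_contour(data = mdf,
                                     ggplot2::aes(z = .data$m),
                                     breaks = 0.5, color = cols[i],
                                     linewidth = 0.6)
    }
  }
  p
}
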