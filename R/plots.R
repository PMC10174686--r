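#' @importFrom ggplot2 ggplot aes autoplot geom_segment geom_raster
#'   geom_histogram geom_violin geom_point geom_line geom_vline labs
#'   scale_fill_viridis_c coord_equal theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Quiver plot of a displacement field
#'
#' @param object A [displacement_field()] tibble.
#' @param scale Arrow length multiplier.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot piv_field
autoplot.piv_field <- function(object, scale = 1, ...) {
  d <- dplyr::filter(object, .data$valid)
  ggplot(d, aes(x = .data$x, y = .data$y,
                xend = .data$x + scale * .data$u,
                yend = .data$y + scale * .data$v)) +
    geom_segment(arrow = grid::arrow(length = grid::unit(1.5, "mm"))) +
    coord_equal() +
    labs(x = "x (µm)", y = "y (µm)",
         title = "PIV displacement field") +
    theme_minimal()
}

#' Heat map of a ciliary beat frequency map
#'
#' @param object A `spectral_map` from [cbf_map()].
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot spectral_map
autoplot.spectral_map <- function(object, ...) {
  d <- dplyr::mutate(object,
                     f = ifelse(.data$valid, .data$peak_frequency, NA))
  ggplot(d, aes(x = .data$col, y = .data$row, fill = .data$f)) +
    geom_raster() +
    scale_fill_viridis_c(name = "CBF (Hz)", na.value = "grey85") +
    coord_equal() +
    labs(x = "x (px)", y = "y (px)", title = "Ciliary beat frequency") +
    theme_minimal()
}

#' Histogram of region speeds with classification thresholds
#'
#' @param speeds Output of [region_speeds()].
#' @param low,high Thresholds drawn as reference lines (um/hr).
#' @param binwidth Histogram bin width (um/hr).
#' @return A ggplot.
#' @export
plot_speed_distribution <- function(speeds, low = 1.5, high = 4,
                                    binwidth = 0.25) {
  ggplot(speeds, aes(x = .data$speed_um_hr)) +
    geom_histogram(binwidth = binwidth, fill = "grey40") +
    geom_vline(xintercept = c(low, high), linetype = "dashed") +
    labs(x = "region speed (µm/hr)", y = "regions",
         title = "Region speed distribution") +
    theme_minimal()
}

#' Violin plot of signature scores by group
#'
#' @param scores A [score_cells()] tibble.
#' @param group_col Metadata column to group by.
#' @return A ggplot.
#' @export
plot_scores <- function(scores, group_col = "group") {
  check_that(group_col %in% names(scores), "grouping column not found")
  ggplot(scores, aes(x = .data[[group_col]], y = .data$score)) +
    geom_violin(fill = "grey80") +
    geom_point(position = ggplot2::position_jitter(width = 0.1),
               size = 0.4, alpha = 0.4) +
    labs(x = group_col, y = "signature score",
         title = unique(scores$signature)[1]) +
    theme_minimal()
}

#' Scree plot of a PCA embedding
#'
#' @param object A `behavex_pca`.
#' @param n Components to show.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot behavex_pca
autoplot.behavex_pca <- function(object, n = 30, ...) {
  d <- tibble(pc = seq_along(object$var_explained),
              var = object$var_explained)
  d <- head(d, n)
  ggplot(d, aes(x = .data$pc, y = .data$var)) +
    geom_point() + geom_line() +
    labs(x = "principal component", y = "variance explained",
         title = "PCA scree") +
    theme_minimal()
}
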