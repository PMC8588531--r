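# ggplot2 views of the result objects. Box plots follow the Tukey
# convention with outliers suppressed from the drawing (they stay in the
# data); RMSE maps are raster heat maps; dictionaries are drawn as
# overlaid atom line plots.

#' Plot spectra
#'
#' @param spectra A spectra tibble.
#' @param colour_by Column mapped to colour (default `id`; use `class`
#'   for scenes).
#' @return A ggplot object.
#' @export
plot_spectra <- function(spectra, colour_by = "id") {
  ggplot2::ggplot(spectra,
                  ggplot2::aes(x = .data$wavelength, y = .data$reflectance,
                               group = .data$id,
                               colour = .data[[colour_by]])) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "wavelength [nm]", y = "reflectance") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ksvd_dictionary <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$wavelength, y = .data$value,
                               colour = .data$atom)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength [nm]", y = "atom value (unit norm)",
                  title = paste0("K-SVD atoms (K = ", object$k, ")")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.updm_bases <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$wavelength, y = .data$reflectance,
                               colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength [nm]", y = "reflectance",
                  title = "UPDM base spectra") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$method, y = .data$rmse)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::coord_cartesian(
      ylim = c(0, grDevices::boxplot.stats(object$per_pixel$rmse)$stats[5] *
                 1.1)) +
    ggplot2::labs(x = NULL, y = "per-pixel RMSE (reflectance)") +
    ggplot2::theme_minimal()
}

#' Compare evaluation reports as side-by-side box plots
#'
#' @param reports List of `eval_report` objects (optionally named).
#' @return A ggplot object; one outlier-suppressed box per report,
#'   faceted by the number of measured bands when it varies.
#' @export
plot_method_comparison <- function(reports) {
  df <- purrr::imap_dfr(reports, function(r, nm) {
    dplyr::mutate(tidy(r),
                  label = if (is.character(nm) && nzchar(nm)) nm else
                    r$method,
                  m = r$config$m %||% NA_integer_)
  })
  upper <- stats::quantile(df$rmse, 0.95)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$rmse)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::coord_cartesian(ylim = c(0, upper)) +
    ggplot2::labs(x = NULL, y = "per-pixel RMSE (reflectance)") +
    ggplot2::theme_minimal()
  if (length(unique(df$m)) > 1) {
    p <- p + ggplot2::facet_wrap(~m, labeller = ggplot2::label_both)
  }
  p
}

#' Band-set transferability plot
#'
#' Scores of the same candidate band sets on two datasets, each sorted by
#' its own RMSE, with lines connecting identical sets: parallel lines mean
#' the ranking transfers, crossing lines in the plateau mean it does not.
#'
#' @param scores_a,scores_b Score tibbles from [score_band_sets()] over
#'   the same candidates.
#' @param labels Character vector of two dataset labels.
#' @return A ggplot object.
#' @export
plot_band_transfer <- function(scores_a, scores_b,
                               labels = c("dataset A", "dataset B")) {
  key <- function(s) vapply(s$bands, paste, character(1), collapse = ",")
  a <- dplyr::mutate(scores_a, set = key(scores_a), dataset = labels[1])
  b <- dplyr::mutate(scores_b, set = key(scores_b), dataset = labels[2])
  df <- dplyr::bind_rows(a, b)[, c("dataset", "rank", "median_rmse", "set")]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dataset, y = .data$median_rmse,
                                   group = .data$set)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$set),
                        show.legend = FALSE) +
    ggplot2::labs(y = "median RMSE (reflectance)", x = NULL) +
    ggplot2::theme_minimal()
}

#' Heat map of a per-pixel RMSE map
#'
#' @param map Tibble from [rmse_map()].
#' @return A ggplot object.
#' @export
plot_rmse_map <- function(map) {
  ggplot2::ggplot(map, ggplot2::aes(x = .data$col, y = .data$row,
                                    fill = .data$rmse)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "RMSE") +
    ggplot2::theme_minimal()
}

#' Lowest / median / highest RMSE spectra overlay
#'
#' @param illustrative Tibble from [illustrative_spectra()].
#' @return A ggplot object.
#' @export
plot_illustrative <- function(illustrative) {
  df <- dplyr::mutate(illustrative,
                      role = factor(.data$role,
                                    c("lowest", "median", "highest")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavelength,
                                   y = .data$reflectance,
                                   linetype = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~role) +
    ggplot2::labs(x = "wavelength [nm]", y = "reflectance") +
    ggplot2::theme_minimal()
}
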