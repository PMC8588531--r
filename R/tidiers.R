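# broom-style accessors for the fitted objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a K-SVD dictionary
#'
#' @param x A `ksvd_dictionary`.
#' @param ... Unused.
#' @return Long tibble with `atom`, `wavelength`, `value`.
#' @export
tidy.ksvd_dictionary <- function(x, ...) {
  k <- ncol(x$atoms)
  tibble::tibble(
    atom = rep(paste0("atom", seq_len(k)), each = nrow(x$atoms)),
    wavelength = rep(x$wavelengths, times = k),
    value = as.vector(x$atoms)
  )
}

#' @rdname tidy.ksvd_dictionary
#' @export
glance.ksvd_dictionary <- function(x, ...) {
  tibble::tibble(
    k = x$k, sparsity_target = x$t, iterations = x$n_iter,
    n_bands = nrow(x$atoms),
    training_error = if (length(x$error_trace)) {
      utils::tail(x$error_trace, 1)
    } else NA_real_,
    seed = x$seed
  )
}

#' Tidy UPDM bases
#'
#' @param x An `updm_bases`.
#' @param ... Unused.
#' @return Long tibble with `class`, `wavelength`, `reflectance`.
#' @export
tidy.updm_bases <- function(x, ...) {
  tibble::tibble(
    class = rep(updm_classes, each = nrow(x$bases)),
    wavelength = rep(x$wavelengths, times = 3),
    reflectance = as.vector(x$bases)
  )
}

#' @rdname tidy.updm_bases
#' @export
glance.updm_bases <- function(x, ...) {
  tibble::tibble(n_bands = nrow(x$bases),
                 gram_condition = x$gram_condition)
}

#' Tidy an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return The per-pixel long tibble (`replication`, `id`, `rmse`).
#' @export
tidy.eval_report <- function(x, ...) {
  dplyr::mutate(x$per_pixel, method = x$method, .before = 1)
}

#' @rdname tidy.eval_report
#' @export
glance.eval_report <- function(x, ...) {
  pooled <- x$per_pixel$rmse
  bs <- grDevices::boxplot.stats(pooled)$stats
  tibble::tibble(
    method = x$method,
    m = x$config$m %||% NA_integer_,
    replications = length(x$per_replication_medians),
    n_pixels = length(unique(x$per_pixel$id)),
    median_of_medians = x$median_of_medians,
    pooled_median = bs[3], pooled_q1 = bs[2], pooled_q3 = bs[4],
    pooled_iqr = bs[4] - bs[2],
    whisker_low = bs[1], whisker_high = bs[5]
  )
}
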