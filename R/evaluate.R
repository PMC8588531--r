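# Quantitative evaluation protocol: per-pixel RMSE over all N bands, the
# median across pixels per replication, and the median of the replication
# medians as the headline number. Replications redraw the band set (and,
# for DCS, the pixel grouping) under derived seeds.

#' Root-mean-square error between two spectra
#'
#' @param estimate,reference Numeric vectors on the same grid.
#' @return `sqrt(mean((estimate - reference)^2))`.
#' @export
rmse <- function(estimate, reference) {
  if (length(estimate) != length(reference)) {
    stop("spectra have different lengths", call. = FALSE)
  }
  sqrt(mean((estimate - reference)^2))
}

rmse_cols <- function(E, R) unname(sqrt(colMeans((E - R)^2)))

#' Per-pixel RMSE between two spectra tibbles
#'
#' @param estimate,reference Spectra tibbles on one grid with matching ids.
#' @return Tibble with `id` and `rmse` (plus `row`, `col`, `class` when the
#'   reference carries them).
#' @export
spectra_rmse <- function(estimate, reference) {
  e <- as_spectra_matrix(estimate)
  r <- as_spectra_matrix(reference)
  if (!identical(e$ids, r$ids) ||
      max(abs(e$wavelengths - r$wavelengths)) > 1e-9) {
    stop("estimate and reference must share grid and pixel ids",
         call. = FALSE)
  }
  out <- tibble::tibble(id = r$ids, rmse = rmse_cols(e$values, r$values))
  if (!is.null(r$class)) out$class <- r$class
  if (!is.null(r$coords)) { out$row <- r$coords$row; out$col <- r$coords$col }
  out
}

#' Per-pixel RMSE map of a reconstructed scene
#'
#' @param reconstructed,reference Spectra tibbles with `row`/`col`
#'   coordinates on the same grid.
#' @return Tibble `row`, `col`, `rmse` suitable for [plot_rmse_map()] or
#'   export as a single-band image.
#' @export
rmse_map <- function(reconstructed, reference) {
  out <- spectra_rmse(reconstructed, reference)
  if (!all(c("row", "col") %in% names(out))) {
    stop("reference has no pixel coordinates", call. = FALSE)
  }
  out[, c("row", "col", "rmse", intersect("class", names(out)))]
}

new_eval_report <- function(method, rmse_matrix, ids, config) {
  meds <- apply(rmse_matrix, 2, stats::median)
  structure(list(
    method = method,
    per_pixel = tibble::tibble(
      replication = rep(seq_len(ncol(rmse_matrix)), each = nrow(rmse_matrix)),
      id = rep(ids, times = ncol(rmse_matrix)),
      rmse = as.vector(rmse_matrix)
    ),
    per_replication_medians = meds,
    median_of_medians = stats::median(meds),
    config = config
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Evaluation report:", x$method, "\n")
  cat("  pixels:", length(unique(x$per_pixel$id)),
      " replications:", length(x$per_replication_medians), "\n")
  cat("  median of per-replication median RMSE:",
      signif(x$median_of_medians, 4), "\n")
  invisible(x)
}

#' Evaluate a reconstruction method under the replication protocol
#'
#' For each of `replications` replications a band set is drawn (or taken
#' from `band_sets`, cycled -- the best-band-set mode), every evaluation
#' pixel is measured at it and reconstructed, and the median per-pixel
#' RMSE is recorded; the report carries the median of those medians.
#'
#' @param spectra Evaluation spectra tibble (the reference truth).
#' @param context A `ksvd_dictionary` or `updm_bases` object.
#' @param m Number of measured bands (ignored when `band_sets` is given).
#' @param replications Number of replications (default 20).
#' @param seed Master seed; band-set seeds are derived from it.
#' @param band_sets Optional list of band sets to cycle through instead of
#'   random draws (e.g. the kept best sets).
#' @param ... Passed to the method's reconstruction routine.
#' @return An `eval_report`.
#' @export
evaluate_method <- function(spectra, context, m = NULL, replications = 20,
                            seed = 1, band_sets = NULL, ...) {
  stopifnot(replications >= 1)
  sm <- as_spectra_matrix(spectra)
  n <- length(sm$wavelengths)
  seeds <- derive_seeds(seed, "eval-bands", replications)
  rmse_mat <- matrix(NA_real_, length(sm$ids), replications)
  used_sets <- vector("list", replications)
  for (r in seq_len(replications)) {
    bs <- if (!is.null(band_sets)) {
      band_sets[[(r - 1L) %% length(band_sets) + 1L]]
    } else {
      random_band_set(n, m, seeds[r])
    }
    est <- reconstruct_with(context, sm$values, bs, ...)
    rmse_mat[, r] <- rmse_cols(est, sm$values)
    used_sets[[r]] <- as.integer(bs)
  }
  new_eval_report(method_tag(context), rmse_mat, sm$ids,
                  list(m = m %||% length(used_sets[[1]]),
                       replications = replications, seed = seed,
                       band_sets = used_sets))
}

reconstruct_with <- function(context, values, bands, ...) {
  Y <- values[as.integer(bands), , drop = FALSE]
  if (inherits(context, "ksvd_dictionary")) {
    reconstruct_ksvd_mat(Y, context, bands, ...)
  } else if (inherits(context, "updm_bases")) {
    reconstruct_updm_mat(Y, context, bands, ...)
  } else {
    stop("unsupported method context: ", paste(class(context),
                                               collapse = "/"),
         call. = FALSE)
  }
}

method_tag <- function(context) {
  if (inherits(context, "ksvd_dictionary")) "ksvd"
  else if (inherits(context, "updm_bases")) "updm"
  else class(context)[1]
}

#' Evaluate grouped JSM-1 reconstruction (DCS and DCS-GM)
#'
#' Replications are the cross of `band_reps` per-node band-set assignments
#' with `groupings` independent pixel groupings (default 4 x 5 = 20). The
#' plain report treats each of the crossed runs as a replication; the
#' group-median report takes, per band-set assignment, the per-band median
#' over the groupings' estimates (one median spectrum per pixel), so it
#' has `band_reps` replications.
#'
#' @param spectra Evaluation spectra tibble.
#' @param m Bands per node.
#' @param band_reps Number of band-set assignments (default 4).
#' @param groupings Number of independent groupings L (default 5).
#' @param group_size Joint-solve group size (default 64).
#' @param seed Master seed.
#' @param ... Passed to [sl0()].
#' @return List with `dcs` and `dcs_gm` eval reports.
#' @export
evaluate_dcs <- function(spectra, m, band_reps = 4, groupings = 5,
                         group_size = 64, seed = 1, ...) {
  sm <- as_spectra_matrix(spectra)
  n <- length(sm$wavelengths)
  p <- length(sm$ids)
  values <- `colnames<-`(sm$values, sm$ids)
  band_seeds <- derive_seeds(seed, "dcs-bands", band_reps)
  group_seeds <- derive_seeds(seed, "dcs-groups", groupings)
  plain <- matrix(NA_real_, p, band_reps * groupings)
  gm <- matrix(NA_real_, p, band_reps)
  rep_i <- 0L
  for (b in seq_len(band_reps)) {
    node_bands <- assign_band_sets(p, n, m, band_seeds[b])
    ests <- vector("list", groupings)
    for (g in seq_len(groupings)) {
      groups <- group_pixels(sm$ids, group_size, group_seeds[g])
      est <- dcs_reconstruct_mat(values, node_bands, groups, ...)
      rep_i <- rep_i + 1L
      plain[, rep_i] <- rmse_cols(est, sm$values)
      ests[[g]] <- est
    }
    med <- apply(simplify2array(ests), c(1, 2), stats::median)
    gm[, b] <- rmse_cols(med, sm$values)
  }
  cfg <- list(m = m, band_reps = band_reps, groupings = groupings,
              group_size = group_size, seed = seed)
  list(dcs = new_eval_report("dcs", plain, sm$ids, cfg),
       dcs_gm = new_eval_report("dcs-gm", gm, sm$ids, cfg))
}

#' Pick the lowest / median / highest RMSE spectra for illustration
#'
#' @param estimate,reference Spectra tibbles with matching ids.
#' @return Tibble of the three pixels' reference and estimated spectra in
#'   long form with columns `role` (`lowest`/`median`/`highest`), `kind`
#'   (`reference`/`estimate`), `id`, `wavelength`, `reflectance`.
#' @export
illustrative_spectra <- function(estimate, reference) {
  per <- spectra_rmse(estimate, reference)
  ord <- order(per$rmse)
  pick <- c(lowest = ord[1],
            median = ord[ceiling(length(ord) / 2)],
            highest = ord[length(ord)])
  purrr::map_dfr(names(pick), function(role) {
    pid <- per$id[pick[[role]]]
    dplyr::bind_rows(
      dplyr::mutate(dplyr::filter(reference, .data$id == pid),
                    kind = "reference"),
      dplyr::mutate(dplyr::filter(estimate, .data$id == pid),
                    kind = "estimate")
    ) |>
      dplyr::mutate(role = role) |>
      dplyr::select(dplyr::all_of(c("role", "kind", "id", "wavelength",
                                    "reflectance")))
  })
}
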