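# Band-subsampling measurement model: a multispectral node measures M of
# the N hyperspectral bands. The sensing operator is the M x N row-selection
# matrix picking those bands; measurements are exact band selections (any
# sensor noise belongs to the scene generator, so all reconstruction
# methods face the identical measurement model).

#' Draw a random band set
#'
#' @param n_bands Number of hyperspectral bands N.
#' @param m Number of measured bands M, `1 <= m <= n_bands`.
#' @param seed Integer seed; identical seeds give identical sets.
#' @return Sorted integer vector of `m` unique 1-based band indices.
#' @export
random_band_set <- function(n_bands, m, seed) {
  stopifnot(n_bands >= 1)
  if (m < 1 || m > n_bands) {
    stop("band-set size m must satisfy 1 <= m <= n_bands", call. = FALSE)
  }
  band_set(with_seed(seed, sample.int(n_bands, m)), n_bands)
}

band_set <- function(indices, n_bands) {
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) < 1 || min(indices) < 1 || max(indices) > n_bands) {
    stop("band indices must be unique integers in [1, n_bands]",
         call. = FALSE)
  }
  structure(indices, n_bands = as.integer(n_bands), class = "band_set")
}

#' Row-selection sensing matrix
#'
#' @param bands A band set (integer indices) from [random_band_set()].
#' @param n_bands Grid length N (taken from the band set if available).
#' @return The M x N 0/1 selection matrix with one 1 per row.
#' @export
sensing_matrix <- function(bands, n_bands = attr(bands, "n_bands")) {
  stopifnot(!is.null(n_bands), max(bands) <= n_bands)
  phi <- matrix(0, nrow = length(bands), ncol = n_bands)
  phi[cbind(seq_along(bands), as.integer(bands))] <- 1
  phi
}

#' Measure spectra at a band set
#'
#' Applies the band-subsampling sensing operator to every spectrum: the
#' measurement is the reflectance at the selected bands, no mixing.
#'
#' @param spectra A spectra tibble on the full working grid.
#' @param bands Band set (1-based indices into the grid).
#' @return A spectra tibble restricted to the measured bands.
#' @export
measure_spectra <- function(spectra, bands) {
  wl <- spectra_grid(spectra)
  n_bands <- attr(bands, "n_bands")
  if (!is.null(n_bands) && n_bands != length(wl)) {
    stop("band set was drawn for a ", n_bands, "-band grid, spectra have ",
         length(wl), " bands", call. = FALSE)
  }
  stopifnot(max(bands) <= length(wl))
  keep <- wl[as.integer(bands)]
  dplyr::filter(spectra, .data$wavelength %in% keep)
}

#' Assign band sets to the nodes of a sensor network
#'
#' Heterogeneous mode draws an independent random band set per node;
#' homogeneous mode gives every node the same set (the mass-fabrication
#' case, where unmeasured bands must be supplied by a learned dictionary).
#'
#' @param n_nodes Number of sensor nodes.
#' @param n_bands Grid length N.
#' @param m Bands per node.
#' @param seed Integer seed.
#' @param homogeneous If `TRUE`, all nodes share one band set.
#' @return List of `n_nodes` band sets.
#' @export
assign_band_sets <- function(n_nodes, n_bands, m, seed,
                             homogeneous = FALSE) {
  stopifnot(n_nodes >= 1)
  if (homogeneous) {
    bs <- random_band_set(n_bands, m, seed)
    return(rep(list(bs), n_nodes))
  }
  seeds <- derive_seeds(seed, "node-bands", n_nodes)
  lapply(seeds, function(s) random_band_set(n_bands, m, s))
}

# Counter-based fan-out of one master seed into independent sub-seeds,
# kept below 2^31 (R integers are 32-bit).
derive_seeds <- function(master, label, n) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.numeric(master) * 48271 + h * 1009 + seq_len(n) * 7919) %% 2147483647
}

#' Serialize band sets to JSON
#'
#' Writes 0-based indices plus a grid fingerprint (band count, range) so a
#' band set cannot silently be applied to the wrong grid.
#'
#' @param band_sets List of band sets.
#' @param wavelengths The grid the sets index into.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_band_sets <- function(band_sets, wavelengths, path) {
  obj <- list(
    grid = list(n_bands = length(wavelengths),
                first_nm = min(wavelengths), last_nm = max(wavelengths)),
    band_sets = lapply(band_sets, function(b) as.integer(b) - 1L)
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_band_sets
#' @export
read_band_sets <- function(path, wavelengths) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (obj$grid$n_bands != length(wavelengths)) {
    stop("band sets were saved for a different grid", call. = FALSE)
  }
  lapply(obj$band_sets, function(b) {
    band_set(unlist(b) + 1L, length(wavelengths))
  })
}
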