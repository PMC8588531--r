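#' Build a spectra tibble
#'
#' The package's universal currency is a long tibble of per-pixel reflectance
#' spectra sharing one wavelength grid: columns `id`, `wavelength` (nm),
#' `reflectance`, and optionally `class` (one of `"vegetation"`, `"soil"`,
#' `"water"`, `"builtup"`) and pixel coordinates `row`, `col`.
#'
#' @param wavelengths Strictly increasing numeric vector of wavelengths in nm.
#' @param values Numeric matrix, `length(wavelengths)` rows, one column per
#'   spectrum; or a numeric vector for a single spectrum.
#' @param ids Optional character vector of spectrum identifiers (default
#'   `"s1"`, `"s2"`, ...).
#' @param class Optional character vector of per-spectrum class labels.
#' @param coords Optional data frame with columns `row`, `col`, one row per
#'   spectrum; coordinates must be unique.
#' @return A tibble with one row per (spectrum, band).
#' @examples
#' spectra_tbl(c(450, 550, 650), cbind(a = c(0.1, 0.2, 0.1)))
#' @export
spectra_tbl <- function(wavelengths, values, ids = NULL, class = NULL,
                        coords = NULL) {
  check_grid(wavelengths)
  if (is.vector(values)) values <- matrix(values, ncol = 1L)
  values <- as.matrix(values)
  if (nrow(values) != length(wavelengths)) {
    stop("`values` must have one row per wavelength", call. = FALSE)
  }
  p <- ncol(values)
  if (is.null(ids)) {
    ids <- colnames(values)
    if (is.null(ids)) ids <- paste0("s", seq_len(p))
  }
  if (length(ids) != p) stop("one id per spectrum required", call. = FALSE)
  if (anyDuplicated(ids)) stop("spectrum ids must be unique", call. = FALSE)
  if (!all(is.finite(values))) {
    stop("reflectance values must be finite", call. = FALSE)
  }
  if (p > 0 && (min(values) < 0 || max(values) > 1.5)) {
    warning("reflectance outside [0, 1.5]; check units/scaling", call. = FALSE)
  }
  out <- tibble::tibble(
    id = rep(ids, each = length(wavelengths)),
    wavelength = rep(wavelengths, times = p),
    reflectance = as.vector(values)
  )
  if (!is.null(class)) {
    stopifnot(length(class) == p)
    out$class <- rep(class, each = length(wavelengths))
  }
  if (!is.null(coords)) {
    stopifnot(nrow(coords) == p)
    if (anyDuplicated(coords[, c("row", "col")])) {
      stop("pixel coordinates must be unique", call. = FALSE)
    }
    out$row <- rep(coords$row, each = length(wavelengths))
    out$col <- rep(coords$col, each = length(wavelengths))
  }
  out
}

check_grid <- function(wavelengths) {
  if (length(wavelengths) < 1 || !all(is.finite(wavelengths))) {
    stop("wavelength grid must be non-empty and finite", call. = FALSE)
  }
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  }
  invisible(wavelengths)
}

#' Shared wavelength grid of a spectra tibble
#'
#' @param spectra A spectra tibble (see [spectra_tbl()]).
#' @return Sorted numeric vector of wavelengths (nm) common to all spectra.
#' @export
spectra_grid <- function(spectra) {
  wl <- sort(unique(spectra$wavelength))
  check_grid(wl)
  wl
}

# Long tibble -> list(wavelengths, values [N x P], ids, class, coords).
# Validates that every spectrum sits on the shared grid.
as_spectra_matrix <- function(spectra) {
  stopifnot(all(c("id", "wavelength", "reflectance") %in% names(spectra)))
  wl <- spectra_grid(spectra)
  n <- length(wl)
  ids <- unique(spectra$id)
  ord <- order(match(spectra$id, ids), spectra$wavelength)
  s <- spectra[ord, ]
  if (nrow(s) != n * length(ids) ||
      !all(s$wavelength == rep(wl, times = length(ids)))) {
    stop("all spectra must share one wavelength grid (ragged set)",
         call. = FALSE)
  }
  values <- matrix(s$reflectance, nrow = n, ncol = length(ids),
                   dimnames = list(NULL, ids))
  first <- s[seq(1L, nrow(s), by = n), , drop = FALSE]
  cls <- if ("class" %in% names(s)) first$class else NULL
  coords <- if (all(c("row", "col") %in% names(s))) {
    tibble::tibble(row = first$row, col = first$col)
  } else NULL
  list(wavelengths = wl, values = values, ids = ids,
       class = cls, coords = coords)
}

n_spectra <- function(spectra) length(unique(spectra$id))

#' Restrict spectra to a wavelength range
#'
#' Keeps only the bands with `lo <= wavelength <= hi`. The default range,
#' 406--1100 nm, is the intersection typically shared by visible/NIR field
#' spectrometers and airborne imagers; it is a convention, not a constraint.
#'
#' @param spectra A spectra tibble.
#' @param lo,hi Range bounds in nm, `lo < hi`.
#' @return The clipped spectra tibble.
#' @export
clip_spectra <- function(spectra, lo = 406, hi = 1100) {
  stopifnot(lo < hi)
  out <- dplyr::filter(spectra, .data$wavelength >= lo, .data$wavelength <= hi)
  if (nrow(out) == 0) {
    stop("clipping to [", lo, ", ", hi, "] nm leaves no bands",
         call. = FALSE)
  }
  out
}

#' Resample spectra onto a target wavelength grid
#'
#' Band matching across sensors is done by nearest-band selection, not
#' interpolation: for each target wavelength the closest source band is
#' taken verbatim (ties break to the lower wavelength). This mirrors how a
#' denser field-spectrometer grid is reduced to an imager's band positions.
#'
#' @param spectra A spectra tibble on the (denser) source grid.
#' @param target Numeric vector: target wavelengths in nm.
#' @param max_gap Maximum tolerated distance (nm) between a target band and
#'   its nearest source band; beyond it the source does not cover the target.
#' @return Spectra tibble on the target grid.
#' @export
resample_spectra <- function(spectra, target, max_gap = 10) {
  check_grid(target)
  sm <- as_spectra_matrix(spectra)
  src <- sm$wavelengths
  idx <- vapply(target, function(w) {
    d <- abs(src - w)
    j <- which(d == min(d))[1L]  # ties: which() returns lower index first
    j
  }, integer(1))
  gaps <- abs(src[idx] - target)
  if (any(gaps > max_gap)) {
    bad <- target[gaps > max_gap][1L]
    stop("no source band within ", max_gap, " nm of target band ", bad,
         " nm", call. = FALSE)
  }
  spectra_tbl(target, sm$values[idx, , drop = FALSE], ids = sm$ids,
              class = sm$class, coords = sm$coords)
}

#' Default working wavelength grid
#'
#' @param n_bands Number of bands (default 40).
#' @param lo,hi Range in nm (default 406--1100).
#' @return Evenly spaced wavelength vector.
#' @export
default_grid <- function(n_bands = 40, lo = 406, hi = 1100) {
  seq(lo, hi, length.out = n_bands)
}
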