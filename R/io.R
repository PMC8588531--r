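#' Read a spectral library CSV
#'
#' Format: UTF-8 CSV with a header row; first column is wavelength in nm,
#' each remaining column one spectrum (column name = spectrum id).
#'
#' @param path Path to the CSV file.
#' @return A spectra tibble.
#' @export
read_spectral_library <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) < 1) stop("empty spectral library", call. = FALSE)
  wl <- raw[[1]]
  if (is.unsorted(wl, strictly = TRUE)) {
    stop("spectral library wavelengths must be strictly increasing",
         call. = FALSE)
  }
  vals <- as.matrix(raw[, -1, drop = FALSE])
  if (ncol(vals) > 0 && !is.numeric(vals)) {
    stop("non-numeric reflectance columns in spectral library", call. = FALSE)
  }
  spectra_tbl(wl, vals, ids = colnames(raw)[-1])
}

#' Write a spectral library CSV
#'
#' @param spectra A spectra tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectral_library <- function(spectra, path) {
  if (nrow(spectra) == 0) {
    writeLines("wavelength", path)
    return(invisible(path))
  }
  sm <- as_spectra_matrix(spectra)
  out <- tibble::as_tibble(as.data.frame(sm$values))
  names(out) <- sm$ids
  out <- tibble::add_column(out, wavelength = sm$wavelengths, .before = 1)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# ---- ENVI cubes --------------------------------------------------------
# Minimal ENVI support: BSQ/BIL interleave, data types 4 (float32),
# 5 (float64), 12 (uint16, optionally with a "reflectance scale factor"
# header entry dividing raw integers to unitless reflectance). No installed
# package reads ENVI, so the .hdr grammar and binary layout are handled here.

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  get_scalar <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?mi)^\\s*", key,
                                        "\\s*=\\s*([^\\n{]+)"), txt,
                                 perl = TRUE))[[1]]
    if (length(m) < 2) NULL else trimws(m[2])
  }
  get_list <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?si)", key,
                                        "\\s*=\\s*\\{([^}]*)\\}"), txt,
                                 perl = TRUE))[[1]]
    if (length(m) < 2) return(NULL)
    as.numeric(strsplit(gsub("\\s", "", m[2]), ",")[[1]])
  }
  hdr <- list(
    samples = as.integer(get_scalar("samples")),
    lines = as.integer(get_scalar("lines")),
    bands = as.integer(get_scalar("bands")),
    data_type = as.integer(get_scalar("data type")),
    interleave = tolower(get_scalar("interleave")),
    byte_order = as.integer(get_scalar("byte order") %||% "0"),
    scale = if (is.null(get_scalar("reflectance scale factor"))) {
      NA_real_
    } else as.numeric(get_scalar("reflectance scale factor")),
    wavelengths = get_list("wavelength")
  )
  for (f in c("samples", "lines", "bands", "data_type", "interleave")) {
    if (is.null(hdr[[f]]) || any(is.na(hdr[[f]]))) {
      stop("ENVI header missing field '", gsub("_", " ", f), "'",
           call. = FALSE)
    }
  }
  if (is.null(hdr$wavelengths)) {
    stop("ENVI header has no wavelength list", call. = FALSE)
  }
  if (length(hdr$wavelengths) != hdr$bands) {
    stop("ENVI header wavelength count does not match bands", call. = FALSE)
  }
  hdr
}

#' Read an ENVI cube
#'
#' Supports BSQ and BIL interleave with float32, float64 or uint16 samples;
#' a `reflectance scale factor` header entry on integer data is applied so
#' the returned values are unitless reflectance. Wavelengths must be listed
#' in the header.
#'
#' @param hdr_path Path to the ENVI `.hdr` file; the binary is looked up as
#'   the same path without `.hdr`, or with `.bsq`/`.bil`/`.dat` extensions.
#' @return A spectra tibble with complete `row`/`col` coordinates
#'   (ids `"r<row>c<col>"`), row-major over the scene.
#' @export
read_envi_cube <- function(hdr_path) {
  hdr <- parse_envi_header(hdr_path)
  if (!hdr$interleave %in% c("bsq", "bil")) {
    stop("unsupported ENVI interleave '", hdr$interleave,
         "' (only bsq/bil)", call. = FALSE)
  }
  stem <- sub("\\.hdr$", "", hdr_path)
  cand <- c(stem, paste0(stem, c(".bsq", ".bil", ".dat", ".img")))
  bin <- cand[file.exists(cand)][1]
  if (is.na(bin)) stop("ENVI binary for ", hdr_path, " not found",
                       call. = FALSE)
  n_el <- hdr$samples * hdr$lines * hdr$bands
  endian <- if (hdr$byte_order == 1) "big" else "little"
  con <- file(bin, "rb")
  on.exit(close(con))
  raw_vals <- switch(as.character(hdr$data_type),
    "4" = readBin(con, "numeric", n = n_el, size = 4, endian = endian),
    "5" = readBin(con, "numeric", n = n_el, size = 8, endian = endian),
    "12" = readBin(con, "integer", n = n_el, size = 2, signed = FALSE,
                   endian = endian),
    stop("unsupported ENVI data type ", hdr$data_type, call. = FALSE))
  if (length(raw_vals) != n_el) {
    stop("ENVI binary size does not match header dimensions", call. = FALSE)
  }
  # reorder to [band, pixel] with pixels row-major (line, then sample)
  if (hdr$interleave == "bsq") {
    a <- array(raw_vals, dim = c(hdr$samples, hdr$lines, hdr$bands))
    vals <- matrix(aperm(a, c(3, 1, 2)), nrow = hdr$bands)
  } else { # bil: sample fastest, then band, then line
    a <- array(raw_vals, dim = c(hdr$samples, hdr$bands, hdr$lines))
    vals <- matrix(aperm(a, c(2, 1, 3)), nrow = hdr$bands)
  }
  # columns of vals are pixels ordered sample-fastest within each line
  if (!is.na(hdr$scale) && hdr$data_type == 12) vals <- vals / hdr$scale
  coords <- expand.grid(col = seq_len(hdr$samples), row = seq_len(hdr$lines))
  coords <- tibble::tibble(row = coords$row, col = coords$col)
  ids <- sprintf("r%dc%d", coords$row, coords$col)
  spectra_tbl(hdr$wavelengths, vals, ids = ids, coords = coords)
}

#' Write an ENVI cube
#'
#' Emits BSQ float32 plus a `.hdr` carrying the wavelength list. The spectra
#' tibble must have complete `row`/`col` coordinates forming a full grid.
#'
#' @param spectra A spectra tibble with `row` and `col` columns.
#' @param path Output stem; `<path>.bsq` and `<path>.hdr` are written.
#' @return `path`, invisibly.
#' @export
write_envi_cube <- function(spectra, path) {
  sm <- as_spectra_matrix(spectra)
  if (is.null(sm$coords)) {
    stop("ENVI output needs row/col pixel coordinates", call. = FALSE)
  }
  rows <- max(sm$coords$row)
  cols <- max(sm$coords$col)
  if (nrow(sm$coords) != rows * cols) {
    stop("pixel coordinates do not form a complete grid", call. = FALSE)
  }
  n <- length(sm$wavelengths)
  # order pixels sample-fastest (col), then line (row)
  ord <- order(sm$coords$row, sm$coords$col)
  vals <- sm$values[, ord, drop = FALSE]
  bsq <- as.vector(t(vals))  # for each band, all pixels
  con <- file(paste0(path, ".bsq"), "wb")
  writeBin(bsq, con, size = 4, endian = "little")
  close(con)
  hdr <- c(
    "ENVI",
    paste0("samples = ", cols),
    paste0("lines = ", rows),
    paste0("bands = ", n),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    paste0("wavelength units = nm"),
    paste0("wavelength = {", paste(format(sm$wavelengths, trim = TRUE),
                                   collapse = ", "), "}")
  )
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
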