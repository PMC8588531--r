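# Universal pattern decomposition: model every pixel spectrum as a linear
# mix of three high-resolution base spectra (water, vegetation, soil),
# estimate the mixing fractions from the measured bands by least squares,
# and recompose the full-resolution spectrum from the bases.

updm_classes <- c("water", "vegetation", "soil")

#' Extract water/vegetation/soil base spectra from labelled pixels
#'
#' Per class, the base spectrum is the mean of the labelled pure pixels
#' (deterministic and noise-robust); `single_pixel = TRUE` instead takes
#' the first labelled pixel verbatim.
#'
#' @param labelled A spectra tibble with a `class` column covering at least
#'   one pixel of each of `water`, `vegetation`, `soil`.
#' @param single_pixel Use one pixel per class instead of the class mean.
#' @return An `updm_bases` object: N x 3 base matrix on the working grid,
#'   with the condition number of the 3 x 3 Gram matrix recorded.
#' @export
extract_bases <- function(labelled, single_pixel = FALSE) {
  sm <- as_spectra_matrix(labelled)
  if (is.null(sm$class)) stop("labelled spectra need a `class` column",
                              call. = FALSE)
  missing <- setdiff(updm_classes, unique(sm$class))
  if (length(missing) > 0) {
    stop("no labelled pixels for class(es): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  B <- vapply(updm_classes, function(cl) {
    cols <- which(sm$class == cl)
    if (single_pixel) sm$values[, cols[1]]
    else rowMeans(sm$values[, cols, drop = FALSE])
  }, numeric(length(sm$wavelengths)))
  g <- crossprod(B)
  structure(list(bases = B, wavelengths = sm$wavelengths,
                 gram_condition = kappa(g, exact = TRUE)),
            class = "updm_bases")
}

#' Bases from explicit spectra
#'
#' @param water,vegetation,soil Spectra tibbles each holding one spectrum
#'   on a shared grid (e.g. noiseless endmembers).
#' @return An `updm_bases` object.
#' @export
updm_bases <- function(water, vegetation, soil) {
  combined <- dplyr::bind_rows(
    dplyr::mutate(water, id = "water", class = "water"),
    dplyr::mutate(vegetation, id = "vegetation", class = "vegetation"),
    dplyr::mutate(soil, id = "soil", class = "soil")
  )
  extract_bases(combined, single_pixel = TRUE)
}

#' @export
print.updm_bases <- function(x, ...) {
  cat("UPDM base spectra (water, vegetation, soil) on",
      length(x$wavelengths), "bands;",
      "Gram condition number", signif(x$gram_condition, 4), "\n")
  invisible(x)
}

#' Estimate material fractions from a multispectral measurement
#'
#' Solves the M x 3 least-squares problem `y ~ [Phi w, Phi v, Phi s] f` for
#' the water/vegetation/soil fractions. Unconstrained by default; with
#' `nonneg = TRUE` the fractions are projected to the nonnegative cone by
#' active-set elimination (NNLS).
#'
#' @param spectra Spectra tibble of pixels on the full grid (measured at
#'   `bands`), or an M x P numeric matrix of measurements.
#' @param bases An [extract_bases()] result.
#' @param bands Band set of measured bands, `length(bands) >= 3` for the
#'   unconstrained mode.
#' @param nonneg Constrain fractions to be nonnegative.
#' @return Tibble with columns `id`, `f_water`, `f_vegetation`, `f_soil`.
#' @export
updm_fractions <- function(spectra, bases, bands, nonneg = FALSE) {
  if (is.data.frame(spectra)) {
    sm <- as_spectra_matrix(spectra)
    check_bases_grid(bases, sm$wavelengths)
    Y <- sm$values[as.integer(bands), , drop = FALSE]
    ids <- sm$ids
  } else {
    Y <- as.matrix(spectra)
    ids <- colnames(Y) %||% paste0("s", seq_len(ncol(Y)))
  }
  f <- updm_fractions_mat(Y, bases, bands, nonneg = nonneg)
  tibble::tibble(id = ids, f_water = f[1, ], f_vegetation = f[2, ],
                 f_soil = f[3, ])
}

updm_fractions_mat <- function(Y, bases, bands, nonneg = FALSE) {
  m <- length(bands)
  if (!nonneg && m < 3) {
    stop("need at least 3 measured bands for unconstrained fractions",
         call. = FALSE)
  }
  Bm <- bases$bases[as.integer(bands), , drop = FALSE]
  g <- crossprod(Bm)
  if (rcond(g) < 1e-12) {
    stop("measured bands make the base spectra collinear ",
         "(singular 3 x 3 normal matrix)", call. = FALSE)
  }
  if (!nonneg) return(unname(solve(g, crossprod(Bm, Y))))
  apply(Y, 2, function(y) nnls3(Bm, y))
}

# tiny NNLS: enumerate the 8 sign patterns of a 3-variable problem and
# keep the feasible fit with the smallest residual
nnls3 <- function(B, y) {
  best <- NULL; best_res <- Inf
  for (subset in 0:7) {
    on <- which(bitwAnd(subset, c(1L, 2L, 4L)) > 0)
    f <- numeric(3)
    if (length(on) > 0) {
      Bs <- B[, on, drop = FALSE]
      fit <- qr.coef(qr(Bs), y)
      if (anyNA(fit) || any(fit < 0)) next
      f[on] <- fit
    }
    res <- sum((y - B %*% f)^2)
    if (res < best_res) { best_res <- res; best <- f }
  }
  best
}

#' Recompose full-resolution spectra from fractions
#'
#' @param fractions Tibble from [updm_fractions()].
#' @param bases An [extract_bases()] result.
#' @return Spectra tibble on the full grid, one spectrum per fraction row.
#' @export
reconstruct_updm <- function(fractions, bases) {
  f <- t(as.matrix(fractions[, c("f_water", "f_vegetation", "f_soil")]))
  vals <- bases$bases %*% f
  spectra_tbl(bases$wavelengths, vals, ids = fractions$id)
}

reconstruct_updm_mat <- function(Y, bases, bands, nonneg = FALSE) {
  bases$bases %*% updm_fractions_mat(Y, bases, bands, nonneg = nonneg)
}

check_bases_grid <- function(bases, wavelengths) {
  if (nrow(bases$bases) != length(wavelengths) ||
      max(abs(bases$wavelengths - wavelengths)) > 1e-9) {
    stop("bases are on a different wavelength grid", call. = FALSE)
  }
  invisible(TRUE)
}
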