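# K-SVD dictionary learning on reflectance spectra, and reconstruction of
# a full spectrum from a few measured bands via SL0 on the subsampled
# dictionary. This is the homogeneous-sensor path: every node measures the
# same band set and the unmeasured bands are supplied by the dictionary
# learned from hyperspectral training data.

#' Default sparsity target (10 percent rule)
#'
#' The sparsity target defaults to 10 percent of the number of
#' hyperspectral bands, floored at 1 and capped at the dictionary size
#' (more atoms than exist cannot be chosen).
#'
#' @param n_bands Number of hyperspectral bands N.
#' @param k Dictionary size.
#' @return Integer sparsity target.
#' @examples
#' default_sparsity_target(40, 300) # 4
#' default_sparsity_target(40, 2)   # capped at 2
#' @export
default_sparsity_target <- function(n_bands, k) {
  stopifnot(n_bands >= 1, k >= 1)
  as.integer(min(k, max(1, round(0.10 * n_bands))))
}

#' Train a spectral dictionary with K-SVD
#'
#' Alternates two steps: (1) sparse-code every training spectrum on the
#' current dictionary with OMP at sparsity target `t`; (2) for each atom,
#' form the residual matrix of the spectra using it with that atom's
#' contribution removed, and replace the atom and its coefficients by the
#' leading singular pair. Unused atoms are replaced by the currently
#' worst-represented training spectrum (normalised). A per-spectrum guard
#' keeps the previous iteration's code wherever fresh OMP coding would
#' increase that spectrum's residual, making the training objective
#' monotonically non-increasing.
#'
#' @param train A spectra tibble of hyperspectral training pixels.
#' @param k Dictionary size (number of atoms); reduced with a warning if
#'   the training set has fewer spectra.
#' @param t Sparsity target; default [default_sparsity_target()].
#' @param n_iter Maximum K-SVD iterations (default 20); iteration stops
#'   early when the relative training-error improvement drops below `tol`.
#' @param seed Integer seed for the initial atom selection.
#' @param tol Relative-improvement early-stop threshold.
#' @return A `ksvd_dictionary`: unit-norm atoms (N x k matrix), the grid,
#'   `k`, `t`, the training error trace and a training-set fingerprint.
#' @export
train_dictionary <- function(train, k, t = NULL, n_iter = 20, seed = 1,
                             tol = 1e-5) {
  sm <- as_spectra_matrix(train)
  X <- sm$values
  n <- nrow(X); p <- ncol(X)
  if (any(colSums(X^2) == 0)) {
    stop("training set contains all-zero spectra", call. = FALSE)
  }
  if (p < k) {
    warning("only ", p, " training spectra; reducing dictionary size from ",
            k, call. = FALSE)
    k <- p
  }
  if (is.null(t)) t <- default_sparsity_target(n, k)
  stopifnot(t >= 1, t <= k)
  D <- init_atoms(X, k, seed)
  gamma <- matrix(0, nrow = k, ncol = p)
  err_trace <- numeric(0)
  iters_run <- 0L
  if (n_iter > 0) {
    for (it in seq_len(n_iter)) {
      # sparse coding (guarded: never worse than the carried-over code)
      for (j in seq_len(p)) {
        code <- omp(D, X[, j], t)$coefficients
        old_res <- sum((X[, j] - D %*% gamma[, j])^2)
        new_res <- sum((X[, j] - D %*% code)^2)
        if (it == 1L || new_res <= old_res) gamma[, j] <- code
      }
      # atom updates
      R <- X - D %*% gamma
      for (kk in seq_len(k)) {
        using <- which(gamma[kk, ] != 0)
        if (length(using) == 0) {
          worst <- which.max(colSums(R^2))
          D[, kk] <- flip_sign(X[, worst] / sqrt(sum(X[, worst]^2)))
          next
        }
        E <- R[, using, drop = FALSE] +
          outer(D[, kk], gamma[kk, using])
        sv <- svd(E, nu = 1, nv = 1)
        atom <- drop(sv$u)
        sgn <- sign(atom[which.max(abs(atom))])
        D[, kk] <- atom * sgn
        gamma[kk, using] <- sv$d[1] * drop(sv$v) * sgn
        R[, using] <- E - outer(D[, kk], gamma[kk, using])
      }
      err <- sqrt(sum((X - D %*% gamma)^2))
      err_trace <- c(err_trace, err)
      iters_run <- it
      if (it > 1 &&
          (err_trace[it - 1] - err) <= tol * max(err_trace[it - 1],
                                                 .Machine$double.eps)) {
        break
      }
    }
  }
  structure(list(atoms = unname(D), wavelengths = sm$wavelengths,
                 k = as.integer(k), t = as.integer(t),
                 n_iter = iters_run, seed = seed,
                 error_trace = err_trace,
                 train_fingerprint = list(n_spectra = p, n_bands = n,
                                          sum = sum(X))),
            class = "ksvd_dictionary")
}

# Seeded farthest-point initialisation: the first atom is a training
# spectrum drawn by seed; each further atom is the spectrum least coherent
# (smallest maximum |cosine|) with the atoms chosen so far. Avoids the
# local minimum where two initial atoms span the same direction.
init_atoms <- function(X, k, seed) {
  Xn <- unname(sweep(X, 2, sqrt(colSums(X^2)), "/"))
  p <- ncol(Xn)
  chosen <- with_seed(seed, sample.int(p, 1))
  while (length(chosen) < k) {
    sims <- abs(crossprod(Xn[, chosen, drop = FALSE], Xn))
    dmin <- 1 - apply(sims, 2, max)
    dmin[chosen] <- -Inf
    chosen <- c(chosen, which.max(dmin))
  }
  normalize_atoms(Xn[, chosen, drop = FALSE])
}

normalize_atoms <- function(D) {
  nrm <- sqrt(colSums(D^2))
  apply(sweep(D, 2, nrm, "/"), 2, flip_sign)
}

# sign convention: largest-magnitude entry positive, so dictionaries are
# comparable across runs
flip_sign <- function(a) a * sign(a[which.max(abs(a))])

#' @export
print.ksvd_dictionary <- function(x, ...) {
  cat("K-SVD spectral dictionary\n")
  cat("  atoms:", x$k, " bands:", nrow(x$atoms),
      " sparsity target:", x$t, "\n")
  cat("  iterations:", x$n_iter, " final training error:",
      if (length(x$error_trace)) signif(utils::tail(x$error_trace, 1), 4)
      else NA, "\n")
  invisible(x)
}

#' Reconstruct spectra from band-subsampled measurements with a dictionary
#'
#' Measures each spectrum at the given band set, solves the sparse code on
#' the subsampled dictionary `Phi D` with SL0 and synthesises the full
#' spectrum `D alpha`. When the dictionary size equals the number of
#' measured bands, `Phi D` is square, SL0 degenerates to the plain L2
#' solution and reconstruction quality is known to suffer; a warning is
#' emitted.
#'
#' @param spectra Spectra tibble of reference pixels on the full grid (only
#'   the selected bands are used as measurements).
#' @param dictionary A [train_dictionary()] fit.
#' @param bands Band set of measured bands.
#' @param ... Passed to [sl0()].
#' @return Spectra tibble of reconstructions on the full grid, same ids.
#' @export
reconstruct_ksvd <- function(spectra, dictionary, bands, ...) {
  sm <- as_spectra_matrix(spectra)
  check_dict_grid(dictionary, sm$wavelengths)
  Y <- sm$values[as.integer(bands), , drop = FALSE]
  vals <- reconstruct_ksvd_mat(Y, dictionary, bands, ...)
  spectra_tbl(sm$wavelengths, vals, ids = sm$ids, class = sm$class,
              coords = sm$coords)
}

# matrix-level core: Y is M x P measured values
reconstruct_ksvd_mat <- function(Y, dictionary, bands, ...) {
  D <- dictionary$atoms
  if (length(bands) < 1) stop("need at least one measured band",
                              call. = FALSE)
  phi_d <- D[as.integer(bands), , drop = FALSE]
  if (ncol(D) == length(bands)) {
    warning("dictionary size equals the number of measured bands; SL0 ",
            "returns the plain L2 solution (no sparsification)",
            call. = FALSE)
  }
  alpha <- sl0(phi_d, Y, ...)
  D %*% alpha
}

check_dict_grid <- function(dictionary, wavelengths) {
  if (nrow(dictionary$atoms) != length(wavelengths) ||
      max(abs(dictionary$wavelengths - wavelengths)) > 1e-9) {
    stop("dictionary was trained on a different wavelength grid",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Serialize a dictionary to JSON / read it back
#'
#' @param dictionary A `ksvd_dictionary`.
#' @param path JSON path.
#' @return `path` (write) or the dictionary (read).
#' @export
write_dictionary <- function(dictionary, path) {
  obj <- unclass(dictionary)
  obj$atoms <- as.data.frame(obj$atoms)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  obj <- jsonlite::fromJSON(path)
  obj$atoms <- as.matrix(obj$atoms)
  dimnames(obj$atoms) <- NULL
  structure(obj, class = "ksvd_dictionary")
}

#' Export dictionary atoms as a spectral library
#'
#' @param dictionary A `ksvd_dictionary`.
#' @return Spectra tibble with one spectrum per atom (`atom1`, `atom2`,
#'   ...), convenient for plotting or [write_spectral_library()].
#' @export
atoms_as_spectra <- function(dictionary) {
  # atoms are unit-norm basis vectors, not reflectances: the reflectance
  # range warning does not apply
  suppressWarnings(
    spectra_tbl(dictionary$wavelengths, dictionary$atoms,
                ids = paste0("atom", seq_len(ncol(dictionary$atoms)))))
}
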