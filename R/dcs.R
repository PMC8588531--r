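# Distributed compressive sensing under the JSM-1 joint sparsity model:
# a group of sensor nodes with (heterogeneous) band sets is reconstructed
# jointly as one sparse common spectrum plus one sparse innovation per
# node, both sparse in the first-difference domain (spectra are smooth, so
# their derivative is concentrated at a few transitions). Group-median
# aggregation (GM) over several independent groupings discards the
# occasional bad group estimate.

#' First-difference sparsifying transform
#'
#' @param n Grid length N.
#' @return The (N-1) x N matrix with rows `(..., -1, +1, ...)`; it
#'   annihilates constants and has rank N-1.
#' @export
difference_matrix <- function(n) {
  stopifnot(n >= 2)
  D <- matrix(0, n - 1, n)
  D[cbind(seq_len(n - 1), seq_len(n - 1))] <- -1
  D[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- 1
  D
}

#' Synthesis matrix for the first-difference domain
#'
#' The difference transform kills constant offsets, so signals are
#' synthesised as `x = S theta` with `S = [1 | L]`: an explicit constant
#' column plus the lower-triangular cumulative-sum matrix. The non-constant
#' part of `theta` then equals the discrete first derivative of `x`.
#'
#' @param n Grid length N.
#' @return The N x N synthesis matrix.
#' @export
synthesis_matrix <- function(n) {
  stopifnot(n >= 2)
  L <- matrix(0, n, n - 1)
  for (j in seq_len(n - 1)) L[(j + 1):n, j] <- 1
  cbind(rep(1, n), L)
}

#' Stack the JSM-1 measurement system for one group
#'
#' Unknowns are `theta = [theta_common; theta_1; ...; theta_J]`, each of
#' length N in the synthesis domain; node j contributes rows
#' `Phi_j S (theta_common + theta_j) = y_j`.
#'
#' @param band_sets List of J band sets (1-based indices).
#' @param n_bands Grid length N.
#' @return List with the stacked `(sum M_j) x ((J+1) N)` matrix `A` and a
#'   row-block index per node.
#' @export
build_jsm1_system <- function(band_sets, n_bands) {
  J <- length(band_sets)
  stopifnot(J >= 1)
  S <- synthesis_matrix(n_bands)
  m_j <- lengths(band_sets)
  A <- matrix(0, sum(m_j), (J + 1) * n_bands)
  row0 <- c(0, cumsum(m_j))
  for (j in seq_len(J)) {
    ps <- S[as.integer(band_sets[[j]]), , drop = FALSE]
    rows <- (row0[j] + 1):row0[j + 1]
    A[rows, seq_len(n_bands)] <- ps
    A[rows, j * n_bands + seq_len(n_bands)] <- ps
  }
  list(A = A, row_blocks = lapply(seq_len(J), function(j) {
    (row0[j] + 1):row0[j + 1]
  }))
}

#' Jointly reconstruct one group of nodes under JSM-1
#'
#' Solves the stacked system with SL0 and synthesises the common and
#' innovation spectra. A rank-deficient stack (e.g. strongly overlapping
#' band sets) is handled by the pseudo-inverse with a warning.
#'
#' @param Y M x J matrix of measurements (column j = node j's measured
#'   bands), or a list of measurement vectors when band-set sizes differ.
#' @param band_sets List of J band sets.
#' @param n_bands Grid length N.
#' @param ... Passed to [sl0()].
#' @return List with `common` (length-N vector), `innovations` and
#'   `reconstructions` (N x J matrices; `reconstructions = common +
#'   innovation`).
#' @export
solve_jsm1 <- function(Y, band_sets, n_bands,
                       sigma_min = 1e-6, sigma_decrease = 0.8, mu = 2,
                       inner_iterations = 3L, sigma0 = NULL) {
  if (is.matrix(Y)) Y <- lapply(seq_len(ncol(Y)), function(j) Y[, j])
  J <- length(band_sets)
  stopifnot(length(Y) == J)
  m_j <- lengths(band_sets)
  stopifnot(all(lengths(Y) == m_j))
  y <- unlist(Y, use.names = FALSE)
  S <- synthesis_matrix(n_bands)
  tS <- t(S)
  # The stacked matrix is [B | blockdiag(B_j)] with B_j = S[bands_j, ],
  # B the row-stack of the B_j. It is never formed: matvecs go through S
  # once for all nodes, and the Gram matrix A A' is the stacked B B' with
  # doubled diagonal blocks.
  bidx <- unlist(lapply(band_sets, as.integer))
  node_of <- rep(seq_len(J), m_j)
  sel <- cbind(bidx, node_of)           # (band, node) per stacked row
  Bmat <- S[bidx, , drop = FALSE]       # (sum M) x N
  row0 <- c(0, cumsum(m_j))
  G <- tcrossprod(Bmat)
  for (j in seq_len(J)) {
    rows <- (row0[j] + 1):row0[j + 1]
    G[rows, rows] <- 2 * G[rows, rows]
  }
  # theta is carried as (common vector, N x J innovation matrix)
  a_mul <- function(com, innov) {
    S %*% (com + innov)                 # N x J; then pick measured rows
  }
  at_mul <- function(z) {               # z: stacked residual
    Zfull <- matrix(0, n_bands, J)
    Zfull[sel] <- z
    W <- tS %*% Zfull
    list(common = rowSums(W), innov = W)
  }
  dense_fallback <- function() {
    sys <- build_jsm1_system(band_sets, n_bands)
    warning("rank-deficient JSM-1 stack; using pseudo-inverse",
            call. = FALSE)
    sl0(sys$A, y, A_pinv = pinv(sys$A), sigma_min = sigma_min,
        sigma_decrease = sigma_decrease, mu = mu,
        inner_iterations = inner_iterations, sigma0 = sigma0)
  }
  ch <- tryCatch({
    chv <- chol(G)
    if (min(diag(chv)) < 1e-8 * max(diag(chv))) NULL else chv
  }, error = function(e) NULL)
  if (is.null(ch)) {
    theta <- dense_fallback()
    com <- theta[seq_len(n_bands)]
    innov_t <- matrix(theta[-seq_len(n_bands)], n_bands, J)
  } else {
    ginv_mul <- function(r) {
      backsolve(ch, backsolve(ch, r, transpose = TRUE))
    }
    project <- function(com, innov) {
      r <- a_mul(com, innov)[sel] - y
      corr <- at_mul(ginv_mul(r))
      list(common = com - corr$common, innov = innov - corr$innov)
    }
    init <- at_mul(ginv_mul(y))         # minimum-L2-norm solution
    com <- init$common; innov <- init$innov
    sigma <- sigma0 %||% (2 * max(abs(com), abs(innov)))
    while (sigma > sigma_min) {
      for (i in seq_len(inner_iterations)) {
        w <- exp(-(cbind(com, innov))^2 / (2 * sigma^2))
        com <- com - mu * com * w[, 1]
        innov <- innov - mu * innov * w[, -1, drop = FALSE]
        st <- project(com, innov)
        com <- st$common; innov <- st$innov
      }
      sigma <- sigma * sigma_decrease
    }
    innov_t <- innov
  }
  common <- drop(S %*% com)
  innovations <- S %*% innov_t
  list(common = common, innovations = innovations,
       reconstructions = innovations + common)
}

#' Randomly partition pixels into groups
#'
#' @param ids Character vector of pixel ids (or a spectra tibble).
#' @param group_size Maximum group size (default 64, the joint-solve
#'   batch the stacked system stays tractable at); the last group may be
#'   smaller.
#' @param seed Integer seed for the uniform shuffle.
#' @return List of id vectors.
#' @export
group_pixels <- function(ids, group_size = 64, seed = 1) {
  if (is.data.frame(ids)) ids <- unique(ids$id)
  stopifnot(group_size >= 1)
  if (length(ids) == 0) stop("no pixels to group", call. = FALSE)
  perm <- with_seed(seed, sample(ids))
  split(perm, ceiling(seq_along(perm) / group_size))
}

# matrix-level DCS pass: reconstruct every pixel of `values` (N x P, with
# column names = ids) given per-pixel band sets and a grouping
dcs_reconstruct_mat <- function(values, node_bands, groups, ...) {
  n <- nrow(values)
  out <- matrix(NA_real_, n, ncol(values),
                dimnames = dimnames(values))
  ids <- colnames(values)
  for (g in groups) {
    cols <- match(g, ids)
    bs <- node_bands[cols]
    Y <- lapply(seq_along(cols), function(j) {
      values[as.integer(bs[[j]]), cols[j]]
    })
    sol <- solve_jsm1(Y, bs, n, ...)
    out[, cols] <- sol$reconstructions
  }
  out
}

#' Reconstruct a scene with grouped JSM-1
#'
#' Each pixel is measured at its node's band set; pixels are solved
#' jointly in groups.
#'
#' @param spectra Spectra tibble of reference pixels on the full grid.
#' @param node_bands List of band sets, one per pixel (in `unique(id)`
#'   order), e.g. from [assign_band_sets()].
#' @param groups Grouping from [group_pixels()] (default: one grouping of
#'   everything with seed 1).
#' @param ... Passed to [sl0()].
#' @return Spectra tibble of reconstructions.
#' @export
reconstruct_dcs <- function(spectra, node_bands, groups = NULL, ...) {
  sm <- as_spectra_matrix(spectra)
  stopifnot(length(node_bands) == length(sm$ids))
  if (is.null(groups)) groups <- group_pixels(sm$ids, seed = 1)
  vals <- dcs_reconstruct_mat(
    `colnames<-`(sm$values, sm$ids), node_bands, groups, ...)
  spectra_tbl(sm$wavelengths, vals, ids = sm$ids, class = sm$class,
              coords = sm$coords)
}

#' Group-median aggregation of repeated estimates
#'
#' Given L reconstructions of the same pixels (from L independent
#' groupings), returns the per-band median spectrum for every pixel; with
#' an even L the mean of the two central values is taken. The median
#' discards the relatively few bad group estimates.
#'
#' @param estimates List of L spectra tibbles on one grid with identical
#'   ids.
#' @return Spectra tibble of median spectra.
#' @export
dcs_gm <- function(estimates) {
  stopifnot(length(estimates) >= 1)
  mats <- lapply(estimates, as_spectra_matrix)
  ref <- mats[[1]]
  for (m in mats[-1]) {
    if (!identical(dim(m$values), dim(ref$values)) ||
        !identical(m$ids, ref$ids) ||
        max(abs(m$wavelengths - ref$wavelengths)) > 1e-9) {
      stop("estimates must share grid and pixel ids", call. = FALSE)
    }
  }
  arr <- simplify2array(lapply(mats, function(m) m$values))
  med <- apply(arr, c(1, 2), stats::median)
  spectra_tbl(ref$wavelengths, med, ids = ref$ids, class = ref$class,
              coords = ref$coords)
}
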