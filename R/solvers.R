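# Sparse recovery engines. OMP does the greedy sparse coding inside K-SVD
# training; SL0 (smoothed-L0 gradient descent with equality projection)
# does the reconstruction from band-subsampled measurements. An exhaustive
# L0 search over small supports serves as an independent oracle in tests.

#' Orthogonal matching pursuit
#'
#' Greedily selects up to `t_max` columns of `A` by maximum absolute
#' correlation with the current residual, refitting the coefficients by
#' least squares on the selected support after every pick. Stops early
#' when the residual norm falls below `tol`.
#'
#' @param A Numeric M x K matrix with nonzero columns.
#' @param y Numeric length-M vector.
#' @param t_max Sparsity target, `1 <= t_max <= min(M, K)`.
#' @param tol Residual norm for early stopping (default 1e-12).
#' @return A `sparse_code`: list with `coefficients` (length K, exact zeros
#'   off support), `support` (selected column indices, in selection order)
#'   and `residual_norms` (one per step; non-increasing).
#' @export
omp <- function(A, y, t_max, tol = 1e-12) {
  A <- as.matrix(A)
  m <- nrow(A); k <- ncol(A)
  stopifnot(length(y) == m)
  col_norms <- sqrt(colSums(A^2))
  if (any(col_norms == 0)) stop("A has a zero column", call. = FALSE)
  if (t_max < 1 || t_max > min(m, k)) {
    stop("sparsity target must satisfy 1 <= t_max <= min(M, K)",
         call. = FALSE)
  }
  support <- integer(0)
  coef_s <- numeric(0)
  r <- y
  res_norms <- numeric(0)
  for (step in seq_len(t_max)) {
    corr <- abs(crossprod(A, r)) / col_norms
    corr[support] <- -Inf
    j <- which.max(corr)
    support <- c(support, j)
    As <- A[, support, drop = FALSE]
    coef_s <- tryCatch(
      qr.coef(qr(As), y),
      error = function(e) NULL
    )
    if (is.null(coef_s) || anyNA(coef_s)) {
      warning("singular support system in OMP; ridge fallback", call. = FALSE)
      g <- crossprod(As) + diag(1e-10, length(support))
      coef_s <- solve(g, crossprod(As, y))
    }
    r <- y - As %*% coef_s
    res_norms <- c(res_norms, sqrt(sum(r^2)))
    if (res_norms[step] < tol) break
  }
  coefficients <- numeric(k)
  coefficients[support] <- coef_s
  structure(list(coefficients = coefficients, support = support,
                 residual_norms = res_norms),
            class = "sparse_code")
}

# Moore-Penrose pseudo-inverse via SVD (tolerance scaled to largest
# singular value, as in MASS::ginv).
pinv <- function(A, tol = .Machine$double.eps) {
  s <- svd(A)
  keep <- s$d > max(dim(A)) * tol * s$d[1]
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Smoothed-L0 sparse recovery
#'
#' Noiseless equality-constrained SL0: starting from the minimum-L2-norm
#' solution `A+ y`, for a geometrically decreasing sequence of smoothing
#' widths sigma it takes `inner_iterations` gradient steps on the smoothed
#' sparsity measure `sum(exp(-x^2 / 2 sigma^2))` and projects back onto
#' `{x : A x = y}` after each step.
#'
#' When `A` is square and invertible the initial L2 solution is already the
#' unique consistent point, the projection undoes every gradient step, and
#' the output equals `solve(A, y)` -- no sparsification occurs. This is the
#' documented failure mode of dictionary reconstruction when the dictionary
#' size equals the number of measured bands.
#'
#' @param A Numeric M x K matrix.
#' @param y Numeric length-M vector (or M x P matrix to solve P systems
#'   sharing `A` in one pass).
#' @param sigma_min Final smoothing width (> 0).
#' @param sigma_decrease Geometric decay factor in (0, 1).
#' @param mu Gradient step size (> 0).
#' @param inner_iterations Gradient steps per sigma level.
#' @param sigma0 Initial sigma; default `2 * max(abs(A+ y))` per system.
#' @param A_pinv Optional precomputed pseudo-inverse of `A`.
#' @return Length-K vector (or K x P matrix) satisfying `A x = y` to
#'   numerical precision.
#' @export
sl0 <- function(A, y, sigma_min = 1e-6, sigma_decrease = 0.8, mu = 2,
                inner_iterations = 3L, sigma0 = NULL, A_pinv = NULL) {
  stopifnot(sigma_min > 0, sigma_decrease > 0, sigma_decrease < 1,
            mu > 0, inner_iterations >= 1)
  A <- as.matrix(A)
  vec_in <- is.null(dim(y))
  Y <- if (vec_in) matrix(y, ncol = 1) else as.matrix(y)
  if (nrow(Y) != nrow(A)) stop("dim mismatch between A and y", call. = FALSE)
  if (is.null(A_pinv)) A_pinv <- pinv(A)
  X <- A_pinv %*% Y
  sigma <- if (is.null(sigma0)) {
    2 * apply(abs(X), 2, max)
  } else rep_len(sigma0, ncol(X))
  sigma[sigma <= 0] <- sigma_min  # all-zero solutions: nothing to shrink
  active <- sigma > sigma_min
  while (any(active)) {
    Xa <- X[, active, drop = FALSE]
    sa <- sigma[active]
    for (i in seq_len(inner_iterations)) {
      delta <- Xa * exp(sweep(Xa^2, 2, -2 * sa^2, "/"))
      Xa <- Xa - mu * delta
      Xa <- Xa - A_pinv %*% (A %*% Xa - Y[, active, drop = FALSE])
    }
    X[, active] <- Xa
    sigma[active] <- sigma[active] * sigma_decrease
    active <- sigma > sigma_min
  }
  if (vec_in) drop(X) else X
}

#' Support of a sparse coefficient vector
#'
#' @param x Numeric vector.
#' @param rel_tol Entries below `rel_tol * max(abs(x))` count as zero.
#' @return Integer indices of the nonzero entries.
#' @export
sparse_support <- function(x, rel_tol = 1e-6) {
  mx <- max(abs(x))
  if (mx == 0) return(integer(0))
  which(abs(x) > rel_tol * mx)
}

#' Exhaustive sparsest-solution oracle
#'
#' Searches supports by increasing size and returns the first exactly
#' consistent least-squares solution. Intended as an independent reference
#' on small instances only.
#'
#' @param A Numeric M x K matrix, `K <= 20`.
#' @param y Length-M vector.
#' @param max_support Largest support size to try (<= 3 by default budget).
#' @param tol Residual norm defining exact consistency.
#' @param budget Maximum number of candidate supports examined.
#' @return List with `coefficients` and `support`, or `NULL` if no
#'   consistent solution exists within `max_support`.
#' @export
l0_oracle <- function(A, y, max_support = 3, tol = 1e-9, budget = 50000) {
  A <- as.matrix(A)
  k <- ncol(A)
  n_cand <- sum(choose(k, 0:max_support))
  if (n_cand > budget) {
    stop("combinatorial budget exceeded (", n_cand, " supports)",
         call. = FALSE)
  }
  if (sqrt(sum(y^2)) < tol) {
    return(list(coefficients = numeric(k), support = integer(0)))
  }
  for (s in seq_len(max_support)) {
    for (supp in utils::combn(k, s, simplify = FALSE)) {
      As <- A[, supp, drop = FALSE]
      fit <- qr.coef(qr(As), y)
      if (anyNA(fit)) next
      if (sqrt(sum((y - As %*% fit)^2)) < tol) {
        coefficients <- numeric(k)
        coefficients[supp] <- fit
        return(list(coefficients = coefficients, support = supp))
      }
    }
  }
  NULL
}
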