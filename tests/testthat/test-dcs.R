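test_that("difference transform annihilates constants and has rank N-1", {
  D <- difference_matrix(8)
  expect_equal(drop(D %*% rep(3, 8)), rep(0, 7))
  expect_equal(qr(D)$rank, 7)
  S <- synthesis_matrix(8)
  # S inverts the (constant, derivative) parametrisation
  x <- cumsum(rnorm(8))
  theta <- c(x[1], diff(x))
  expect_equal(drop(S %*% theta), x)
  expect_equal(drop(D %*% (S %*% theta)), theta[-1])
})

test_that("stacked JSM-1 system has the documented shape", {
  sets <- assign_band_sets(64, 40, 8, seed = 1)
  sys <- build_jsm1_system(sets, 40)
  expect_identical(dim(sys$A), c(512L, 2600L))
  # J = 1 reduces to a single-node system with doubled unknowns
  one <- build_jsm1_system(sets[1], 40)
  expect_identical(dim(one$A), c(8L, 80L))
})

test_that("a constant spectrum needs only the common constant coefficient", {
  sets <- assign_band_sets(3, 10, 4, seed = 2)
  sys <- build_jsm1_system(sets, 10)
  theta <- numeric(4 * 10)
  theta[1] <- 0.42            # common constant coefficient
  y <- drop(sys$A %*% theta)
  expect_equal(y, rep(0.42, 12))
})

test_that("identical piecewise-constant nodes are recovered exactly", {
  # small instance cross-checked against the exhaustive oracle
  n <- 8
  x <- c(rep(0.3, 4), rep(0.7, 4))   # two plateaus, one step
  sets <- list(hsrecon:::band_set(c(1, 3, 5), n),
               hsrecon:::band_set(c(2, 6, 8), n),
               hsrecon:::band_set(c(4, 7, 8), n))
  Y <- lapply(sets, function(b) x[as.integer(b)])
  sol <- solve_jsm1(Y, sets, n)
  for (j in 1:3) expect_lt(rmse(sol$reconstructions[, j], x), 1e-6)
  # oracle on the common-only reduced system: common part alone explains y
  S <- synthesis_matrix(n)
  A_common <- do.call(rbind, lapply(sets, function(b) {
    S[as.integer(b), , drop = FALSE]
  }))
  oracle <- l0_oracle(A_common, unlist(Y), max_support = 2)
  expect_equal(drop(S %*% oracle$coefficients), x, tolerance = 1e-9)
})

test_that("64 heterogeneous 4-band nodes reconstruct a shared signal", {
  n <- 40
  x <- c(rep(0.2, 15), rep(0.6, 25))
  sets <- assign_band_sets(64, n, 4, seed = 5)
  expect_setequal(sort(unique(unlist(lapply(sets, as.integer)))), 1:n)
  Y <- lapply(sets, function(b) x[as.integer(b)])
  sol <- solve_jsm1(Y, sets, n)
  err <- apply(sol$reconstructions, 2, function(r) rmse(r, x))
  expect_lt(max(err), 1e-6)
})

test_that("zero measurements give the zero solution", {
  sets <- assign_band_sets(4, 12, 3, seed = 6)
  Y <- lapply(sets, function(b) rep(0, 3))
  sol <- solve_jsm1(Y, sets, 12)
  expect_equal(sol$reconstructions, matrix(0, 12, 4))
  expect_equal(sol$common, rep(0, 12))
})

test_that("an innovation is carried by the deviating node only", {
  n <- 16
  base <- c(rep(0.3, 8), rep(0.5, 8))
  dev <- base + c(rep(0, 12), rep(0.2, 4))  # one extra step
  # covering sets; the deviating node measures both sides of its step so
  # the innovation position is identifiable
  sets <- lapply(list(c(1, 4, 7, 10, 13, 16), c(2, 5, 8, 11, 14, 15),
                      c(3, 6, 9, 12, 15, 16), c(1, 5, 8, 12, 13, 14),
                      c(2, 6, 9, 11, 14, 16), c(1, 6, 9, 12, 13, 16)),
                 hsrecon:::band_set, n_bands = n)
  X <- cbind(matrix(base, n, 5), dev)
  Y <- lapply(1:6, function(j) X[as.integer(sets[[j]]), j])
  sol <- solve_jsm1(Y, sets, n)
  for (j in 1:6) expect_lt(rmse(sol$reconstructions[, j], X[, j]), 1e-6)
  innov_size <- apply(sol$innovations, 2, function(z) max(abs(z)))
  expect_lt(max(innov_size[1:5]), 1e-6)
  expect_gt(innov_size[6], 0.1)
})

test_that("solutions satisfy measurement consistency", {
  set.seed(9)
  n <- 20
  sets <- assign_band_sets(8, n, 5, seed = 10)
  X <- sapply(1:8, function(j) {
    pmin(pmax(cumsum(rnorm(n, 0, 0.05)) + 0.4, 0), 1)
  })
  Y <- lapply(1:8, function(j) X[as.integer(sets[[j]]), j])
  sol <- solve_jsm1(Y, sets, n)
  worst <- max(vapply(1:8, function(j) {
    max(abs(sol$reconstructions[as.integer(sets[[j]]), j] - Y[[j]]))
  }, numeric(1)))
  expect_lt(worst, 1e-6)
})

test_that("homogeneous band sets leave unmeasured bands undetermined", {
  n <- 12
  x <- c(rep(0.3, 6), rep(0.8, 6))
  errs <- vapply(c(4, 16, 64), function(J) {
    sets <- assign_band_sets(J, n, 3, seed = 3, homogeneous = TRUE)
    Y <- lapply(sets, function(b) x[as.integer(b)])
    sol <- suppressWarnings(solve_jsm1(Y, sets, n))
    unmeasured <- setdiff(1:n, as.integer(sets[[1]]))
    mean(abs(sol$reconstructions[unmeasured, 1] - x[unmeasured]))
  }, numeric(1))
  # adding nodes brings no new bands: the error does not converge to zero
  expect_gt(min(errs), 0.01)
})

test_that("pixel grouping partitions ids reproducibly", {
  ids <- sprintf("p%03d", 1:128)
  g <- group_pixels(ids, 64, seed = 4)
  expect_length(g, 2)
  expect_true(all(lengths(g) == 64))
  expect_setequal(unlist(g), ids)
  g2 <- group_pixels(ids[1:100], 64, seed = 4)
  expect_equal(unname(lengths(g2)), c(64L, 36L))
  expect_identical(group_pixels(ids, 64, seed = 4), g)
  expect_error(group_pixels(character(0)), "no pixels")
})

test_that("group-median aggregation is a per-band median", {
  wl <- c(500, 600)
  mk <- function(v) spectra_tbl(wl, matrix(v, 2, 1), ids = "p1")
  ests <- lapply(list(c(0.2, 0.2), c(0.21, 0.9), c(0.19, 0.2),
                      c(0.9, 0.21), c(0.2, 0.19)), mk)
  out <- dcs_gm(ests)
  expect_equal(out$reflectance, c(0.2, 0.2))
  # L = 1 is the identity
  expect_equal(dcs_gm(ests[2])$reflectance, ests[[2]]$reflectance)
  # permutation invariance
  expect_equal(dcs_gm(rev(ests)), out)
  # even L averages the two central values
  expect_equal(dcs_gm(ests[1:2])$reflectance, c(0.205, 0.55))
  expect_error(dcs_gm(list(mk(c(0.1, 0.2)),
                           spectra_tbl(500, matrix(0.1), ids = "p1"))),
               "share grid")
})

test_that("the median discards a corrupted grouping", {
  scene <- small_scene(seed = 51, rows = 8, cols = 8)
  sm <- hsrecon:::as_spectra_matrix(scene)
  vals <- `colnames<-`(sm$values, sm$ids)
  nb <- assign_band_sets(64, 40, 6, seed = 2)
  ests <- lapply(1:5, function(g) {
    est <- hsrecon:::dcs_reconstruct_mat(
      vals, nb, group_pixels(sm$ids, 32, seed = g))
    suppressWarnings(spectra_tbl(sm$wavelengths, est, ids = sm$ids))
  })
  # corrupt one grouping's estimates badly
  bad <- ests[[3]]
  bad$reflectance <- bad$reflectance + 0.5
  ests[[3]] <- bad
  ref <- spectra_tbl(sm$wavelengths, sm$values, ids = sm$ids)
  med_rmse <- function(e) stats::median(spectra_rmse(e, ref)$rmse)
  gm <- suppressWarnings(dcs_gm(ests))  # corrupted values exceed 1.5
  singles <- vapply(ests, med_rmse, numeric(1))
  # the median discards the corrupted grouping entirely ...
  expect_lt(med_rmse(gm), singles[3] / 5)
  # ... and stays within the range of the uncorrupted groupings
  expect_lte(med_rmse(gm), max(singles[-3]))
})
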