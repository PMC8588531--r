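test_that("the 10 percent rule floors at 1 and caps at K", {
  expect_identical(default_sparsity_target(40, 300), 4L)
  expect_identical(default_sparsity_target(40, 2), 2L)
  expect_identical(default_sparsity_target(5, 10), 1L)
})

test_that("rank-1 training data yields the normalised spectrum as atom", {
  grid <- tiny_grid
  s <- c(0.2, 0.6, 0.3)
  train <- spectra_tbl(grid, matrix(rep(s, 5), nrow = 3),
                       ids = paste0("p", 1:5))
  d <- train_dictionary(train, k = 1, t = 1, seed = 2)
  expect_equal(drop(d$atoms), s / sqrt(sum(s^2)), tolerance = 1e-12)
  expect_lt(utils::tail(d$error_trace, 1), 1e-12)
})

test_that("zero iterations return the seeded initialisation unchanged", {
  train <- tiny_spectra()
  d0 <- train_dictionary(train, k = 2, t = 1, n_iter = 0, seed = 5)
  sm <- hsrecon:::as_spectra_matrix(train)
  init <- hsrecon:::init_atoms(sm$values, 2, seed = 5)
  expect_equal(d0$atoms, init, ignore_attr = TRUE)
  expect_identical(d0$n_iter, 0L)
})

test_that("K is reduced with a warning when training spectra are scarce", {
  expect_warning(d <- train_dictionary(tiny_spectra(), k = 5, t = 1,
                                       n_iter = 1, seed = 1),
                 "reducing dictionary size")
  expect_identical(d$k, 2L)
})

test_that("all-zero training spectra are rejected", {
  bad <- spectra_tbl(tiny_grid, cbind(a = c(0.1, 0.2, 0.3), b = c(0, 0, 0)))
  expect_error(train_dictionary(bad, k = 1, t = 1), "all-zero")
})

test_that("K-SVD recovers a planted orthonormal dictionary", {
  set.seed(31)
  n <- 12
  D0 <- qr.Q(qr(matrix(rnorm(n * 4), n, 4)))
  codes <- sample(4, 200, replace = TRUE)
  amps <- runif(200, 0.5, 1.5)
  X <- sapply(seq_len(200), function(i) amps[i] * D0[, codes[i]])
  train <- suppressWarnings(
    spectra_tbl(seq(400, 950, by = 50), X, ids = paste0("p", 1:200)))
  d <- train_dictionary(train, k = 4, t = 1, n_iter = 20, seed = 8)
  corr <- abs(crossprod(D0, d$atoms))   # 4 x 4 |cosine| matrix
  matched <- apply(corr, 1, max)
  expect_true(all(matched > 0.99))
})

test_that("training error is monotone and atoms stay unit norm", {
  scene <- small_scene(seed = 19)
  train <- dplyr::filter(scene, .data$id %in% unique(.data$id)[1:60])
  d <- train_dictionary(train, k = 6, t = 2, n_iter = 12, seed = 3)
  expect_true(all(diff(d$error_trace) <= 1e-10))
  expect_equal(colSums(d$atoms^2), rep(1, 6), tolerance = 1e-12)
})

test_that("training is bitwise reproducible", {
  scene <- small_scene(seed = 23)
  d1 <- train_dictionary(scene, k = 5, t = 2, n_iter = 5, seed = 7)
  d2 <- train_dictionary(scene, k = 5, t = 2, n_iter = 5, seed = 7)
  expect_identical(d1, d2)
})

test_that("full sampling of an in-dictionary sparse spectrum is exact", {
  scene <- small_scene(seed = 29)
  d <- train_dictionary(scene, k = 6, t = 2, n_iter = 8, seed = 2)
  alpha <- numeric(6); alpha[c(2, 5)] <- c(0.8, 0.3)
  x <- drop(d$atoms %*% alpha)
  truth <- suppressWarnings(spectra_tbl(d$wavelengths, x, ids = "px"))
  full <- hsrecon:::band_set(1:40, 40)
  rec <- suppressWarnings(reconstruct_ksvd(truth, d, full))
  expect_lt(rmse(rec$reflectance, truth$reflectance), 1e-8)
})

test_that("a zero spectrum reconstructs to zero", {
  scene <- small_scene(seed = 29)
  d <- train_dictionary(scene, k = 6, t = 2, n_iter = 4, seed = 2)
  y <- matrix(0, 8, 1)
  bands <- random_band_set(40, 8, seed = 1)
  out <- hsrecon:::reconstruct_ksvd_mat(y, d, bands)
  expect_equal(drop(out), rep(0, 40))
})

test_that("a single atom measured at random bands is recovered", {
  scene <- small_scene(seed = 37)
  d <- train_dictionary(scene, k = 6, t = 2, n_iter = 8, seed = 4)
  bands <- random_band_set(40, 8, seed = 3)
  j <- 3L
  y <- d$atoms[as.integer(bands), j, drop = FALSE]
  out <- hsrecon:::reconstruct_ksvd_mat(y, d, bands)
  expect_lt(rmse(drop(out), d$atoms[, j]), 1e-4)
  # agrees with the exhaustive oracle on the subsampled system
  oracle <- l0_oracle(d$atoms[as.integer(bands), ], drop(y),
                      max_support = 1)
  expect_identical(oracle$support, j)
})

test_that("the square-dictionary case warns about the SL0 pathology", {
  scene <- small_scene(seed = 41)
  d <- train_dictionary(scene, k = 8, t = 2, n_iter = 2, seed = 4)
  bands <- random_band_set(40, 8, seed = 2)
  expect_warning(
    hsrecon:::reconstruct_ksvd_mat(matrix(0.1, 8, 1), d, bands),
    "equals the number of measured bands")
})

test_that("learned atoms are dominated by the red edge", {
  cfg <- scene_config(rows = 12, cols = 12, patch = 4,
                      class_props = c(vegetation = 1), seed = 43)
  train <- make_scene(cfg)
  grid <- default_grid()
  mid <- (grid[-1] + grid[-length(grid)]) / 2
  for (k in c(4, 8)) {
    d <- train_dictionary(train, k = k, n_iter = 10, seed = 5)
    peaks <- apply(d$atoms, 2, function(a) mid[which.max(abs(diff(a)))])
    expect_true(any(peaks >= 650 & peaks <= 750))
  }
})

test_that("dictionaries serialize to JSON and back", {
  d <- train_dictionary(tiny_spectra(), k = 2, t = 1, n_iter = 2, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_dictionary(d, path)
  back <- read_dictionary(path)
  expect_equal(back$atoms, d$atoms, tolerance = 1e-12)
  expect_equal(back$k, d$k)
  expect_equal(back$wavelengths, d$wavelengths)
  expect_equal(nrow(atoms_as_spectra(d)) , 3 * 2)
})
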