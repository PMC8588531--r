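test_that("rmse matches closed forms", {
  expect_equal(rmse(c(0.1, 0.2), c(0.1, 0.2)), 0)
  x <- runif(10)
  expect_equal(rmse(x + 0.05, x), 0.05)
  expect_equal(rmse(c(0.03, 0.04, 0), c(0, 0, 0)), sqrt(0.0025 / 3))
  expect_equal(rmse(c(0.03, 0.04, 0), c(0, 0, 0)), 0.028868, tolerance = 1e-4)
  expect_error(rmse(1:3, 1:4), "length")
})

test_that("per-pixel rmse requires matching grids and ids", {
  a <- tiny_spectra()
  expect_equal(spectra_rmse(a, a)$rmse, c(0, 0))
  b <- dplyr::mutate(a, wavelength = .data$wavelength + 5)
  expect_error(spectra_rmse(a, b), "share grid")
  expect_error(spectra_rmse(a, dplyr::filter(a, .data$id == "a")), "share")
})

test_that("an exact method yields an all-zero report", {
  # UPDM on spectra inside the span of its own bases is exact
  em <- endmembers_tbl()
  bases <- extract_bases(dplyr::mutate(em, id = .data$class))
  set.seed(3)
  mixes <- bases$bases %*% matrix(runif(30), 3, 10)
  eval_set <- suppressWarnings(
    spectra_tbl(default_grid(), mixes, ids = paste0("p", 1:10)))
  rep <- evaluate_method(eval_set, bases, m = 6, replications = 3, seed = 5)
  expect_lt(rep$median_of_medians, 1e-8)
  expect_true(all(rep$per_pixel$rmse < 1e-8))
  expect_equal(rep$median_of_medians,
               stats::median(rep$per_replication_medians))
})

test_that("reports are deterministic in the master seed", {
  scene <- small_scene(seed = 71)
  d <- train_dictionary(scene, k = 4, t = 2, n_iter = 6, seed = 2)
  r1 <- evaluate_method(scene, d, m = 6, replications = 3, seed = 9)
  r2 <- evaluate_method(scene, d, m = 6, replications = 3, seed = 9)
  expect_identical(r1, r2)
  expect_error(evaluate_method(scene, d, m = 6, replications = 0), ">= 1")
})

test_that("single-replication median-of-medians is that median", {
  scene <- small_scene(seed = 73)
  d <- train_dictionary(scene, k = 4, t = 2, n_iter = 6, seed = 2)
  r <- evaluate_method(scene, d, m = 6, replications = 1, seed = 4)
  expect_equal(r$median_of_medians, r$per_replication_medians[1])
  expect_length(r$per_replication_medians, 1)
})

test_that("band-set cycling drives BBS-style evaluation", {
  scene <- small_scene(seed = 79)
  d <- train_dictionary(scene, k = 4, t = 2, n_iter = 6, seed = 2)
  sets <- lapply(1:2, function(s) random_band_set(40, 6, seed = s))
  r <- evaluate_method(scene, d, band_sets = sets, replications = 4)
  expect_identical(r$config$band_sets[[1]], r$config$band_sets[[3]])
  expect_equal(r$per_pixel$rmse[r$per_pixel$replication == 1],
               r$per_pixel$rmse[r$per_pixel$replication == 3])
})

test_that("rmse maps localise errors", {
  scene <- small_scene(seed = 81, rows = 4, cols = 4)
  m0 <- rmse_map(scene, scene)
  expect_true(all(m0$rmse == 0))
  expect_setequal(names(m0)[1:3], c("row", "col", "rmse"))
  corrupt <- scene
  pick <- unique(scene$id)[5]
  corrupt$reflectance[corrupt$id == pick] <-
    corrupt$reflectance[corrupt$id == pick] + 0.2
  m1 <- rmse_map(corrupt, scene)
  expect_equal(sum(m1$rmse > 0), 1)
  expect_equal(m1$rmse[m1$rmse > 0], 0.2)
  no_coords <- dplyr::select(scene, -dplyr::all_of(c("row", "col")))
  expect_error(rmse_map(no_coords, no_coords), "coordinates")
})

test_that("anomaly pixels carry higher error under a vegetation dictionary", {
  cfg_train <- scene_config(rows = 10, cols = 10, patch = 4,
                            class_props = c(vegetation = 1), seed = 83)
  train <- make_scene(cfg_train)
  d <- train_dictionary(train, k = 4, n_iter = 10, seed = 2)
  cfg_eval <- scene_config(rows = 10, cols = 10, patch = 10,
                           class_props = c(vegetation = 1),
                           anomaly_fraction = 0.2, seed = 89)
  eval_scene <- make_scene(cfg_eval)
  bands <- random_band_set(40, 8, seed = 11)
  rec <- suppressWarnings(reconstruct_ksvd(eval_scene, d, bands))
  per <- spectra_rmse(rec, eval_scene)
  expect_gt(mean(per$rmse[per$class == "builtup"]),
            mean(per$rmse[per$class == "vegetation"]))
})

test_that("evaluate_dcs crosses band assignments with groupings", {
  scene <- small_scene(seed = 91, rows = 6, cols = 6)
  both <- evaluate_dcs(scene, m = 6, band_reps = 2, groupings = 2,
                       group_size = 18, seed = 5)
  expect_s3_class(both$dcs, "eval_report")
  expect_length(both$dcs$per_replication_medians, 4)     # 2 x 2
  expect_length(both$dcs_gm$per_replication_medians, 2)  # one per band rep
  expect_identical(both$dcs$method, "dcs")
  expect_identical(both$dcs_gm$method, "dcs-gm")
  both2 <- evaluate_dcs(scene, m = 6, band_reps = 2, groupings = 2,
                        group_size = 18, seed = 5)
  expect_identical(both2$dcs$median_of_medians,
                   both$dcs$median_of_medians)
})

test_that("illustrative spectra pick lowest, median and highest RMSE", {
  scene <- small_scene(seed = 93, rows = 4, cols = 4)
  est <- scene
  ids <- unique(scene$id)
  offs <- seq(0, 0.15, length.out = length(ids))
  for (i in seq_along(ids)) {
    est$reflectance[est$id == ids[i]] <-
      est$reflectance[est$id == ids[i]] + offs[i]
  }
  ill <- illustrative_spectra(est, scene)
  expect_setequal(unique(ill$role), c("lowest", "median", "highest"))
  expect_identical(unique(ill$id[ill$role == "lowest"]), ids[1])
  expect_identical(unique(ill$id[ill$role == "highest"]),
                   ids[length(ids)])
  expect_equal(nrow(ill), 3 * 2 * 40)
})
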