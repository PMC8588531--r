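# End-to-end seeded experiments: generate scene splits, train the
# artifacts, select bands, evaluate every requested method x band-count
# (x dictionary-size) combination, and report median-of-medians RMSEs.
# One master seed fans out deterministically to scene, training,
# band-selection and evaluation sub-seeds, so a rerun with the same
# configuration reproduces every report bitwise.

#' Experiment configuration
#'
#' @param scene A [scene_config()] describing the synthetic scene family.
#' @param n_train,n_select,n_eval Pixels in the train / band-selection /
#'   evaluation splits (always disjoint; the evaluation split is rendered
#'   by a denser "second sensor" and band-matched back, see
#'   [make_splits()]).
#' @param methods Subset of `ksvd`, `ksvd-bbs`, `updm`, `updm-bbs`, `dcs`,
#'   `dcs-gm`.
#' @param m_list Band counts to evaluate.
#' @param k_list Dictionary sizes for the K-SVD variants.
#' @param t Sparsity target, or `"auto"` for the 10 percent rule.
#' @param replications Replications for the plain (non-BBS) methods
#'   (default 20).
#' @param n_candidates,keep BBS candidates drawn and sets kept (20 / 3).
#' @param band_reps,groupings DCS cross structure: band-set assignments x
#'   pixel groupings (4 x 5 = 20 runs; the GM median is over groupings).
#' @param group_size DCS joint-solve group size (default 64).
#' @param seed Master seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(scene = scene_config(),
                              n_train = 200, n_select = 200, n_eval = 400,
                              methods = c("ksvd", "ksvd-bbs", "updm",
                                          "updm-bbs", "dcs", "dcs-gm"),
                              m_list = 8, k_list = 8, t = "auto",
                              replications = 20,
                              n_candidates = 20, keep = 3,
                              band_reps = 4, groupings = 5,
                              group_size = 64, seed = 1) {
  methods <- match.arg(methods, several.ok = TRUE,
                       choices = c("ksvd", "ksvd-bbs", "updm", "updm-bbs",
                                   "dcs", "dcs-gm"))
  stopifnot(inherits(scene, "scene_config"),
            n_train >= 1, n_select >= 1, n_eval >= 1,
            all(m_list >= 1), all(k_list >= 1),
            replications >= 1, n_candidates >= 1, keep >= 1,
            band_reps >= 1, groupings >= 1, group_size >= 1)
  if (!identical(t, "auto")) stopifnot(is.numeric(t), t >= 1)
  structure(as.list(environment()), class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Top-level keys mirror the [experiment_config()] arguments; a `scene`
#' mapping mirrors [scene_config()]. Unknown keys are an error.
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(experiment_config)), "scene")
  bad <- setdiff(names(raw), c(known, "scene"))
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  args <- raw[intersect(names(raw), known)]
  if (!is.null(raw$scene)) {
    sk <- names(formals(scene_config))
    bad_s <- setdiff(names(raw$scene), sk)
    if (length(bad_s) > 0) {
      stop("unknown scene config key(s): ", paste(bad_s, collapse = ", "),
           call. = FALSE)
    }
    if (!is.null(raw$scene$class_props)) {
      raw$scene$class_props <- unlist(raw$scene$class_props)
    }
    args$scene <- do.call(scene_config, raw$scene)
  }
  do.call(experiment_config, args)
}

#' Run a full reconstruction experiment
#'
#' @param config An [experiment_config()].
#' @param seed Master seed (defaults to the config's).
#' @param verbose Print per-stage progress.
#' @return An `experiment_result`: tibble of reports (`method`, `m`, `k`,
#'   `median_of_medians`, `report` list-column), the trained artifacts,
#'   and a manifest of the seeds used.
#' @export
run_experiment <- function(config, seed = config$seed, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(...)
  seeds <- list(scene = derive_seeds(seed, "scene", 1),
                train = derive_seeds(seed, "train", 1),
                bbs = derive_seeds(seed, "bbs", 1),
                eval = derive_seeds(seed, "eval", 1))
  say("generating scene splits")
  splits <- make_splits(config$scene, config$n_train, config$n_select,
                        config$n_eval, seed = seeds$scene)
  n <- length(config$scene$wavelengths)
  need_ksvd <- any(grepl("^ksvd", config$methods))
  need_updm <- any(grepl("^updm", config$methods))
  dicts <- list()
  if (need_ksvd) {
    for (k in config$k_list) {
      t <- if (identical(config$t, "auto")) {
        default_sparsity_target(n, k)
      } else min(config$t, k)
      say("training dictionary K = ", k, " (T = ", t, ")")
      dicts[[as.character(k)]] <-
        train_dictionary(splits$train, k, t, seed = seeds$train)
    }
  }
  bases <- if (need_updm) extract_bases(splits$train) else NULL
  rows <- list()
  add_row <- function(method, m, k, report) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      method = method, m = m, k = k %||% NA_integer_,
      median_of_medians = report$median_of_medians,
      report = list(report))
  }
  for (m in config$m_list) {
    for (method in config$methods) {
      if (method %in% c("ksvd", "ksvd-bbs")) {
        for (k in config$k_list) {
          dict <- dicts[[as.character(k)]]
          say(method, " m = ", m, " k = ", k)
          rep <- if (method == "ksvd") {
            evaluate_method(splits$eval, dict, m,
                            replications = config$replications,
                            seed = seeds$eval)
          } else {
            bbs <- best_band_sets(splits$band_select, dict, m,
                                  config$n_candidates, config$keep,
                                  seed = seeds$bbs)
            r <- evaluate_method(splits$eval, dict,
                                 band_sets = bbs$best,
                                 replications = config$keep,
                                 seed = seeds$eval)
            r$config$bbs_scores <- bbs$scores
            r$method <- "ksvd-bbs"
            r
          }
          add_row(method, m, k, rep)
        }
      } else if (method %in% c("updm", "updm-bbs")) {
        say(method, " m = ", m)
        rep <- if (method == "updm") {
          evaluate_method(splits$eval, bases, m,
                          replications = config$replications,
                          seed = seeds$eval)
        } else {
          bbs <- best_band_sets(splits$band_select, bases, m,
                                config$n_candidates, config$keep,
                                seed = seeds$bbs)
          r <- evaluate_method(splits$eval, bases,
                               band_sets = bbs$best,
                               replications = config$keep,
                               seed = seeds$eval)
          r$method <- "updm-bbs"
          r
        }
        add_row(method, m, NULL, rep)
      }
    }
    if (any(c("dcs", "dcs-gm") %in% config$methods)) {
      say("dcs m = ", m)
      both <- evaluate_dcs(splits$eval, m,
                           band_reps = config$band_reps,
                           groupings = config$groupings,
                           group_size = config$group_size,
                           seed = seeds$eval)
      if ("dcs" %in% config$methods) add_row("dcs", m, NULL, both$dcs)
      if ("dcs-gm" %in% config$methods) {
        add_row("dcs-gm", m, NULL, both$dcs_gm)
      }
    }
  }
  structure(list(
    reports = dplyr::bind_rows(rows),
    dictionaries = dicts,
    bases = bases,
    splits = splits,
    manifest = list(seed = seed, sub_seeds = seeds,
                    methods = config$methods, m_list = config$m_list,
                    k_list = config$k_list, t = config$t,
                    n_bands = n,
                    splits = vapply(splits, n_spectra, numeric(1)))
  ), class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Experiment result (", nrow(x$reports), " reports)\n", sep = "")
  print(x$reports[, c("method", "m", "k", "median_of_medians")])
  invisible(x)
}

#' Summarise an experiment as one row per report
#'
#' @param x An `experiment_result`.
#' @param ... Unused.
#' @return Tibble of [glance.eval_report()] rows with `method`, `m`, `k`.
#' @export
glance.experiment_result <- function(x, ...) {
  dplyr::bind_cols(
    x$reports[, c("method", "m", "k")],
    dplyr::bind_rows(lapply(x$reports$report,
                            function(r) glance(r)[, -(1:2)]))
  )
}
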