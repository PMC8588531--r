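# Synthetic vegetation scenes. The generator emulates the statistical
# structure the reconstruction methods assume: smooth spectra, a steep
# vegetation red edge near 700 nm, bright smooth soil, dark water, and a
# small fraction of broadband "built-up" anomaly pixels that fall outside
# the water/vegetation/soil mixing model.

#' Default endmember shape parameters
#'
#' @param class One of `"vegetation"`, `"soil"`, `"water"`, `"builtup"`.
#' @param ... Named overrides of individual parameters.
#' @return A named list of shape parameters with a `class` entry.
#'
#' @details Vegetation is a logistic red-edge transition from a low visible
#' level to a NIR plateau plus a Gaussian green-peak bump: `visible` and
#' `nir` are reflectance levels, `red_edge` the transition centre in nm,
#' `red_edge_width` the 10--90 percent transition width in nm. Soil is a
#' smooth linear increase (`intercept`, `slope` over the grid range), water
#' a low decreasing line, and built-up a broadband level plus low-frequency
#' cosine ripples (`ripple`, `phase` vectors).
#' @export
endmember_params <- function(class = c("vegetation", "soil", "water",
                                       "builtup"), ...) {
  class <- match.arg(class)
  p <- switch(class,
    vegetation = list(visible = 0.05, green_peak = 0.03, green_center = 550,
                      green_width = 30, red_edge = 715, red_edge_width = 30,
                      nir = 0.5),
    soil = list(intercept = 0.15, slope = 0.25),
    water = list(level = 0.08, decay = 1.5),
    builtup = list(level = 0.3, ripple = c(0.05, 0.03, 0.02),
                   phase = c(0, 1, 2))
  )
  dots <- list(...)
  p[names(dots)] <- dots
  c(list(class = class), p)
}

#' Evaluate an endmember model on a wavelength grid
#'
#' Deterministic smooth reflectance spectrum for one land-cover class;
#' values outside \[0, 1\] are clamped with a warning.
#'
#' @param params Parameter list from [endmember_params()].
#' @param wavelengths Wavelength grid (nm).
#' @return A spectra tibble with a single spectrum labelled by class.
#' @export
endmember_spectrum <- function(params, wavelengths) {
  check_grid(wavelengths)
  r <- endmember_values(params, wavelengths)
  if (any(r < 0) || any(r > 1)) {
    warning("endmember reflectance clamped to [0, 1]", call. = FALSE)
    r <- pmin(pmax(r, 0), 1)
  }
  spectra_tbl(wavelengths, r, ids = params$class, class = params$class)
}

endmember_values <- function(params, wl) {
  lo <- min(wl); hi <- max(wl)
  u <- (wl - lo) / max(hi - lo, 1)
  switch(params$class,
    vegetation = {
      # logistic scale s: 10-90% transition over red_edge_width nm
      s <- params$red_edge_width / (2 * log(9))
      params$visible +
        params$green_peak *
          exp(-(wl - params$green_center)^2 / (2 * params$green_width^2)) +
        (params$nir - params$visible) *
          stats::plogis((wl - params$red_edge) / s)
    },
    soil = params$intercept + params$slope * u,
    water = params$level * exp(-params$decay * u),
    builtup = {
      k <- seq_along(params$ripple)
      params$level +
        colSums(params$ripple *
                  cos(outer(k, 2 * pi * u) + params$phase))
    },
    stop("unknown endmember class ", params$class, call. = FALSE)
  )
}

#' Scene configuration
#'
#' @param wavelengths Working wavelength grid (nm); default 40 bands over
#'   406--1100 nm.
#' @param rows,cols Scene dimensions in pixels.
#' @param class_props Named numeric vector of land-cover proportions over
#'   `vegetation`, `soil`, `water` (normalised internally).
#' @param patch Side length (pixels) of the rectangular land-use patches.
#' @param jitter Relative per-pixel jitter of endmember shape parameters
#'   (standard deviation of a multiplicative perturbation; the red-edge
#'   position is jittered additively by `20 * jitter` nm).
#' @param noise_sd Standard deviation of additive Gaussian sensor noise in
#'   reflectance units (default 0.005).
#' @param anomaly_fraction Fraction of pixels replaced by built-up anomaly
#'   spectra (label `"builtup"`).
#' @param seed Integer seed; identical configurations give identical scenes.
#' @return A `scene_config` list.
#' @export
scene_config <- function(wavelengths = default_grid(),
                         rows = 32, cols = 32,
                         class_props = c(vegetation = 0.7, soil = 0.2,
                                         water = 0.1),
                         patch = 8,
                         jitter = 0.05,
                         noise_sd = 0.005,
                         anomaly_fraction = 0,
                         seed = 1) {
  check_grid(wavelengths)
  stopifnot(rows >= 1, cols >= 1, patch >= 1,
            noise_sd >= 0, anomaly_fraction >= 0, anomaly_fraction <= 1,
            all(class_props >= 0), sum(class_props) > 0)
  structure(list(wavelengths = wavelengths, rows = rows, cols = cols,
                 class_props = class_props / sum(class_props),
                 patch = patch, jitter = jitter, noise_sd = noise_sd,
                 anomaly_fraction = anomaly_fraction,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# run code under a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Draw the per-pixel latent model of a scene: class map (rectangular
# patches), jittered endmember parameters, anomaly replacement. Rendering
# onto a wavelength grid is separate so the same pixels can be "observed"
# by sensors with different band grids.
scene_pixels <- function(config) {
  with_seed(config$seed, {
    rows <- config$rows; cols <- config$cols
    pr <- ceiling(rows / config$patch)
    pc <- ceiling(cols / config$patch)
    patch_class <- sample(names(config$class_props), pr * pc, replace = TRUE,
                          prob = config$class_props)
    ri <- (seq_len(rows) - 1L) %/% config$patch
    ci <- (seq_len(cols) - 1L) %/% config$patch
    grid <- expand.grid(row = seq_len(rows), col = seq_len(cols))
    cls <- patch_class[ri[grid$row] * pc + ci[grid$col] + 1L]
    n_px <- nrow(grid)
    n_anom <- round(config$anomaly_fraction * n_px)
    anom <- if (n_anom > 0) sample.int(n_px, n_anom) else integer(0)
    cls[anom] <- "builtup"
    params <- lapply(seq_len(n_px), function(i) {
      p <- if (cls[i] == "builtup") {
        endmember_params("builtup",
                         level = stats::runif(1, 0.15, 0.45),
                         ripple = stats::runif(3, -0.06, 0.06),
                         phase = stats::runif(3, 0, 2 * pi))
      } else {
        endmember_params(cls[i])
      }
      jitter_params(p, config$jitter)
    })
    noise_seeds <- sample.int(.Machine$integer.max, n_px)
    list(config = config,
         coords = tibble::tibble(row = grid$row, col = grid$col),
         class = cls, params = params, noise_seeds = noise_seeds)
  })
}

jitter_params <- function(p, jitter) {
  if (jitter <= 0) return(p)
  for (nm in setdiff(names(p), c("class", "red_edge", "green_center",
                                 "phase"))) {
    p[[nm]] <- p[[nm]] * (1 + stats::rnorm(length(p[[nm]]), 0, jitter))
  }
  if (!is.null(p$red_edge)) {
    p$red_edge <- p$red_edge + stats::rnorm(1, 0, 20 * jitter)
  }
  p
}

render_pixels <- function(pixels, which_px, wavelengths) {
  cfg <- pixels$config
  vals <- vapply(which_px, function(i) {
    r <- endmember_values(pixels$params[[i]], wavelengths)
    if (cfg$noise_sd > 0) {
      r <- r + with_seed(pixels$noise_seeds[i],
                         stats::rnorm(length(wavelengths), 0, cfg$noise_sd))
    }
    pmin(pmax(r, 0), 1)
  }, numeric(length(wavelengths)))
  coords <- pixels$coords[which_px, , drop = FALSE]
  spectra_tbl(wavelengths, vals,
              ids = sprintf("r%dc%d", coords$row, coords$col),
              class = pixels$class[which_px], coords = coords)
}

#' Generate a synthetic hyperspectral scene
#'
#' Per-pixel spectrum = jittered class endmember + i.i.d. Gaussian noise,
#' clamped to \[0, 1\]; a configured fraction of pixels is replaced by
#' built-up anomaly spectra. Identical configuration (including seed)
#' yields an identical scene.
#'
#' @param config A [scene_config()].
#' @return A spectra tibble with `row`, `col` and `class` columns.
#' @export
make_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  px <- scene_pixels(config)
  render_pixels(px, seq_len(nrow(px$coords)), config$wavelengths)
}

#' Split a scene into train / band-selection / evaluation sets
#'
#' Mimics a cross-sensor protocol: training and band-selection pixels are
#' observed on the working grid, while evaluation pixels are observed by a
#' "different sensor" with a denser grid and then matched back onto the
#' working grid by nearest-band resampling. The three splits are disjoint
#' in pixel coordinates.
#'
#' @param config A [scene_config()]; `rows * cols` must cover the requested
#'   split sizes.
#' @param n_train,n_select,n_eval Pixels per role.
#' @param fine_factor Density multiplier of the evaluation sensor's grid.
#' @param seed Integer seed for the pixel assignment.
#' @return Named list of spectra tibbles: `train`, `band_select`, `eval`.
#' @export
make_splits <- function(config, n_train, n_select, n_eval,
                        fine_factor = 4, seed = config$seed) {
  stopifnot(inherits(config, "scene_config"))
  n_px <- config$rows * config$cols
  if (n_train + n_select + n_eval > n_px) {
    stop("requested split sizes exceed scene size (", n_px, " pixels)",
         call. = FALSE)
  }
  px <- scene_pixels(config)
  perm <- with_seed(seed, sample.int(n_px))
  i_train <- perm[seq_len(n_train)]
  i_select <- perm[n_train + seq_len(n_select)]
  i_eval <- perm[n_train + n_select + seq_len(n_eval)]
  wl <- config$wavelengths
  fine <- seq(min(wl), max(wl),
              length.out = fine_factor * (length(wl) - 1) + 1)
  max_gap <- max(diff(wl))
  list(
    train = render_pixels(px, i_train, wl),
    band_select = render_pixels(px, i_select, wl),
    eval = resample_spectra(render_pixels(px, i_eval, fine), wl,
                            max_gap = max_gap)
  )
}
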