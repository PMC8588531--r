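# Shared fixtures, generated in code.

tiny_grid <- c(450, 550, 650)

tiny_spectra <- function() {
  spectra_tbl(tiny_grid,
              cbind(a = c(0.10, 0.20, 0.15), b = c(0.05, 0.40, 0.30)))
}

# small labelled scene rendered once per test run
small_scene <- function(seed = 7, rows = 12, cols = 12, patch = 4,
                        anomaly_fraction = 0, noise_sd = 0.005) {
  make_scene(scene_config(rows = rows, cols = cols, patch = patch,
                          noise_sd = noise_sd,
                          anomaly_fraction = anomaly_fraction, seed = seed))
}

# noiseless endmembers on the default grid
endmembers_tbl <- function(grid = default_grid()) {
  dplyr::bind_rows(lapply(c("vegetation", "soil", "water"), function(cl) {
    endmember_spectrum(endmember_params(cl), grid)
  }))
}

reflectance_at <- function(spectra, id_, wl_) {
  w <- spectra$wavelength[spectra$id == id_]
  r <- spectra$reflectance[spectra$id == id_]
  r[which.min(abs(w - wl_))]
}
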