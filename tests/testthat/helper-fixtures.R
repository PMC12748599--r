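# Shared fixtures, built in code.

# annual_spectra realizing a given NBR series exactly (constant nir+swir2)
spectra_from_nbr <- function(nbr, years = seq_along(nbr) + 1984, s0 = 0.3) {
  refl <- matrix(0.05, length(nbr), 6, dimnames = list(NULL, band_names()))
  refl[, "nir"] <- s0 * (1 + nbr) / 2
  refl[, "swir2"] <- s0 * (1 - nbr) / 2
  miss <- is.na(nbr)
  refl[miss, ] <- NA
  annual_spectra(years, refl, miss)
}

# brute-force SSE-minimizing single-knee fit: the independent oracle for
# the greedy segmentation on two-piece series
brute_force_knee <- function(y, t) {
  best <- NULL
  for (k in t[2:(length(t) - 1)]) {
    fit <- lm(y ~ t + pmax(t - k, 0))
    sse <- sum(residuals(fit)^2)
    if (is.null(best) || sse < best$sse - 1e-12) best <- list(knee = k, sse = sse)
  }
  best
}

# a small trained model shared across tests (4 distinctive classes,
# trained once per session)
tiny_model_env <- new.env()
tiny_model <- function() {
  if (is.null(tiny_model_env$m)) {
    ts <- simulate_training_set(n_per_class = 60, noise_sd = 0.01, seed = 99)
    keep <- ts$label %in% c("fire", "harvest_total", "defol_medium", "forest")
    tiny_model_env$m <- tempcnn_train(
      ts$x[keep, , ], ts$label[keep],
      tcfg = train_config(epochs = 12, seed = 7))
  }
  tiny_model_env$m
}
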