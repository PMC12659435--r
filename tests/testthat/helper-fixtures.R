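# shared fixtures, built once per test session and memoized

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- build()
  .fixture_env[[key]]
}

# small mixed library
small_library <- function(n_pfas = 10L, n_background = 30L, seed = 7L) {
  memo(sprintf("lib_%d_%d_%d", n_pfas, n_background, seed),
       function() generate_library(n_pfas, n_background, seed = seed))
}

# a quick trained autoencoder on a small library (shared across tests that
# only need *a* trained model, not a converged one)
quick_ae <- function() {
  memo("quick_ae", function() {
    lib <- small_library()
    train_autoencoder(lib, model_config(seed = 5L), epochs = 8L, seed = 5L)
  })
}

# synthetic spectra for a library: one record per molecule
quick_spectra <- function(lib = small_library(), seed = 21L,
                          noise_sd = 0.003) {
  lapply(seq_along(lib), function(i)
    simulate_spectrum(lib[[i]], seed = seed + i, noise_sd = noise_sd))
}

# preprocess a spectrum_record to a tokenized_spectrum
prep_tokens <- function(s, max_peaks = 100L, max_len = 256L) {
  s$peaks <- normalize_intensities(s$peaks[!s$peaks$is_loss, , drop = FALSE])
  tokenize_spectrum(add_loss_features(s), max_peaks, max_len)
}

# hand-made tokenized_spectrum
mk_tokspec <- function(tokens, intensities,
                       segs = rep("fragment", length(tokens))) {
  structure(list(tokens = as.integer(tokens), intensities = intensities,
                 segment_flags = segs), class = "tokenized_spectrum")
}
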