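test_that("autoencoder training decreases loss reproducibly", {
  lib <- small_library()[1:12]
  cfg <- model_config(gru_hidden = 48L, emb_dim = 24L, latent_dim = 16L,
                      seed = 2L)
  ae1 <- train_autoencoder(lib, cfg, epochs = 4L, seed = 2L)
  ae2 <- train_autoencoder(lib, cfg, epochs = 4L, seed = 2L)
  expect_identical(ae1$history$train_loss, ae2$history$train_loss)
  expect_lt(utils::tail(ae1$history$train_loss, 1),
            ae1$history$train_loss[1])
  # the best-so-far curve is monotone non-increasing
  expect_true(all(diff(ae1$history$best_loss) <= 0))
  # epochs = 0 returns an untrained model with empty history
  ae0 <- train_autoencoder(lib, cfg, epochs = 0L, seed = 2L)
  expect_length(ae0$history$train_loss, 0L)
  expect_s3_class(ae0, "smiles_ae")
  expect_error(train_autoencoder(list(), cfg), "empty-input")
})

test_that("untrained models reconstruct at chance level", {
  lib <- small_library()
  cfg <- model_config(gru_hidden = 48L, emb_dim = 24L, latent_dim = 16L)
  ae0 <- train_autoencoder(lib, cfg, epochs = 0L, seed = 1L)
  expect_lte(reconstruction_accuracy(ae0, lib), 0.05)
  expect_error(reconstruction_accuracy(ae0, list()), "empty-input")
})

test_that("spectral alignment memorizes a single pair to below 1e-3 MSE", {
  ae <- quick_ae()
  lib <- small_library()
  s <- quick_spectra(lib[1:2])[[1]]
  pair <- list(list(spectrum = prep_tokens(s),
                    target = encode_molecule(lib[[1]], ae)))
  enc <- train_spectral_encoder(pair, ae$config, epochs = 150L, seed = 3L,
                                lr = 5e-3)
  pred <- encode_spectrum(pair[[1]]$spectrum, enc)
  expect_lt(mean((pred - pair[[1]]$target)^2), 1e-3)
})

test_that("spectral training is reproducible and validates shapes", {
  ae <- quick_ae()
  lib <- small_library()[1:6]
  pairs <- lapply(quick_spectra(lib), function(s) {
    i <- match(s$compound_key, vapply(lib, `[[`, character(1), "inchikey2d"))
    list(spectrum = prep_tokens(s), target = encode_molecule(lib[[i]], ae))
  })
  e1 <- train_spectral_encoder(pairs, ae$config, epochs = 2L, seed = 4L)
  e2 <- train_spectral_encoder(pairs, ae$config, epochs = 2L, seed = 4L)
  expect_identical(e1$history$train_loss, e2$history$train_loss)
  bad_cfg <- model_config(latent_dim = 32L)
  expect_error(train_spectral_encoder(pairs, bad_cfg), "shape")
  expect_error(train_spectral_encoder(list(), ae$config), "empty-input")
})

test_that("alignment training never mutates the autoencoder", {
  ae <- quick_ae()
  lib <- small_library()[1:4]
  before <- serialize(ae$params, NULL)
  pairs <- lapply(quick_spectra(lib), function(s) {
    i <- match(s$compound_key, vapply(lib, `[[`, character(1), "inchikey2d"))
    list(spectrum = prep_tokens(s), target = encode_molecule(lib[[i]], ae))
  })
  invisible(train_spectral_encoder(pairs, ae$config, epochs = 2L, seed = 1L))
  expect_identical(serialize(ae$params, NULL), before)
})

test_that("randomized serializations of one molecule embed closer than
           unrelated molecules", {
  lib <- small_library()
  ae <- memo("geom_ae", function()
    train_autoencoder(lib, model_config(seed = 19L), epochs = 30L,
                      seed = 19L))
  emb <- t(vapply(lib, function(r) encode_molecule(r, ae),
                  numeric(ae$config$latent_dim)))
  inter <- as.numeric(dist(emb))^2 / ae$config$latent_dim  # MSE distances
  med_inter <- stats::median(inter)
  ok <- vapply(lib[seq(1, length(lib), by = 4)], function(r) {
    z1 <- encode_molecule(tokenize_smiles(randomize_smiles(r, 1L)), ae)
    z2 <- encode_molecule(tokenize_smiles(randomize_smiles(r, 2L)), ae)
    mean((z1 - z2)^2) < med_inter
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("augmentation always targets the canonical sequence", {
  # randomized serializations of one molecule all decode-target the same
  # canonical ids: check by construction through the vocabulary mapping
  lib <- small_library()[1:5]
  vocab <- ms2pfas:::smiles_vocab(lib)
  for (r in lib) {
    can <- ms2pfas:::.tokens_to_ids(r$smiles_tokens, vocab, 110L)
    for (seed in 1:3) {
      rnd <- randomize_smiles(r, seed)
      rec <- prepare_molecule(rnd)
      expect_identical(
        ms2pfas:::.tokens_to_ids(rec$smiles_tokens, vocab, 110L), can)
    }
  }
})
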