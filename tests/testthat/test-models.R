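test_that("intensity-modulated rotation is a norm-preserving relative code", {
  set.seed(11)
  X <- matrix(rnorm(6 * 8), 6, 8)
  ints <- c(0, 0.2, 0.4, 0.6, 0.8, 1.0)
  R <- intensity_rope(X, ints, rope_scale = 100)
  # zero intensity -> zero angle -> unchanged
  expect_equal(R[1, ], X[1, ], tolerance = 1e-12)
  # rotations preserve norms
  expect_equal(sqrt(rowSums(R^2)), sqrt(rowSums(X^2)), tolerance = 1e-6)
  # equal intensities: rotated dot product equals unrotated dot product
  Y <- matrix(rnorm(2 * 8), 2, 8)
  Ry <- intensity_rope(Y, c(0.37, 0.37), rope_scale = 100)
  expect_equal(sum(Ry[1, ] * Ry[2, ]), sum(Y[1, ] * Y[2, ]),
               tolerance = 1e-6)
  # interaction depends only on the intensity difference
  d1 <- intensity_rope(Y, c(0.9, 0.6))
  d2 <- intensity_rope(Y, c(0.5, 0.2))
  expect_equal(sum(d1[1, ] * d1[2, ]), sum(d2[1, ] * d2[2, ]),
               tolerance = 1e-6)
  # inversion undoes the rotation
  expect_equal(intensity_rope(R, ints, invert = TRUE), X, tolerance = 1e-10)
  expect_error(intensity_rope(X[, 1:7], ints), "shape")
  # all-zero intensities reduce the whole transform to a no-op
  expect_equal(intensity_rope(X, rep(0, 6)), X, tolerance = 1e-12)
})

test_that("molecule encoding is deterministic with the configured shape", {
  ae <- quick_ae()
  lib <- small_library()
  z1 <- encode_molecule(lib[[1]], ae)
  z2 <- encode_molecule(lib[[1]], ae)
  expect_identical(z1, z2)
  expect_length(z1, ae$config$latent_dim)
  expect_true(all(is.finite(z1)))
  expect_error(encode_molecule(c(lib[[1]]$smiles_tokens, "ZZ"), ae), "vocab")
  expect_error(encode_molecule(rep("C", 200), ae), "length")
})

test_that("greedy decoding respects the hard cap and never crashes", {
  ae <- quick_ae()
  out <- decode_molecule(rep(0, ae$config$latent_dim), ae)
  expect_true(is.character(out))
  expect_lte(length(out), 110L)
  expect_error(decode_molecule(rep(0, 3), ae), "shape")
})

test_that("spectrum encoding is deterministic, shaped and validated", {
  ae <- quick_ae()
  enc <- memo("quick_encoder", function() {
    lib <- small_library()
    pairs <- lapply(quick_spectra(lib), function(s) {
      i <- match(s$compound_key, vapply(lib, `[[`, character(1), "inchikey2d"))
      list(spectrum = prep_tokens(s), target = encode_molecule(lib[[i]], ae))
    })
    train_spectral_encoder(pairs, ae$config, epochs = 3L, seed = 5L)
  })
  ts <- prep_tokens(quick_spectra(small_library()[1:2])[[1]])
  e1 <- encode_spectrum(ts, enc)
  e2 <- encode_spectrum(ts, enc)
  expect_identical(e1, e2)
  expect_length(e1, enc$config$latent_dim)
  bad <- ts; bad$intensities <- bad$intensities[-1]
  expect_error(encode_spectrum(bad, enc), "shape")
  long <- mk_tokspec(seq_len(300), rep(1, 300))
  expect_error(encode_spectrum(long, enc), "length")
})

test_that("one optimizer step strictly decreases the batch loss", {
  # autoencoder
  lib <- small_library()[1:8]
  cfg <- model_config(seed = 3L)
  vocab <- ms2pfas:::smiles_vocab(lib)
  ids <- lapply(lib, function(r) ms2pfas:::.tokens_to_ids(r$smiles_tokens,
                                                          vocab, 110L))
  Xin <- ms2pfas:::.pad_ids(ids)
  Ytgt <- ms2pfas:::.pad_ids(lapply(ids, function(x) c(x, 3L)))
  set.seed(3)
  p <- ms2pfas:::.init_ae_params(cfg, length(vocab))
  r0 <- ms2pfas:::.ae_batch(p, Xin, Ytgt, cfg, want_grads = TRUE)
  flat <- ms2pfas:::.flatten_params(p)
  st <- ms2pfas:::adam_state(flat)
  upd <- ms2pfas:::adam_step(flat, ms2pfas:::.flatten_params(r0$grads), st,
                             lr = 1e-3)
  p1 <- ms2pfas:::.unflatten_params(upd$params, p)
  r1 <- ms2pfas:::.ae_batch(p1, Xin, Ytgt, cfg, want_grads = FALSE)
  expect_lt(r1$loss, r0$loss)

  # spectral encoder
  cfg2 <- model_config(seed = 4L, vocab_size_spectrum = 1000L,
                       cnn_kernel_sizes = c(1L, 3L, 5L), spec_emb_dim = 16L,
                       attn_heads = 2L, latent_dim = 8L)
  set.seed(4)
  batch <- lapply(1:6, function(i) list(
    spectrum = mk_tokspec(sample(990, 5), runif(5)),
    target = rnorm(8)))
  p2 <- ms2pfas:::.init_spec_params(cfg2)
  s0 <- ms2pfas:::.spec_batch(p2, batch, cfg2, want_grads = TRUE)
  opt <- ms2pfas:::.spec_opt_state(p2)
  opt <- ms2pfas:::.spec_adam(p2, s0$grads, opt, lr = 1e-3)
  s1 <- ms2pfas:::.spec_batch(opt$params, batch, cfg2, want_grads = FALSE)
  expect_lt(s1$loss, s0$loss)
})
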