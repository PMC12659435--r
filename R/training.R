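#' Train the SMILES autoencoder
#'
#' Unsupervised pretraining that defines the chemical latent space. Every
#' epoch each molecule contributes a freshly randomized SMILES as encoder
#' input (plus the canonical identity pair) with its canonical token
#' sequence as the decoding target; the objective is per-token
#' cross-entropy. Fully reproducible for a fixed seed.
#'
#' @param library list of `molecule_record`.
#' @param config a [model_config()].
#' @param epochs number of epochs (0 returns an untrained model).
#' @param seed integer seed controlling initialization, augmentation and
#'   batch order.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param include_canonical also feed each molecule's canonical form as an
#'   identity pair every epoch.
#' @param lr_decay cosine-decay the learning rate to `lr/20` over the run.
#' @param verbose print per-epoch loss?
#' @return an object of class `smiles_ae`: `params`, `vocab`, `config`, and
#'   `history` (`train_loss` per epoch and monotone `best_loss`).
#' @export
train_autoencoder <- function(library, config = model_config(), epochs = 50L,
                              seed = 1L, lr = 2e-3, batch_size = 32L,
                              include_canonical = TRUE, lr_decay = TRUE,
                              verbose = FALSE) {
  if (length(library) == 0L) stop("empty-input: no molecules", call. = FALSE)
  vocab <- smiles_vocab(library)
  can_ids <- lapply(library, function(r)
    .tokens_to_ids(r$smiles_tokens, vocab, config$max_smiles_len))
  with_preserved_seed({
    set.seed(as.integer(seed))
    p <- .init_ae_params(config, length(vocab))
    flat <- .flatten_params(p)
    st <- adam_state(flat)
    hist <- numeric(0)
    n <- length(library)
    for (ep in seq_len(epochs)) {
      # cosine learning-rate decay to lr/20 for a clean final fit
      lr_ep <- if (lr_decay && epochs > 1L)
        lr / 20 + 0.5 * (lr - lr / 20) * (1 + cos(pi * (ep - 1) / (epochs - 1)))
      else lr
      # fresh randomized serialization per molecule per epoch
      aug_seed_base <- sample.int(1e6, 1L)
      inputs <- list(); targets <- list()
      for (i in seq_len(n)) {
        rnd <- randomize_smiles(library[[i]], aug_seed_base + i)
        rnd_ids <- tryCatch(
          .tokens_to_ids(tokenize_smiles(rnd), vocab, config$max_smiles_len),
          error = function(e) NULL)
        tgt <- c(can_ids[[i]], .EOS_ID)
        if (!is.null(rnd_ids)) {
          inputs[[length(inputs) + 1L]] <- rnd_ids
          targets[[length(targets) + 1L]] <- tgt
        }
        if (include_canonical) {
          inputs[[length(inputs) + 1L]] <- can_ids[[i]]
          targets[[length(targets) + 1L]] <- tgt
        }
      }
      # bucket by target length to limit padding, then shuffle batch order
      ord <- order(vapply(targets, length, integer(1)))
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      batches <- batches[sample.int(length(batches))]
      ep_loss <- 0; ep_n <- 0
      for (bi in batches) {
        Xin <- .pad_ids(inputs[bi])
        Ytgt <- .pad_ids(targets[bi])
        res <- .ae_batch(p, Xin, Ytgt, config, want_grads = TRUE)
        gflat <- .flatten_params(res$grads)
        upd <- adam_step(flat, gflat, st, lr = lr_ep)
        flat <- upd$params; st <- upd$state
        p <- .unflatten_params(flat, p)
        ep_loss <- ep_loss + res$loss * length(bi)
        ep_n <- ep_n + length(bi)
      }
      hist <- c(hist, ep_loss / ep_n)
      if (verbose) message(sprintf("epoch %d  loss %.4f", ep, utils::tail(hist, 1)))
    }
    structure(list(params = p, vocab = vocab, config = config,
                   seed = as.integer(seed),
                   history = list(train_loss = hist, best_loss = cummin(
                     if (length(hist)) hist else numeric(0)))),
              class = "smiles_ae")
  })
}

#' Exact-reconstruction rate of a trained autoencoder
#'
#' Fraction of molecules whose greedy decode of their own canonical
#' encoding reproduces the canonical token sequence exactly.
#'
#' @param ae a trained `smiles_ae`.
#' @param library list of `molecule_record`.
#' @return fraction in \[0, 1\].
#' @export
reconstruction_accuracy <- function(ae, library) {
  stopifnot(inherits(ae, "smiles_ae"))
  if (length(library) == 0L) stop("empty-input", call. = FALSE)
  ok <- vapply(library, function(r) {
    z <- encode_molecule(r, ae)
    dec <- decode_molecule(z, ae)
    identical(dec, r$smiles_tokens)
  }, logical(1))
  mean(ok)
}

#' Train the spectral encoder against frozen molecular embeddings
#'
#' Aligns spectrum embeddings E_s with the chemical latent codes E_a of
#' their parent molecules by minimizing mean squared error. The autoencoder
#' that produced the targets is never updated.
#'
#' @param pairs list of `list(spectrum = tokenized_spectrum, target =
#'   numeric latent vector)`.
#' @param config a [model_config()] whose `latent_dim` matches the targets.
#' @param epochs training epochs.
#' @param seed integer seed.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param verbose print per-epoch loss?
#' @return an object of class `spectral_encoder` with `params`, `config`
#'   and `history` (per-epoch MSE).
#' @export
train_spectral_encoder <- function(pairs, config = model_config(),
                                   epochs = 30L, seed = 1L, lr = 2e-3,
                                   batch_size = 32L, verbose = FALSE) {
  if (length(pairs) == 0L) stop("empty-input: no training pairs", call. = FALSE)
  L <- length(pairs[[1]]$target)
  if (L != config$latent_dim)
    stop("shape: target latent dim != config latent_dim", call. = FALSE)
  with_preserved_seed({
    set.seed(as.integer(seed))
    p <- .init_spec_params(config)
    opt <- .spec_opt_state(p)
    hist <- numeric(0)
    n <- length(pairs)
    lens <- vapply(pairs, function(pr) length(pr$spectrum$tokens), integer(1))
    for (ep in seq_len(epochs)) {
      ord <- order(lens + stats::runif(n))  # stable-ish buckets, random ties
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      batches <- batches[sample.int(length(batches))]
      ep_loss <- 0
      for (bi in batches) {
        batch <- pairs[bi]
        res <- .spec_batch(p, batch, config, want_grads = TRUE)
        opt <- .spec_adam(p, res$grads, opt, lr)
        p <- opt$params
        ep_loss <- ep_loss + res$loss * length(bi)
      }
      hist <- c(hist, ep_loss / n)
      if (verbose) message(sprintf("epoch %d  mse %.5f", ep, utils::tail(hist, 1)))
    }
    structure(list(params = p, config = config, seed = as.integer(seed),
                   history = list(train_loss = hist)),
              class = "spectral_encoder")
  })
}

#' @export
print.spectral_encoder <- function(x, ...) {
  cat("<spectral_encoder> latent", x$config$latent_dim, ";",
      x$config$attn_layers, "attention layers x", x$config$attn_heads,
      "heads;", x$config$cnn_layers, "conv kernels\n")
  if (length(x$history$train_loss) > 0L)
    cat(sprintf("  trained %d epochs; final MSE %.5f\n",
                length(x$history$train_loss),
                utils::tail(x$history$train_loss, 1)))
  invisible(x)
}
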