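#' Model configuration
#'
#' Shared configuration for the SMILES autoencoder and the spectral
#' encoder. The two components must agree on `latent_dim`: the autoencoder
#' defines the chemical latent space and the spectral encoder is trained to
#' land in it. Defaults are desk-scale: they train on a CPU in minutes on
#' synthetic libraries of a few hundred molecules.
#'
#' @param latent_dim dimension of the shared chemical latent space.
#' @param emb_dim SMILES token embedding dimension.
#' @param gru_hidden GRU hidden width (encoder and decoder).
#' @param gru_layers number of GRU layers (1 supported).
#' @param attn_layers number of attention layers in the spectral encoder.
#' @param attn_heads attention heads.
#' @param cnn_kernel_sizes kernel lengths of the convolutional feature bank
#'   (default the 11 odd sizes 1, 3, ..., 21).
#' @param cnn_channels output channels per kernel.
#' @param spec_emb_dim spectral token embedding dimension.
#' @param vocab_size_spectrum spectrum vocabulary size: 100001 m/z tokens
#'   (0.01-Da bins over 0..1000 Da) plus specials.
#' @param rope_scale scale mapping normalized intensity in \[0,1\] to a
#'   rotary position value.
#' @param max_smiles_len maximum SMILES token length.
#' @param max_spectrum_len maximum spectrum sequence length.
#' @param seed integer seed recorded with the config.
#' @return a list of class `model_config`.
#' @export
model_config <- function(latent_dim = 64L, emb_dim = 64L, gru_hidden = 128L,
                         gru_layers = 1L, attn_layers = 2L, attn_heads = 4L,
                         cnn_kernel_sizes = seq(1L, 21L, by = 2L),
                         cnn_channels = 16L, spec_emb_dim = 64L,
                         vocab_size_spectrum = 100003L, rope_scale = 100,
                         max_smiles_len = 110L, max_spectrum_len = 256L,
                         seed = 1L) {
  stopifnot(latent_dim > 0, gru_layers == 1L,
            spec_emb_dim %% (2L * attn_heads) == 0L)
  cfg <- list(latent_dim = as.integer(latent_dim),
              emb_dim = as.integer(emb_dim),
              gru_hidden = as.integer(gru_hidden),
              gru_layers = 1L,
              attn_layers = as.integer(attn_layers),
              attn_heads = as.integer(attn_heads),
              cnn_layers = length(cnn_kernel_sizes),
              cnn_kernel_sizes = as.integer(cnn_kernel_sizes),
              cnn_channels = as.integer(cnn_channels),
              spec_emb_dim = as.integer(spec_emb_dim),
              vocab_size_spectrum = as.integer(vocab_size_spectrum),
              rope_scale = rope_scale,
              max_smiles_len = as.integer(max_smiles_len),
              max_spectrum_len = as.integer(max_spectrum_len),
              seed = as.integer(seed))
  class(cfg) <- "model_config"
  cfg
}

# special SMILES token ids
.PAD_ID <- 1L
.SOS_ID <- 2L
.EOS_ID <- 3L

#' Build a SMILES token vocabulary from a molecule library
#'
#' @param records list of `molecule_record`.
#' @return named integer vector mapping token to id (ids 1..3 are the
#'   PAD/SOS/EOS specials).
#' @export
smiles_vocab <- function(records) {
  toks <- sort(unique(unlist(lapply(records, `[[`, "smiles_tokens"))))
  ids <- seq_along(toks) + 3L
  names(ids) <- toks
  c("<pad>" = .PAD_ID, "<sos>" = .SOS_ID, "<eos>" = .EOS_ID, ids)
}

.tokens_to_ids <- function(tokens, vocab, max_len = 110L) {
  if (length(tokens) > max_len)
    stop("length: token sequence longer than ", max_len, call. = FALSE)
  ids <- unname(vocab[tokens])
  if (any(is.na(ids)))
    stop("vocab: unknown SMILES token(s): ",
         paste(unique(tokens[is.na(ids)]), collapse = " "), call. = FALSE)
  as.integer(ids)
}

.init_ae_params <- function(cfg, vocab_size) {
  De <- cfg$emb_dim; H <- cfg$gru_hidden; L <- cfg$latent_dim
  V <- vocab_size
  list(Emb = .nn_init(V, De, 0.1),
       enc = gru_params(De, H),
       Wl = .nn_init(H, L), bl = rep(0, L),
       W0 = .nn_init(L, H), b0 = rep(0, H),
       dec = gru_params(De + L, H),
       Wo = .nn_init(H, V), bo = rep(0, V))
}

# pad a list of id vectors into a B x T matrix (PAD right)
.pad_ids <- function(id_list) {
  Tn <- max(vapply(id_list, length, integer(1)))
  B <- length(id_list)
  M <- matrix(.PAD_ID, B, Tn)
  for (i in seq_len(B)) M[i, seq_along(id_list[[i]])] <- id_list[[i]]
  M
}

# forward + loss + (optionally) gradients for one batch
# Xin: B x Tin input ids; Ytgt: B x Tout target ids (ending in EOS, padded)
.ae_batch <- function(p, Xin, Ytgt, cfg, want_grads = TRUE) {
  B <- nrow(Xin); Tin <- ncol(Xin); Tout <- ncol(Ytgt)
  De <- cfg$emb_dim; H <- cfg$gru_hidden; L <- cfg$latent_dim
  mask_in <- (Xin != .PAD_ID) * 1
  mask_out <- (Ytgt != .PAD_ID) * 1
  Xemb <- lapply(seq_len(Tin), function(t) p$Emb[Xin[, t], , drop = FALSE])
  h0 <- matrix(0, B, H)
  enc <- gru_forward(Xemb, h0, p$enc, mask_in, keep_cache = want_grads)
  Z <- enc$h %*% p$Wl + matrix(p$bl, B, L, byrow = TRUE)
  h0d_pre <- Z %*% p$W0 + matrix(p$b0, B, H, byrow = TRUE)
  h0d <- tanh(h0d_pre)
  prev <- cbind(rep(.SOS_ID, B), Ytgt[, -Tout, drop = FALSE])
  Xdec <- lapply(seq_len(Tout), function(t)
    cbind(p$Emb[prev[, t], , drop = FALSE], Z))
  dec <- gru_forward(Xdec, h0d, p$dec, mask_out, keep_cache = want_grads)
  loss <- 0; n_eff <- 0
  dh_steps <- if (want_grads) vector("list", Tout) else NULL
  gWo <- if (want_grads) 0 * p$Wo else NULL
  gbo <- if (want_grads) 0 * p$bo else NULL
  for (t in seq_len(Tout)) {
    ht <- dec$hs[[t]]
    logits <- ht %*% p$Wo + matrix(p$bo, B, length(p$bo), byrow = TRUE)
    sx <- softmax_xent(logits, Ytgt[, t], mask_out[, t])
    loss <- loss + sx$loss; n_eff <- n_eff + sx$n_eff
    if (want_grads) {
      dh_steps[[t]] <- sx$dlogits %*% t(p$Wo)
      gWo <- gWo + t(ht) %*% sx$dlogits
      gbo <- gbo + colSums(sx$dlogits)
    }
  }
  mean_loss <- loss / max(n_eff, 1)
  if (!want_grads) return(list(loss = mean_loss))
  scale <- 1 / max(n_eff, 1)
  gWo <- gWo * scale; gbo <- gbo * scale
  dh_steps <- lapply(dh_steps, function(d) d * scale)
  decb <- gru_backward(dec$cache, p$dec, dh_steps, matrix(0, B, H))
  # split decoder input grads into embedding part and latent part
  dZ <- matrix(0, B, L)
  emb_ids <- integer(0); emb_gr <- NULL
  dEmb_acc <- list()
  for (t in seq_len(Tout)) {
    dxt <- decb$dX[[t]]
    dEmb_acc[[t]] <- list(ids = prev[, t], g = dxt[, seq_len(De), drop = FALSE])
    dZ <- dZ + dxt[, De + seq_len(L), drop = FALSE]
  }
  dh0d <- decb$dh0
  dpre <- dh0d * (1 - h0d * h0d)
  gW0 <- t(Z) %*% dpre; gb0 <- colSums(dpre)
  dZ <- dZ + dpre %*% t(p$W0)
  gWl <- t(enc$h) %*% dZ; gbl <- colSums(dZ)
  dhT <- dZ %*% t(p$Wl)
  encb <- gru_backward(enc$cache, p$enc, NULL, dhT)
  for (t in seq_len(Tin))
    dEmb_acc[[Tout + t]] <- list(ids = Xin[, t], g = encb$dX[[t]])
  all_ids <- unlist(lapply(dEmb_acc, `[[`, "ids"))
  all_g <- do.call(rbind, lapply(dEmb_acc, `[[`, "g"))
  eg <- rowsum(all_g, group = all_ids)
  gEmb <- 0 * p$Emb
  gEmb[as.integer(rownames(eg)), ] <- eg
  gEmb[.PAD_ID, ] <- 0
  list(loss = mean_loss,
       grads = list(Emb = gEmb, enc = encb$grads,
                    Wl = gWl, bl = gbl, W0 = gW0, b0 = gb0,
                    dec = decb$grads, Wo = gWo, bo = gbo))
}

# flatten nested param list (enc/dec sublists) for the optimizer
.flatten_params <- function(p) {
  out <- list()
  for (nm in names(p)) {
    if (is.list(p[[nm]])) {
      for (nm2 in names(p[[nm]])) out[[paste0(nm, ".", nm2)]] <- p[[nm]][[nm2]]
    } else out[[nm]] <- p[[nm]]
  }
  out
}

.unflatten_params <- function(flat, template) {
  p <- template
  for (nm in names(flat)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) == 2L) p[[parts[1]]][[parts[2]]] <- flat[[nm]]
    else p[[nm]] <- flat[[nm]]
  }
  p
}

#' Project a molecule into the chemical latent space
#'
#' Deterministic inference-mode encoding of a SMILES token sequence with a
#' trained autoencoder.
#'
#' @param x a `molecule_record`, a SMILES string, or a character vector of
#'   SMILES tokens.
#' @param ae a trained `smiles_ae`.
#' @return numeric vector of length `latent_dim`.
#' @export
encode_molecule <- function(x, ae) {
  stopifnot(inherits(ae, "smiles_ae"))
  tokens <- if (inherits(x, "molecule_record")) x$smiles_tokens
            else if (is.character(x) && length(x) == 1L) tokenize_smiles(x)
            else x
  ids <- .tokens_to_ids(tokens, ae$vocab, ae$config$max_smiles_len)
  p <- ae$params; cfg <- ae$config
  X <- matrix(ids, nrow = 1)
  Xemb <- lapply(seq_along(ids), function(t) p$Emb[X[, t], , drop = FALSE])
  enc <- gru_forward(Xemb, matrix(0, 1, cfg$gru_hidden), p$enc,
                     matrix(1, 1, length(ids)), keep_cache = FALSE)
  as.numeric(enc$h %*% p$Wl + p$bl)
}

#' Greedy-decode a latent code back to SMILES tokens
#'
#' Emits tokens greedily until the end token or 110 tokens. The output is a
#' token sequence; validity of the corresponding SMILES is measured, not
#' guaranteed.
#'
#' @param code numeric vector of length `latent_dim`.
#' @param ae a trained `smiles_ae`.
#' @return character vector of SMILES tokens (possibly empty).
#' @export
decode_molecule <- function(code, ae) {
  stopifnot(inherits(ae, "smiles_ae"))
  cfg <- ae$config; p <- ae$params
  if (length(code) != cfg$latent_dim)
    stop("shape: latent code has wrong length", call. = FALSE)
  Z <- matrix(code, nrow = 1)
  h <- tanh(Z %*% p$W0 + matrix(p$b0, 1, cfg$gru_hidden, byrow = TRUE))
  prev <- .SOS_ID
  out <- integer(0)
  inv <- names(ae$vocab)
  for (t in seq_len(cfg$max_smiles_len)) {
    xt <- cbind(p$Emb[prev, , drop = FALSE], Z)
    st <- gru_forward(list(xt), h, p$dec, matrix(1, 1, 1), keep_cache = FALSE)
    h <- st$h
    logits <- h %*% p$Wo + matrix(p$bo, 1, length(p$bo), byrow = TRUE)
    nxt <- which.max(logits[1, ])
    if (nxt == .EOS_ID) break
    out <- c(out, nxt)
    prev <- nxt
  }
  inv[out]
}

#' @export
print.smiles_ae <- function(x, ...) {
  cat("<smiles_ae> vocab", length(x$vocab), "tokens; latent",
      x$config$latent_dim, "; hidden", x$config$gru_hidden, "\n")
  if (length(x$history$train_loss) > 0L)
    cat(sprintf("  trained %d epochs; final loss %.4f\n",
                length(x$history$train_loss),
                utils::tail(x$history$train_loss, 1)))
  invisible(x)
}
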