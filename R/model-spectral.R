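#' Intensity-modulated rotary encoding
#'
#' Standard rotary positional encoding with the integer position index
#' replaced by `intensity * rope_scale`: query/key vectors are rotated,
#' per 2-D feature pair, by angles proportional to the peak's normalized
#' intensity. Rotation preserves norms, and the pre-softmax interaction
#' between two tokens depends only on their intensity difference, which
#' encodes relative intensity structure without imposing a sequence order.
#'
#' @param q_or_k numeric matrix (sequence length x feature dim, even dim).
#' @param intensities numeric vector in \[0,1\], one per row.
#' @param rope_scale scale mapping intensity to a position value.
#' @param invert rotate by the negated angles (used in backpropagation).
#' @return rotated matrix of the same shape.
#' @export
intensity_rope <- function(q_or_k, intensities, rope_scale = 100,
                           invert = FALSE) {
  D <- ncol(q_or_k)
  if (D %% 2L != 0L) stop("shape: feature dimension must be even", call. = FALSE)
  if (length(intensities) != nrow(q_or_k))
    stop("shape: one intensity per sequence position", call. = FALSE)
  half <- D %/% 2L
  omega <- 10000^(-(2 * (seq_len(half) - 1)) / D)
  ang <- outer(intensities * rope_scale, omega)
  if (invert) ang <- -ang
  co <- cos(ang); si <- sin(ang)
  odd <- seq(1L, D, by = 2L); even <- seq(2L, D, by = 2L)
  x1 <- q_or_k[, odd, drop = FALSE]; x2 <- q_or_k[, even, drop = FALSE]
  out <- q_or_k
  out[, odd] <- x1 * co - x2 * si
  out[, even] <- x1 * si + x2 * co
  out
}

# spectrum token id -> embedding row (tokens 0..100000 -> rows 1..100001);
# the last vocabulary row is reserved for padding
.spec_row <- function(token) as.integer(token) + 1L
.spec_pad_row <- function(cfg) cfg$vocab_size_spectrum

.init_spec_params <- function(cfg) {
  D <- cfg$spec_emb_dim
  p <- list(
    EmbS = matrix(stats::rnorm(cfg$vocab_size_spectrum * D, 0, 0.05),
                  cfg$vocab_size_spectrum, D),
    Seg = .nn_init(2L, D, 0.05),
    layers = lapply(seq_len(cfg$attn_layers), function(l) list(
      Wq = .nn_init(D, D), Wk = .nn_init(D, D), Wv = .nn_init(D, D),
      Wo = .nn_init(D, D), gamma = rep(1, D), beta = rep(0, D))),
    conv = lapply(cfg$cnn_kernel_sizes, function(k) list(
      W = .nn_init(k * cfg$attn_layers * D, cfg$cnn_channels),
      b = rep(0, cfg$cnn_channels))),
    Whd = .nn_init(cfg$cnn_layers * cfg$cnn_channels, cfg$latent_dim),
    bhd = rep(0, cfg$latent_dim))
  p$EmbS[.spec_pad_row(cfg), ] <- 0
  p
}

# pack a list of tokenized_spectrum into padded batch matrices
.spec_pack <- function(specs, cfg) {
  lens <- vapply(specs, function(s) length(s$tokens), integer(1))
  stopifnot(all(lens >= 1L))
  if (any(lens > cfg$max_spectrum_len))
    stop("length: spectrum sequence longer than max_spectrum_len",
         call. = FALSE)
  B <- length(specs); Tn <- max(lens)
  ids <- matrix(.spec_pad_row(cfg), B, Tn)
  intens <- matrix(0, B, Tn)
  seg <- matrix(1L, B, Tn)
  for (i in seq_len(B)) {
    s <- specs[[i]]
    if (length(s$tokens) != length(s$intensities) ||
        length(s$tokens) != length(s$segment_flags))
      stop("shape: misaligned token/intensity/segment sequences",
           call. = FALSE)
    idx <- seq_len(lens[i])
    ids[i, idx] <- .spec_row(s$tokens)
    intens[i, idx] <- s$intensities
    seg[i, idx] <- ifelse(s$segment_flags == "loss", 2L, 1L)
  }
  mask <- matrix(0, B, Tn)
  for (i in seq_len(B)) mask[i, seq_len(lens[i])] <- 1
  list(ids = ids, intens = intens, seg = seg, mask = mask, B = B, Tn = Tn)
}

# forward (+ backward) pass over one batch; batch = list of
# list(spectrum=tokenized_spectrum, target=latent vector) when training,
# or packed spectra only at inference (targets NULL)
.spec_batch <- function(p, batch, cfg, want_grads = TRUE) {
  specs <- lapply(batch, function(x) if (!is.null(x$spectrum)) x$spectrum else x)
  targets <- if (!is.null(batch[[1]]$target))
    do.call(rbind, lapply(batch, `[[`, "target")) else NULL
  pk <- .spec_pack(specs, cfg)
  B <- pk$B; Tn <- pk$Tn
  D <- cfg$spec_emb_dim; nh <- cfg$attn_heads; dh <- D %/% nh
  nl <- cfg$attn_layers
  idvec <- as.integer(t(pk$ids))          # row-major: item-by-item blocks
  segvec <- as.integer(t(pk$seg))
  maskvec <- as.numeric(t(pk$mask))
  BT <- B * Tn
  X <- (p$EmbS[idvec, , drop = FALSE] + p$Seg[segvec, , drop = FALSE]) * maskvec
  rows_of <- function(b) ((b - 1L) * Tn + 1L):(b * Tn)
  scl <- 1 / sqrt(dh)
  caches <- vector("list", nl)
  Ys <- vector("list", nl)
  for (l in seq_len(nl)) {
    lay <- p$layers[[l]]
    ln <- layernorm_forward(X, lay$gamma, lay$beta)
    Q <- ln$Y %*% lay$Wq; K <- ln$Y %*% lay$Wk; V <- ln$Y %*% lay$Wv
    AO <- matrix(0, BT, D)
    att <- vector("list", B)
    for (b in seq_len(B)) {
      rb <- rows_of(b)
      ints_b <- pk$intens[b, ]
      mb <- pk$mask[b, ] == 1
      att_b <- vector("list", nh)
      for (h in seq_len(nh)) {
        ch <- ((h - 1L) * dh + 1L):(h * dh)
        Qr <- intensity_rope(Q[rb, ch, drop = FALSE], ints_b, cfg$rope_scale)
        Kr <- intensity_rope(K[rb, ch, drop = FALSE], ints_b, cfg$rope_scale)
        S <- (Qr %*% t(Kr)) * scl
        S[, !mb] <- -Inf
        A <- exp(S - apply(S, 1, max))
        A <- A / rowSums(A)
        AO[rb, ch] <- A %*% V[rb, ch, drop = FALSE]
        att_b[[h]] <- if (want_grads) list(A = A, Qr = Qr, Kr = Kr) else NULL
      }
      att[[b]] <- att_b
    }
    O <- AO %*% lay$Wo
    Y <- (X + O) * maskvec
    caches[[l]] <- if (want_grads) list(ln = ln, Q = Q, K = K, V = V,
                                        AO = AO, att = att, Xin = X) else NULL
    Ys[[l]] <- Y
    X <- Y
  }
  M <- do.call(cbind, Ys)                  # BT x (nl*D)
  Cmap <- ncol(M)
  Mpad <- rbind(M, rep(0, Cmap))           # virtual zero row for shifts
  Cc <- cfg$cnn_channels
  P <- matrix(0, B, cfg$cnn_layers * Cc)
  conv_cache <- vector("list", cfg$cnn_layers)
  tvec <- rep(seq_len(Tn), times = B)      # position within item per row
  for (ki in seq_along(cfg$cnn_kernel_sizes)) {
    k <- cfg$cnn_kernel_sizes[ki]
    halfk <- k %/% 2L
    offs <- (-halfk):(halfk)
    idx_mat <- matrix(0L, BT, k)
    for (oi in seq_along(offs)) {
      tt <- tvec + offs[oi]
      valid <- tt >= 1L & tt <= Tn
      idx <- ifelse(valid, seq_len(BT) + offs[oi], BT + 1L)
      idx_mat[, oi] <- idx
    }
    Xcol <- matrix(0, BT, k * Cmap)
    for (oi in seq_len(k))
      Xcol[, ((oi - 1L) * Cmap + 1L):(oi * Cmap)] <- Mpad[idx_mat[, oi], ]
    pre <- Xcol %*% p$conv[[ki]]$W +
      matrix(p$conv[[ki]]$b, BT, Cc, byrow = TRUE)
    act <- pmax(pre, 0)
    act_eff <- act
    act_eff[maskvec == 0, ] <- -Inf
    arg <- matrix(0L, B, Cc)
    for (b in seq_len(B)) {
      rb <- rows_of(b)
      sub <- act_eff[rb, , drop = FALSE]
      am <- max.col(t(sub), ties.method = "first")
      arg[b, ] <- rb[am]
      P[b, (ki - 1L) * Cc + seq_len(Cc)] <- sub[cbind(am, seq_len(Cc))]
    }
    conv_cache[[ki]] <- if (want_grads) list(Xcol = Xcol, pre = pre,
                                             idx_mat = idx_mat, arg = arg)
                        else NULL
  }
  out <- P %*% p$Whd + matrix(p$bhd, B, cfg$latent_dim, byrow = TRUE)
  if (is.null(targets)) return(list(out = out))
  diff <- out - targets
  loss <- mean(diff * diff)
  if (!want_grads) return(list(out = out, loss = loss))

  # ---- backward ----
  dout <- 2 * diff / length(diff)
  gWhd <- t(P) %*% dout
  gbhd <- colSums(dout)
  dP <- dout %*% t(p$Whd)
  dM <- matrix(0, BT + 1L, Cmap)
  gconv <- vector("list", cfg$cnn_layers)
  for (ki in seq_along(cfg$cnn_kernel_sizes)) {
    k <- cfg$cnn_kernel_sizes[ki]
    cc <- conv_cache[[ki]]
    Cc_idx <- (ki - 1L) * Cc + seq_len(Cc)
    dact <- matrix(0, BT, Cc)
    for (b in seq_len(B))
      dact[cbind(cc$arg[b, ], seq_len(Cc))] <-
        dact[cbind(cc$arg[b, ], seq_len(Cc))] + dP[b, Cc_idx]
    dpre <- dact * (cc$pre > 0)
    gconv[[ki]] <- list(W = t(cc$Xcol) %*% dpre, b = colSums(dpre))
    dXcol <- dpre %*% t(p$conv[[ki]]$W)
    for (oi in seq_len(k)) {
      blk <- dXcol[, ((oi - 1L) * Cmap + 1L):(oi * Cmap), drop = FALSE]
      tgt_rows <- cc$idx_mat[, oi]
      agg <- rowsum(blk, group = tgt_rows)
      dM[as.integer(rownames(agg)), ] <- dM[as.integer(rownames(agg)), ] + agg
    }
  }
  dM <- dM[seq_len(BT), , drop = FALSE]
  dYs <- lapply(seq_len(nl), function(l)
    dM[, ((l - 1L) * D + 1L):(l * D), drop = FALSE])
  glayers <- vector("list", nl)
  carry <- matrix(0, BT, D)
  for (l in rev(seq_len(nl))) {
    lay <- p$layers[[l]]; cc <- caches[[l]]
    dY <- (dYs[[l]] + carry) * maskvec
    dO <- dY
    gWo <- t(cc$AO) %*% dO
    dAO <- dO %*% t(lay$Wo)
    dQ <- matrix(0, BT, D); dK <- matrix(0, BT, D); dV <- matrix(0, BT, D)
    for (b in seq_len(B)) {
      rb <- rows_of(b)
      ints_b <- pk$intens[b, ]
      for (h in seq_len(nh)) {
        ch <- ((h - 1L) * dh + 1L):(h * dh)
        ab <- cc$att[[b]][[h]]
        dout_bh <- dAO[rb, ch, drop = FALSE]
        dA <- dout_bh %*% t(cc$V[rb, ch, drop = FALSE])
        dV[rb, ch] <- t(ab$A) %*% dout_bh
        dS <- ab$A * (dA - rowSums(dA * ab$A))
        dQr <- (dS %*% ab$Kr) * scl
        dKr <- (t(dS) %*% ab$Qr) * scl
        dQ[rb, ch] <- intensity_rope(dQr, ints_b, cfg$rope_scale, invert = TRUE)
        dK[rb, ch] <- intensity_rope(dKr, ints_b, cfg$rope_scale, invert = TRUE)
      }
    }
    gWq <- t(cc$ln$Y) %*% dQ
    gWk <- t(cc$ln$Y) %*% dK
    gWv <- t(cc$ln$Y) %*% dV
    dln <- dQ %*% t(lay$Wq) + dK %*% t(lay$Wk) + dV %*% t(lay$Wv)
    lnb <- layernorm_backward(dln, cc$ln, lay$gamma)
    glayers[[l]] <- list(Wq = gWq, Wk = gWk, Wv = gWv, Wo = gWo,
                         gamma = lnb$dgamma, beta = lnb$dbeta)
    carry <- dY + lnb$dX
  }
  dX0 <- carry * maskvec
  eg <- rowsum(dX0, group = idvec)
  emb_rows <- as.integer(rownames(eg))
  keep <- emb_rows != .spec_pad_row(cfg)
  sg <- rowsum(dX0, group = segvec)
  gSeg <- 0 * p$Seg
  gSeg[as.integer(rownames(sg)), ] <- sg
  list(loss = loss, out = out,
       grads = list(emb_rows = emb_rows[keep],
                    emb_grad = eg[keep, , drop = FALSE],
                    Seg = gSeg, layers = glayers, conv = gconv,
                    Whd = gWhd, bhd = gbhd))
}

.spec_opt_state <- function(p) {
  dense <- .spec_dense_params(p)
  list(dense = adam_state(dense),
       emb = list(m = 0 * p$EmbS, v = 0 * p$EmbS, t = 0L),
       params = p)
}

.spec_dense_params <- function(p) {
  out <- list(Seg = p$Seg, Whd = p$Whd, bhd = p$bhd)
  for (l in seq_along(p$layers))
    for (nm in names(p$layers[[l]]))
      out[[sprintf("L%d.%s", l, nm)]] <- p$layers[[l]][[nm]]
  for (k in seq_along(p$conv))
    for (nm in names(p$conv[[k]]))
      out[[sprintf("C%d.%s", k, nm)]] <- p$conv[[k]][[nm]]
  out
}

.spec_adam <- function(p, grads, opt, lr) {
  gd <- list(Seg = grads$Seg, Whd = grads$Whd, bhd = grads$bhd)
  for (l in seq_along(grads$layers))
    for (nm in names(grads$layers[[l]]))
      gd[[sprintf("L%d.%s", l, nm)]] <- grads$layers[[l]][[nm]]
  for (k in seq_along(grads$conv))
    for (nm in names(grads$conv[[k]]))
      gd[[sprintf("C%d.%s", k, nm)]] <- grads$conv[[k]][[nm]]
  dense <- .spec_dense_params(p)
  upd <- adam_step(dense, gd, opt$dense, lr = lr)
  opt$dense <- upd$state
  dense <- upd$params
  p$Seg <- dense$Seg; p$Whd <- dense$Whd; p$bhd <- dense$bhd
  for (l in seq_along(p$layers))
    for (nm in names(p$layers[[l]]))
      p$layers[[l]][[nm]] <- dense[[sprintf("L%d.%s", l, nm)]]
  for (k in seq_along(p$conv))
    for (nm in names(p$conv[[k]]))
      p$conv[[k]][[nm]] <- dense[[sprintf("C%d.%s", k, nm)]]
  opt$emb$t <- opt$emb$t + 1L
  emb_upd <- adam_step_rows(p$EmbS, grads$emb_grad, grads$emb_rows,
                            opt$emb, lr = lr, t = opt$emb$t)
  p$EmbS <- emb_upd$W
  opt$emb$m <- emb_upd$state$m; opt$emb$v <- emb_upd$state$v
  opt$params <- p
  opt
}

#' Project a tokenized spectrum into the chemical latent space
#'
#' Deterministic inference-mode embedding E_s of a spectrum with a trained
#' spectral encoder; lives in the same space as the autoencoder's E_a.
#'
#' @param ts a `tokenized_spectrum` (or list of them).
#' @param encoder a trained `spectral_encoder`.
#' @return numeric vector of length `latent_dim` (or a matrix, one row per
#'   spectrum, for a list input).
#' @export
encode_spectrum <- function(ts, encoder) {
  stopifnot(inherits(encoder, "spectral_encoder"))
  single <- inherits(ts, "tokenized_spectrum")
  specs <- if (single) list(ts) else ts
  out <- matrix(0, length(specs), encoder$config$latent_dim)
  # batched inference in chunks to bound memory
  chunk <- 64L
  i <- 1L
  while (i <= length(specs)) {
    j <- min(i + chunk - 1L, length(specs))
    res <- .spec_batch(encoder$params, specs[i:j], encoder$config,
                       want_grads = FALSE)
    out[i:j, ] <- res$out
    i <- j + 1L
  }
  if (single) as.numeric(out[1, ]) else out
}
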