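#' Lightweight neural-network primitives
#'
#' Purpose-built, dependency-free building blocks for the two model
#' components: parameter initialization, a batched GRU cell with full
#' backpropagation-through-time, layer normalization, softmax
#' cross-entropy, and an Adam optimizer with sparse embedding updates.
#' Everything is plain double-precision matrix algebra so training is
#' deterministic for a fixed RNG stream.
#'
#' @name nn-core
#' @keywords internal
NULL

.nn_init <- function(nrow, ncol, scale = NULL) {
  if (is.null(scale)) scale <- sqrt(2 / (nrow + ncol))
  matrix(stats::rnorm(nrow * ncol, 0, scale), nrow, ncol)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- batched GRU ----------------------------------------------------------
# X: list over time of B x Din input matrices; mask: B x T (1 = real token)
# returns h_T and (optionally) per-step cache for BPTT
gru_forward <- function(X, h0, p, mask, keep_cache = TRUE) {
  Tn <- length(X)
  h <- h0
  cache <- if (keep_cache) vector("list", Tn) else NULL
  hs <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    xt <- X[[t]]
    z <- .sigmoid(xt %*% p$Wz + h %*% p$Uz +
                    matrix(p$bz, nrow(xt), length(p$bz), byrow = TRUE))
    r <- .sigmoid(xt %*% p$Wr + h %*% p$Ur +
                    matrix(p$br, nrow(xt), length(p$br), byrow = TRUE))
    hh <- tanh(xt %*% p$Wh + (r * h) %*% p$Uh +
                 matrix(p$bh, nrow(xt), length(p$bh), byrow = TRUE))
    hnew <- (1 - z) * h + z * hh
    m <- mask[, t]
    hout <- h + m * (hnew - h)
    if (keep_cache) cache[[t]] <- list(xt = xt, hprev = h, z = z, r = r,
                                       hh = hh, m = m)
    h <- hout
    hs[[t]] <- h
  }
  list(h = h, hs = hs, cache = cache)
}

# dh_steps: list over time of B x H grads flowing into h_t from outside the
# recurrence (NULL allowed); dh_final: grad into the last hidden state
gru_backward <- function(cache, p, dh_steps, dh_final) {
  Tn <- length(cache)
  H <- ncol(p$Uz)
  g <- list(Wz = 0 * p$Wz, Wr = 0 * p$Wr, Wh = 0 * p$Wh,
            Uz = 0 * p$Uz, Ur = 0 * p$Ur, Uh = 0 * p$Uh,
            bz = 0 * p$bz, br = 0 * p$br, bh = 0 * p$bh)
  dh <- dh_final
  dX <- vector("list", Tn)
  for (t in rev(seq_len(Tn))) {
    cc <- cache[[t]]
    if (!is.null(dh_steps) && !is.null(dh_steps[[t]])) dh <- dh + dh_steps[[t]]
    m <- cc$m
    dh_cell <- dh * m          # grad through the updated state
    dh_skip <- dh * (1 - m)    # grad through the pass-through (padding)
    z <- cc$z; r <- cc$r; hh <- cc$hh; hprev <- cc$hprev; xt <- cc$xt
    dz <- dh_cell * (hh - hprev)
    dhh <- dh_cell * z
    dhprev <- dh_cell * (1 - z)
    dhh_pre <- dhh * (1 - hh * hh)
    drh <- dhh_pre %*% t(p$Uh)
    dr <- drh * hprev
    dhprev <- dhprev + drh * r
    dz_pre <- dz * z * (1 - z)
    dr_pre <- dr * r * (1 - r)
    g$Wz <- g$Wz + t(xt) %*% dz_pre
    g$Wr <- g$Wr + t(xt) %*% dr_pre
    g$Wh <- g$Wh + t(xt) %*% dhh_pre
    g$Uz <- g$Uz + t(hprev) %*% dz_pre
    g$Ur <- g$Ur + t(hprev) %*% dr_pre
    g$Uh <- g$Uh + t(r * hprev) %*% dhh_pre
    g$bz <- g$bz + colSums(dz_pre)
    g$br <- g$br + colSums(dr_pre)
    g$bh <- g$bh + colSums(dhh_pre)
    dX[[t]] <- dz_pre %*% t(p$Wz) + dr_pre %*% t(p$Wr) + dhh_pre %*% t(p$Wh)
    dhprev <- dhprev + dz_pre %*% t(p$Uz) + dr_pre %*% t(p$Ur)
    dh <- dh_skip + dhprev
  }
  list(grads = g, dX = dX, dh0 = dh)
}

gru_params <- function(din, H) {
  list(Wz = .nn_init(din, H), Wr = .nn_init(din, H), Wh = .nn_init(din, H),
       Uz = .nn_init(H, H), Ur = .nn_init(H, H), Uh = .nn_init(H, H),
       bz = rep(0, H), br = rep(0, H), bh = rep(0, H))
}

# ---- softmax cross-entropy ------------------------------------------------
# logits: N x V; target: integer vector length N; weight: length N
softmax_xent <- function(logits, target, weight = NULL) {
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  sm <- ex / rowSums(ex)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), target)
  nll <- -log(pmax(sm[idx], 1e-12))
  if (is.null(weight)) weight <- rep(1, n)
  loss <- sum(nll * weight)
  dlogits <- sm
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits * weight
  list(loss = loss, dlogits = dlogits, n_eff = sum(weight))
}

# ---- layer norm -----------------------------------------------------------
layernorm_forward <- function(X, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  Y <- xhat * matrix(gamma, nrow(X), ncol(X), byrow = TRUE) +
    matrix(beta, nrow(X), ncol(X), byrow = TRUE)
  list(Y = Y, xhat = xhat, istd = istd)
}

layernorm_backward <- function(dY, cache, gamma) {
  xhat <- cache$xhat; istd <- cache$istd
  D <- ncol(dY)
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * matrix(gamma, nrow(dY), D, byrow = TRUE)
  dx <- istd * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- Adam -----------------------------------------------------------------
adam_state <- function(params) {
  list(m = lapply(params, function(p) 0 * p),
       v = lapply(params, function(p) 0 * p),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# sparse Adam row update for embedding tables: rows not touched keep their
# moments (no decay applied), which is the standard "sparse Adam" treatment
adam_step_rows <- function(W, dW_rows, rows, state, lr = 1e-3, beta1 = 0.9,
                           beta2 = 0.999, eps = 1e-8, t = 1L) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  m <- state$m[rows, , drop = FALSE]
  v <- state$v[rows, , drop = FALSE]
  m <- beta1 * m + (1 - beta1) * dW_rows
  v <- beta2 * v + (1 - beta2) * dW_rows * dW_rows
  W[rows, ] <- W[rows, , drop = FALSE] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  state$m[rows, ] <- m
  state$v[rows, ] <- v
  list(W = W, state = state)
}

# accumulate embedding gradients by token row
embedding_grad <- function(ids, dX, vocab_rows) {
  agg <- rowsum(dX, group = ids)
  rows <- as.integer(rownames(agg))
  list(rows = rows, grad = agg)
}
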