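# Low-level network layers with hand-derived reverse-mode gradients.
# All layers return a forward value plus the cache needed by their backward
# companion; gradients are accumulated into an environment (`acc`) so a
# minibatch shares one set of gradient buffers.

LN_EPS <- 1e-5

# broadcast a length-d vector across the rows of an m x d matrix
.bcast <- function(v, m) rep(v, each = m)

ln_forward <- function(x, gamma, beta) {
  m <- nrow(x)
  mu <- rowMeans(x)
  xc <- x - mu
  s <- sqrt(rowMeans(xc * xc) + LN_EPS)
  xhat <- xc / s
  list(y = xhat * .bcast(gamma, m) + .bcast(beta, m), xhat = xhat, s = s)
}

# returns dx; adds dgamma/dbeta into acc under the given names
ln_backward <- function(dy, cache, gamma, acc, gname, bname) {
  m <- nrow(dy)
  xhat <- cache$xhat
  acc[[gname]] <- acc[[gname]] + colSums(dy * xhat)
  acc[[bname]] <- acc[[bname]] + colSums(dy)
  dxhat <- dy * .bcast(gamma, m)
  (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / cache$s
}

# row-wise feed-forward: ReLU(x W1 + b1) W2 + b2
rff_forward <- function(x, W1, b1, W2, b2) {
  m <- nrow(x)
  a <- x %*% W1 + .bcast(b1, m)
  hdn <- pmax(a, 0)
  list(y = hdn %*% W2 + .bcast(b2, m), x = x, a = a, hdn = hdn)
}

rff_backward <- function(dy, cache, W1, W2, acc, prefix) {
  acc[[paste0(prefix, "_W2")]] <- acc[[paste0(prefix, "_W2")]] +
    crossprod(cache$hdn, dy)
  acc[[paste0(prefix, "_b2")]] <- acc[[paste0(prefix, "_b2")]] + colSums(dy)
  dh <- dy %*% t(W2)
  da <- dh * (cache$a > 0)
  acc[[paste0(prefix, "_W1")]] <- acc[[paste0(prefix, "_W1")]] +
    crossprod(cache$x, da)
  acc[[paste0(prefix, "_b1")]] <- acc[[paste0(prefix, "_b1")]] + colSums(da)
  da %*% t(W1)
}

# Multi-head additive attention. Per head t with column block ct of width dh:
#   score z_ij = w_t . tanh(Q0 Wq[, ct]_i + K0 Wk[, ct]_j)
#   A_t = row-softmax(z), O_t = A_t (K0 Wv[, ct]); O = [O_1 ... O_h].
# Returns O (m x d), A (m x k x h array) and the backward cache.
# attn_forward/attn_backward run the compiled kernels; the _r versions are
# the plain-R reference implementation they are tested against.
attn_forward <- function(Q0, K0, Wq, Wk, Wv, w, heads) {
  out <- .attn_forward_cpp(Q0, K0, Wq, Wk, Wv, w, heads)
  out$Q0 <- Q0
  out$K0 <- K0
  out
}

attn_backward <- function(dO, dA_extra, cache, Wq, Wk, Wv, w, heads,
                          acc, prefix) {
  g <- .attn_backward_cpp(dO, dA_extra, cache$A, cache$Qp, cache$Kp,
                          cache$Vp, cache$W_big, cache$Q0, cache$K0,
                          Wq, Wk, Wv, heads)
  acc[[paste0(prefix, "_w")]] <- acc[[paste0(prefix, "_w")]] + g$dw
  acc[[paste0(prefix, "_Wq")]] <- acc[[paste0(prefix, "_Wq")]] + g$dWq
  acc[[paste0(prefix, "_Wk")]] <- acc[[paste0(prefix, "_Wk")]] + g$dWk
  acc[[paste0(prefix, "_Wv")]] <- acc[[paste0(prefix, "_Wv")]] + g$dWv
  list(dQ0 = g$dQ0, dK0 = g$dK0)
}

attn_forward_r <- function(Q0, K0, Wq, Wk, Wv, w, heads) {
  m <- nrow(Q0); k <- nrow(K0); d <- ncol(Wq); dh <- d %/% heads
  Qp <- Q0 %*% Wq
  Kp <- K0 %*% Wk
  Vp <- K0 %*% Wv
  iq <- rep(seq_len(m), times = k)
  ik <- rep(seq_len(k), each = m)
  Tm <- tanh(Qp[iq, , drop = FALSE] + Kp[ik, , drop = FALSE])
  # all head scores in one matmul: W_big has w[, t] in rows of block t
  W_big <- matrix(0, d, heads)
  for (t in seq_len(heads))
    W_big[((t - 1L) * dh + 1L):(t * dh), t] <- w[, t]
  Z <- Tm %*% W_big                     # (m*k) x heads
  Z <- exp(Z - max(Z))                  # scores are bounded: |z| <= ||w||_1
  A <- array(0, dim = c(m, k, heads))
  O <- matrix(0, m, d)
  for (t in seq_len(heads)) {
    ez <- matrix(Z[, t], m, k)
    At <- ez / rowSums(ez)
    A[, , t] <- At
    ct <- ((t - 1L) * dh + 1L):(t * dh)
    O[, ct] <- At %*% Vp[, ct, drop = FALSE]
  }
  list(O = O, A = A, Tm = Tm, Qp = Qp, Kp = Kp, Vp = Vp, W_big = W_big,
       Q0 = Q0, K0 = K0, iq = iq, ik = ik, m = m, k = k, dh = dh)
}

# dO: m x d upstream gradient of the concatenated head outputs.
# dA_extra: optional m x k x h gradient flowing directly into the attention
# weights (the attention-regularization loss path). Returns dQ0 and dK0 and
# accumulates parameter gradients under `prefix`.
attn_backward_r <- function(dO, dA_extra, cache, Wq, Wk, Wv, w, heads,
                          acc, prefix) {
  m <- cache$m; k <- cache$k; dh <- cache$dh
  Tm <- cache$Tm; Vp <- cache$Vp
  dZ <- matrix(0, m * k, heads)
  dVp <- matrix(0, k, heads * dh)
  for (t in seq_len(heads)) {
    ct <- ((t - 1L) * dh + 1L):(t * dh)
    At <- cache$A[, , t]
    if (m == 1L) At <- matrix(At, 1L, k)
    dOt <- dO[, ct, drop = FALSE]
    dAt <- tcrossprod(dOt, Vp[, ct, drop = FALSE])
    if (!is.null(dA_extra)) dAt <- dAt + dA_extra[, , t]
    dVp[, ct] <- crossprod(At, dOt)
    dz <- At * (dAt - rowSums(At * dAt))          # softmax backward
    dZ[, t] <- dz                                 # (m*k), i-fastest
  }
  dwfull <- crossprod(Tm, dZ)                     # d x heads
  dw <- matrix(0, dh, heads)
  for (t in seq_len(heads))
    dw[, t] <- dwfull[((t - 1L) * dh + 1L):(t * dh), t]
  acc[[paste0(prefix, "_w")]] <- acc[[paste0(prefix, "_w")]] + dw
  dT <- tcrossprod(dZ, cache$W_big)               # (m*k) x d
  dT <- dT * (1 - Tm * Tm)                        # tanh backward
  dQp <- rowsum(dT, group = cache$iq, reorder = TRUE)
  dKp <- rowsum(dT, group = cache$ik, reorder = TRUE)
  acc[[paste0(prefix, "_Wq")]] <- acc[[paste0(prefix, "_Wq")]] +
    crossprod(cache$Q0, dQp)
  acc[[paste0(prefix, "_Wk")]] <- acc[[paste0(prefix, "_Wk")]] +
    crossprod(cache$K0, dKp)
  acc[[paste0(prefix, "_Wv")]] <- acc[[paste0(prefix, "_Wv")]] +
    crossprod(cache$K0, dVp)
  list(dQ0 = tcrossprod(dQp, Wq),
       dK0 = tcrossprod(dKp, Wk) + tcrossprod(dVp, Wv))
}

# fixed sinusoidal positional features (memoized per (m, d))
.pos_cache <- new.env(parent = emptyenv())
pos_encoding <- function(m, d) {
  key <- paste0(m, "_", d)
  if (!is.null(.pos_cache[[key]])) return(.pos_cache[[key]])
  pos <- seq_len(m)
  pe <- matrix(0, m, d)
  for (j in seq_len(ceiling(d / 2))) {
    freq <- 1 / 10000^((2 * (j - 1)) / d)
    pe[, 2L * j - 1L] <- sin(pos * freq)
    if (2L * j <= d) pe[, 2L * j] <- cos(pos * freq)
  }
  pe <- 0.1 * pe   # keep positional features small relative to embeddings
  .pos_cache[[key]] <- pe
  pe
}
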