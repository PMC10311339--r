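# Model parameters, single-instance forward pass, and its exact reverse-mode
# backward pass. The architecture: residue embeddings R attend (multi-head
# additive attention) over the ligand's substructure embeddings S augmented
# with one trainable pseudo-substructure row appended LAST; the refined
# residues are pooled by attention from u trainable seed vectors (PMA) into a
# single complex embedding, which a two-layer MLP maps to the predicted
# log-affinity.

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' @keywords internal
init_params <- function(cfg) {
  d <- cfg$d; r <- cfg$rff_hidden_dim; u <- cfg$u
  dh <- cfg$dh; h <- cfg$heads
  p <- list(
    E_res = matrix(stats::rnorm(21L * d, sd = 0.2), 21L, d),
    E_sub = matrix(stats::rnorm(cfg$vocab_size * d, sd = 0.2),
                   cfg$vocab_size, d),
    pseudo = stats::rnorm(d, sd = 0.2),
    mab_Wq = glorot(d, d), mab_Wk = glorot(d, d), mab_Wv = glorot(d, d),
    mab_w = glorot(dh, h),
    rff1_W1 = glorot(d, r), rff1_b1 = numeric(r),
    rff1_W2 = glorot(r, d), rff1_b2 = numeric(d),
    rff2_W1 = glorot(d, r), rff2_b1 = numeric(r),
    rff2_W2 = glorot(r, d), rff2_b2 = numeric(d),
    ln1_g = rep(1, d), ln1_b = numeric(d),
    ln2_g = rep(1, d), ln2_b = numeric(d),
    seeds = matrix(stats::rnorm(u * d, sd = 0.2), u, d),
    pma_Wq = glorot(d, d), pma_Wk = glorot(d, d), pma_Wv = glorot(d, d),
    pma_w = glorot(dh, h),
    rff3_W1 = glorot(d, r), rff3_b1 = numeric(r),
    rff3_W2 = glorot(r, d), rff3_b2 = numeric(d),
    ln3_g = rep(1, d), ln3_b = numeric(d),
    ln4_g = rep(1, d), ln4_b = numeric(d),
    lin_W = glorot(u * d, d), lin_b = numeric(d),
    mlp_W1 = glorot(d, d), mlp_b1 = numeric(d),
    mlp_W2 = glorot(d, 1L), mlp_b2 = 0
  )
  p
}

#' Construct an attention map
#'
#' @param per_head `h x m x (n+1)` array of per-head attention weights.
#' @param residue_ids optional length-`m` labels (amino-acid letters).
#' @param substructure_indices the `n` fingerprint bit indices (0-based)
#'   behind columns `1..n`; the last column is always the pseudo key.
#' @return object of class `"attention_map"` with head-averaged `weights`
#'   (`m x (n+1)`), the `per_head` array, and `pseudo_column = n + 1`.
#' @export
attention_map <- function(per_head, residue_ids = NULL,
                          substructure_indices = NULL) {
  stopifnot(length(dim(per_head)) == 3L)
  h <- dim(per_head)[1L]
  weights <- colMeans(per_head)            # arithmetic mean over heads
  if (is.null(dim(weights)))
    weights <- matrix(weights, dim(per_head)[2L], dim(per_head)[3L])
  m <- structure(list(weights = weights, per_head = per_head,
                      residue_ids = residue_ids,
                      substructure_indices = substructure_indices,
                      pseudo_column = ncol(weights)),
                 class = "attention_map")
  m
}

#' @export
print.attention_map <- function(x, ...) {
  cat(sprintf("attention map: %d residues x %d keys (%d substructures + pseudo), %d heads\n",
              nrow(x$weights), ncol(x$weights), ncol(x$weights) - 1L,
              dim(x$per_head)[1L]))
  cat(sprintf("  mean pseudo weight: %.3f\n",
              mean(x$weights[, x$pseudo_column])))
  invisible(x)
}

# ARK-MAB block: cross-attention from residues to substructures + pseudo,
# with the configured residual wiring. Returns Rstar plus the full cache.
.arkmab_fwd <- function(par, cfg, R0, Splus) {
  att <- attn_forward(R0, Splus, par$mab_Wq, par$mab_Wk, par$mab_Wv,
                      par$mab_w, cfg$heads)
  if (cfg$strict_eq7) {
    f1 <- rff_forward(att$O, par$rff1_W1, par$rff1_b1,
                      par$rff1_W2, par$rff1_b2)
    l1 <- ln_forward(R0 + f1$y, par$ln1_g, par$ln1_b)
    f2 <- rff_forward(R0, par$rff2_W1, par$rff2_b1,
                      par$rff2_W2, par$rff2_b2)
    l2 <- ln_forward(l1$y + f2$y, par$ln2_g, par$ln2_b)
  } else {
    l1 <- ln_forward(R0 + att$O, par$ln1_g, par$ln1_b)
    f1 <- rff_forward(l1$y, par$rff1_W1, par$rff1_b1,
                      par$rff1_W2, par$rff1_b2)
    f2 <- NULL
    l2 <- ln_forward(l1$y + f1$y, par$ln2_g, par$ln2_b)
  }
  list(Rstar = l2$y, att = att, f1 = f1, l1 = l1, f2 = f2, l2 = l2)
}

# PMA: standard attention block from the trainable seed vectors onto the
# refined residue set, then seed-ordered concatenation and linear reduction.
.pma_fwd <- function(par, cfg, Rstar) {
  att2 <- attn_forward(par$seeds, Rstar, par$pma_Wq, par$pma_Wk, par$pma_Wv,
                       par$pma_w, cfg$heads)
  l3 <- ln_forward(par$seeds + att2$O, par$ln3_g, par$ln3_b)
  f3 <- rff_forward(l3$y, par$rff3_W1, par$rff3_b1,
                    par$rff3_W2, par$rff3_b2)
  l4 <- ln_forward(l3$y + f3$y, par$ln4_g, par$ln4_b)
  cvec <- as.vector(t(l4$y))              # concatenation in fixed seed order
  C <- as.vector(crossprod(par$lin_W, cvec)) + par$lin_b
  list(C = C, att2 = att2, l3 = l3, f3 = f3, l4 = l4, cvec = cvec)
}

# residue token indices from the protein encoder input (1..21); synthetic
# instances may instead carry a precomputed residue-embedding matrix.
# Returns list(yhat, map (attention_map), cache or NULL).
forward_instance <- function(par, cfg, R0, sub_idx, train = FALSE,
                             keep_cache = FALSE, residue_ids = NULL) {
  m <- nrow(R0)
  n <- length(sub_idx)
  if (n < 1L) stop("instance has an empty substructure set (n >= 1 required)")
  if (m < 1L) stop("empty residue set: pooling over an empty set is undefined")
  if (any(sub_idx < 0L) || any(sub_idx >= cfg$vocab_size))
    stop("substructure index out of range [0, ", cfg$vocab_size - 1L, "]")
  S <- par$E_sub[sub_idx + 1L, , drop = FALSE]
  Splus <- rbind(S, par$pseudo)                      # pseudo row LAST
  core <- .arkmab_fwd(par, cfg, R0, Splus)
  att <- core$att; f1 <- core$f1; l1 <- core$l1
  f2 <- core$f2; l2 <- core$l2
  Rstar <- core$Rstar
  pool <- .pma_fwd(par, cfg, Rstar)
  att2 <- pool$att2; l3 <- pool$l3; f3 <- pool$f3; l4 <- pool$l4
  cvec <- pool$cvec; C <- pool$C
  a <- as.vector(crossprod(par$mlp_W1, C)) + par$mlp_b1
  if (train && cfg$dropout_rate > 0) {
    mask <- (stats::runif(length(a)) >= cfg$dropout_rate) /
      (1 - cfg$dropout_rate)
    ad <- a * mask
  } else {
    mask <- NULL
    ad <- a
  }
  hdn <- pmax(ad, 0)
  yhat <- sum(hdn * par$mlp_W2) + par$mlp_b2
  if (!is.finite(yhat))
    stop("numerical error: non-finite activation in affinity head")
  map <- attention_map(aperm(att$A, c(3L, 1L, 2L)),
                       residue_ids = residue_ids,
                       substructure_indices = sub_idx)
  cache <- NULL
  if (keep_cache)
    cache <- list(R0 = R0, sub_idx = sub_idx, att = att, f1 = f1, l1 = l1,
                  f2 = f2, l2 = l2, Rstar = Rstar, att2 = att2, l3 = l3,
                  f3 = f3, l4 = l4, cvec = cvec, C = C, a = a, ad = ad,
                  mask = mask, hdn = hdn, m = m, n = n)
  list(yhat = yhat, map = map, cache = cache)
}

# Backward pass. dyhat: scalar gradient on the prediction. dAbar: m x (n+1)
# gradient on the HEAD-AVERAGED attention map (or NULL); it is split evenly
# across heads. Accumulates parameter gradients in `acc` and returns dR0 so
# the caller can push gradients into the protein encoder.
backward_instance <- function(par, cfg, cache, dyhat, dAbar, acc) {
  m <- cache$m; n <- cache$n; h <- cfg$heads
  acc$mlp_b2 <- acc$mlp_b2 + dyhat
  acc$mlp_W2 <- acc$mlp_W2 + matrix(cache$hdn * dyhat, ncol = 1L)
  dhdn <- as.vector(par$mlp_W2) * dyhat
  dad <- dhdn * (cache$ad > 0)
  da <- if (is.null(cache$mask)) dad else dad * cache$mask
  acc$mlp_W1 <- acc$mlp_W1 + outer(cache$C, da)
  acc$mlp_b1 <- acc$mlp_b1 + da
  dC <- as.vector(par$mlp_W1 %*% da)
  acc$lin_W <- acc$lin_W + outer(cache$cvec, dC)
  acc$lin_b <- acc$lin_b + dC
  dcvec <- as.vector(par$lin_W %*% dC)
  dRa <- matrix(dcvec, cfg$u, cfg$d, byrow = TRUE)
  dl3y <- ln_backward(dRa, cache$l4, par$ln4_g, acc, "ln4_g", "ln4_b")
  dl3y_f <- rff_backward(dl3y, cache$f3, par$rff3_W1, par$rff3_W2,
                         acc, "rff3")
  dl3 <- dl3y + dl3y_f
  dsum3 <- ln_backward(dl3, cache$l3, par$ln3_g, acc, "ln3_g", "ln3_b")
  bw2 <- attn_backward(dsum3, NULL, cache$att2, par$pma_Wq, par$pma_Wk,
                       par$pma_Wv, par$pma_w, h, acc, "pma")
  acc$seeds <- acc$seeds + dsum3 + bw2$dQ0
  dRstar <- bw2$dK0
  dA_extra <- NULL
  if (!is.null(dAbar)) {
    dA_extra <- array(0, dim = c(m, n + 1L, h))
    per <- dAbar / h
    for (t in seq_len(h)) dA_extra[, , t] <- per
  }
  if (cfg$strict_eq7) {
    dsum2 <- ln_backward(dRstar, cache$l2, par$ln2_g, acc, "ln2_g", "ln2_b")
    dR0 <- rff_backward(dsum2, cache$f2, par$rff2_W1, par$rff2_W2,
                        acc, "rff2")
    dl1y <- dsum2
    dsum1 <- ln_backward(dl1y, cache$l1, par$ln1_g, acc, "ln1_g", "ln1_b")
    dO <- rff_backward(dsum1, cache$f1, par$rff1_W1, par$rff1_W2,
                       acc, "rff1")
    dR0 <- dR0 + dsum1
  } else {
    dsum2 <- ln_backward(dRstar, cache$l2, par$ln2_g, acc, "ln2_g", "ln2_b")
    dl1y_f <- rff_backward(dsum2, cache$f1, par$rff1_W1, par$rff1_W2,
                           acc, "rff1")
    dl1y <- dsum2 + dl1y_f
    dsum1 <- ln_backward(dl1y, cache$l1, par$ln1_g, acc, "ln1_g", "ln1_b")
    dO <- dsum1
    dR0 <- dsum1
  }
  bw1 <- attn_backward(dO, dA_extra, cache$att, par$mab_Wq, par$mab_Wk,
                       par$mab_Wv, par$mab_w, h, acc, "mab")
  dR0 <- dR0 + bw1$dQ0
  dSplus <- bw1$dK0
  idx <- cache$sub_idx + 1L
  acc$E_sub[idx, ] <- acc$E_sub[idx, , drop = FALSE] +
    dSplus[seq_len(n), , drop = FALSE]
  acc$pseudo <- acc$pseudo + dSplus[n + 1L, ]
  dR0
}

# zeroed gradient buffers matching the parameter list
zero_grads <- function(par) {
  acc <- new.env(parent = emptyenv())
  for (nm in names(par)) {
    v <- par[[nm]]
    acc[[nm]] <- if (is.matrix(v)) matrix(0, nrow(v), ncol(v)) else
      numeric(length(v))
  }
  acc
}

# ---- standalone operation surface -------------------------------------------

#' Multi-head additive attention weights
#'
#' Per head, the score of query `i` against key `j` is
#' `w . tanh(Wq q_i + Wk k_j)` on the head's projection block, softmax-
#' normalized over all keys, so every row of every head sums to 1.
#'
#' @param queries `m x d` matrix.
#' @param keys `k x d` matrix.
#' @param heads head count (must divide `d`).
#' @param Wq,Wk `d x d` projection matrices (head blocks of `d/heads`
#'   columns); random (seeded) if omitted.
#' @param w `d/heads x heads` per-head scoring vectors; random if omitted.
#' @param seed seed for generated projections.
#' @return `heads x m x k` array of attention weights.
#' @export
additive_attention <- function(queries, keys, heads = 4L, Wq = NULL,
                               Wk = NULL, w = NULL, seed = 1L) {
  d <- ncol(queries)
  if (d %% heads != 0L)
    stop("config error: heads (", heads, ") must divide d (", d, ")")
  if (is.null(Wq) || is.null(Wk) || is.null(w)) {
    old <- .Random.seed_save()
    set.seed(seed)
    if (is.null(Wq)) Wq <- glorot(d, d)
    if (is.null(Wk)) Wk <- glorot(d, d)
    if (is.null(w)) w <- glorot(d %/% heads, heads)
    .Random.seed_restore(old)
  }
  att <- attn_forward(queries, keys, Wq, Wk, diag(d), w, heads)
  aperm(att$A, c(3L, 1L, 2L))
}

#' ARK-MAB forward pass
#'
#' Appends the trainable pseudo-substructure embedding as the LAST key/value
#' row, runs multi-head additive cross-attention from the residues onto the
#' augmented substructure set, and applies the residual/feed-forward/
#' layer-norm wiring selected by `config$strict_eq7`.
#'
#' @param R `m x d` residue embeddings.
#' @param S `n x d` substructure embeddings.
#' @param params model parameter list (see [dta_model()]).
#' @param config a [dta_config()].
#' @param substructure_indices optional bit indices for map annotation.
#' @return list with `R_star` (`m x d`) and `map` (an [attention_map()]
#'   with `n + 1` columns, pseudo last).
#' @export
arkmab_forward <- function(R, S, params, config,
                           substructure_indices = NULL) {
  stopifnot(ncol(R) == config$d, ncol(S) == config$d)
  core <- .arkmab_fwd(params, config, R, rbind(S, params$pseudo))
  list(R_star = core$Rstar,
       map = attention_map(aperm(core$att$A, c(3L, 1L, 2L)),
                           substructure_indices = substructure_indices))
}

#' Attention pooling (PMA) into a complex embedding
#'
#' Attention from `u` trainable seed vectors onto the refined residue set,
#' concatenated in fixed seed order and reduced by one linear map (no
#' activation) to a `d`-dimensional complex embedding. Permutation-invariant
#' in the residue order.
#'
#' @param R_star `m x d` refined residue embeddings (`m >= 1`).
#' @param params model parameter list.
#' @param config a [dta_config()].
#' @return numeric complex embedding of length `d`.
#' @export
pma_pool <- function(R_star, params, config) {
  if (is.null(nrow(R_star)) || nrow(R_star) == 0L)
    stop("empty-set error: cannot pool zero residues")
  .pma_fwd(params, config, R_star)$C
}

#' Affinity head
#'
#' Two-layer MLP `W2 ReLU(Dropout(W1 c + b1)) + b2` on the complex
#' embedding; dropout is active only with `train = TRUE`.
#'
#' @param c complex embedding (length `d`).
#' @param params model parameter list.
#' @param config a [dta_config()].
#' @param train apply dropout.
#' @return unbounded real prediction (log-affinity scale).
#' @export
predict_affinity <- function(c, params, config, train = FALSE) {
  a <- as.vector(crossprod(params$mlp_W1, c)) + params$mlp_b1
  if (train && config$dropout_rate > 0)
    a <- a * (stats::runif(length(a)) >= config$dropout_rate) /
      (1 - config$dropout_rate)
  sum(pmax(a, 0) * params$mlp_W2) + params$mlp_b2
}

#' Construct an untrained model
#'
#' Seeded random initialization of all parameters; the returned object has
#' the same class and methods as a trained fit ([predict.dta_fit()],
#' [evaluate()], ...), which makes untrained forward passes and property
#' checks convenient.
#'
#' @param config a [dta_config()].
#' @param encoder optional encoder handle (default: fallback encoder with
#'   the config's dimension and seed).
#' @return a `"dta_fit"` with empty history.
#' @export
dta_model <- function(config = dta_config(), encoder = NULL) {
  cfg <- config
  if (is.null(encoder))
    encoder <- encoder_fallback(cfg$d, positional = cfg$positional,
                                seed = cfg$seed)
  old <- .Random.seed_save()
  set.seed(cfg$seed)
  par <- init_params(cfg)
  .Random.seed_restore(old)
  if (encoder$type == "fallback") par$E_res <- encoder$table
  structure(list(params = par, config = cfg, encoder = encoder,
                 history = NULL, best_epoch = 0L, best_val_rmse = NA_real_,
                 measurement = cfg$measurement, n_train = 0L, n_val = 0L),
            class = "dta_fit")
}
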