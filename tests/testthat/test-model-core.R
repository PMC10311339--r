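# The attention network: additive attention, guided cross-attention block,
# attention pooling, affinity head, and the composed forward pass.

test_that("additive attention rows are probability distributions", {
  set.seed(4)
  for (i in 1:10) {
    m <- sample(1:9, 1); k <- sample(1:7, 1); d <- 8L
    A <- additive_attention(matrix(rnorm(m * d), m), matrix(rnorm(k * d), k),
                            heads = 2L, seed = i)
    expect_equal(dim(A), c(2L, m, k))
    expect_lt(max(abs(apply(A, c(1, 2), sum) - 1)), 1e-5)
    expect_true(all(A >= 0))
  }
  # degenerate softmax: a single key receives everything
  A1 <- additive_attention(matrix(rnorm(10 * 8), 10), matrix(rnorm(8), 1),
                           heads = 4L)
  expect_true(all(A1 == 1))
  expect_error(additive_attention(matrix(0, 2, 9), matrix(0, 2, 9),
                                  heads = 2L), "config error")
})

test_that("additive attention matches by-hand softmax on a 1-head case", {
  # m = 1, n = 1 (k = 2 keys), d = 2, one head; fixed small parameters
  q <- matrix(c(0.3, -0.2), 1)
  keys <- rbind(c(0.5, 0.1), c(-0.4, 0.7))
  Wq <- matrix(c(1, 0.5, -0.5, 1), 2)
  Wk <- diag(2) * 0.8
  w <- matrix(c(1, -1), 2, 1)
  zhand <- vapply(1:2, function(j)
    sum(w * tanh(as.vector(q %*% Wq) + as.vector(keys[j, ] %*% Wk))), 0)
  Ahand <- exp(zhand) / sum(exp(zhand))
  A <- additive_attention(q, keys, heads = 1L, Wq = Wq, Wk = Wk, w = w)
  expect_equal(as.vector(A[1, 1, ]), Ahand, tolerance = 1e-12)
})

test_that("the cross-attention block is equivariant in the substructure set
           and leaves predictions unchanged", {
  cfg <- tiny_config()
  model <- tiny_model(cfg)
  par <- model$params
  set.seed(9)
  m <- 7L; n <- 5L
  R <- matrix(rnorm(m * cfg$d), m)
  S <- matrix(rnorm(n * cfg$d), n)
  out <- arkmab_forward(R, S, par, cfg)
  expect_equal(dim(out$R_star), c(m, cfg$d))
  expect_equal(dim(out$map$weights), c(m, n + 1L))
  expect_equal(out$map$pseudo_column, n + 1L)
  perm <- c(3L, 1L, 5L, 2L, 4L)
  out_p <- arkmab_forward(R, S[perm, ], par, cfg)
  # attention columns over real substructures permute identically...
  expect_equal(out_p$map$weights[, seq_len(n)],
               out$map$weights[, perm], tolerance = 1e-12)
  # ...the pseudo column and the refined residues are untouched
  expect_equal(out_p$map$weights[, n + 1L], out$map$weights[, n + 1L])
  expect_equal(out_p$R_star, out$R_star, tolerance = 1e-12)
})

test_that("attention rows sum to one on random forward passes", {
  cfg <- tiny_config()
  model <- tiny_model(cfg)
  set.seed(12)
  for (i in 1:30) {
    m <- sample(1:20, 1); n <- sample(1:10, 1)
    out <- arkmab_forward(matrix(rnorm(m * cfg$d), m),
                          matrix(rnorm(n * cfg$d), n), model$params, cfg)
    expect_lt(max(abs(rowSums(out$map$weights) - 1)), 1e-5)
    expect_lt(max(abs(apply(out$map$per_head, c(1, 2), sum) - 1)), 1e-5)
    # the head-averaged map is the arithmetic mean over heads
    expect_equal(out$map$weights, colMeans(out$map$per_head),
                 tolerance = 1e-12)
  }
})

test_that("attention pooling is permutation-invariant and fixed-size", {
  cfg <- tiny_config()
  par <- tiny_model(cfg)$params
  set.seed(5)
  for (m in c(1L, 4L, 17L)) {
    Rs <- matrix(rnorm(m * cfg$d), m)
    cvec <- pma_pool(Rs, par, cfg)
    expect_length(cvec, cfg$d)
    p <- sample(m)
    expect_equal(pma_pool(Rs[p, , drop = FALSE], par, cfg), cvec,
                 tolerance = 1e-5)
  }
  expect_error(pma_pool(matrix(0, 0, cfg$d), par, cfg), "empty-set")
})

test_that("a single residue with one seed receives unit pooling attention", {
  cfg <- tiny_config(u = 1L)
  par <- tiny_model(cfg)$params
  att <- attn_forward(par$seeds, matrix(rnorm(cfg$d), 1), par$pma_Wq,
                      par$pma_Wk, par$pma_Wv, par$pma_w, cfg$heads)
  expect_true(all(att$A == 1))
})

test_that("the affinity head follows its closed form", {
  cfg <- tiny_config()
  par <- tiny_model(cfg)$params
  zero <- par
  zero$mlp_W1[] <- 0; zero$mlp_b1[] <- 0; zero$mlp_W2[] <- 0; zero$mlp_b2 <- 0
  expect_identical(predict_affinity(rnorm(cfg$d), zero, cfg), 0)
  cvec <- rnorm(cfg$d)
  expect_equal(predict_affinity(cvec, par, cfg),
               sum(pmax(as.vector(crossprod(par$mlp_W1, cvec)) + par$mlp_b1,
                        0) * par$mlp_W2) + par$mlp_b2)
  # eval mode is deterministic; dropout can perturb training mode
  expect_identical(predict_affinity(cvec, par, cfg),
                   predict_affinity(cvec, par, cfg))
  cfg_dp <- tiny_config(dropout_rate = 0.5)
  set.seed(1)
  draws <- replicate(20, predict_affinity(cvec, par, cfg_dp, train = TRUE))
  expect_gt(length(unique(draws)), 1L)
})

test_that("the composed forward pass is reproducible, finite and shaped", {
  cfg <- tiny_config()
  model <- tiny_model(cfg)
  set.seed(21)
  insts <- replicate(30, random_instance(m = sample(2:25, 1),
                                         n = sample(1:9, 1)),
                     simplify = FALSE)
  y1 <- predict(model, insts)
  y2 <- predict(model, insts)
  expect_identical(y1, y2)          # bit-reproducible in evaluation mode
  expect_true(all(is.finite(y1)))
  maps <- predict(model, insts, type = "attention")
  for (i in seq_along(insts)) {
    expect_equal(dim(maps[[i]]$weights),
                 c(insts[[i]]$protein$m, insts[[i]]$substructures$n + 1L))
  }
})

test_that("residue-order permutation permutes the refined set and attention
           rows identically and leaves the prediction unchanged", {
  cfg <- tiny_config()
  par <- tiny_model(cfg)$params
  set.seed(8)
  m <- 9L; n <- 4L
  R <- matrix(rnorm(m * cfg$d), m)
  S <- matrix(rnorm(n * cfg$d), n)
  out <- arkmab_forward(R, S, par, cfg)
  perm <- sample(m)
  out_p <- arkmab_forward(R[perm, ], S, par, cfg)
  expect_equal(out_p$R_star, out$R_star[perm, ], tolerance = 1e-12)
  expect_equal(out_p$map$weights, out$map$weights[perm, ],
               tolerance = 1e-12)
  expect_equal(pma_pool(out_p$R_star, par, cfg),
               pma_pool(out$R_star, par, cfg), tolerance = 1e-5)
})

test_that("analytic gradients match central finite differences", {
  # tiny config in double precision; 20 sampled parameters across tensors
  cfg <- tiny_config(d = 8L, heads = 2L, dropout_rate = 0)
  for (wiring in c(TRUE, FALSE)) {
    cfg$strict_eq7 <- wiring
    model <- dta_model(cfg)
    par <- model$params
    set.seed(33)
    insts <- replicate(2, random_instance(m = 6, n = 3), simplify = FALSE)
    loss_fn <- function(par) {
      yh <- numeric(2); l2 <- numeric(2)
      for (i in 1:2) {
        R0 <- par$E_res[insts[[i]]$protein$res_tok, , drop = FALSE]
        fw <- ncidta:::forward_instance(par, cfg, R0,
                                        insts[[i]]$substructures$indices)
        yh[i] <- fw$yhat
        l2[i] <- attention_regularization_loss(fw$map,
                                               insts[[i]]$nci_labels)
      }
      affinity_loss(yh, vapply(insts, `[[`, 0, "y")) + 5 * mean(l2)
    }
    acc <- ncidta:::zero_grads(par)
    for (i in 1:2) {
      inst <- insts[[i]]
      R0 <- par$E_res[inst$protein$res_tok, , drop = FALSE]
      fw <- ncidta:::forward_instance(par, cfg, R0,
                                      inst$substructures$indices,
                                      keep_cache = TRUE)
      dy <- 2 * (fw$yhat - inst$y) / 2
      dA <- ncidta:::attention_loss_grad(fw$map, inst$nci_labels,
                                         scale = 5 / 2)
      dR0 <- ncidta:::backward_instance(par, cfg, fw$cache, dy, dA, acc)
      gE <- rowsum(dR0, group = inst$protein$res_tok)
      rows <- as.integer(rownames(gE))
      acc$E_res[rows, ] <- acc$E_res[rows, , drop = FALSE] + gE
    }
    set.seed(101)
    eps <- 1e-6
    checked <- 0L
    while (checked < 20L) {
      nm <- sample(names(par), 1)
      k <- sample(length(par[[nm]]), 1)
      pp <- par; pp[[nm]][k] <- pp[[nm]][k] + eps
      pm <- par; pm[[nm]][k] <- pm[[nm]][k] - eps
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      ana <- acc[[nm]][k]
      if (abs(num) < 1e-9 && abs(ana) < 1e-9) next  # untouched parameter
      expect_lt(abs(num - ana) / max(abs(num), abs(ana)), 1e-3)
      checked <- checked + 1L
    }
  }
})
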