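# Objective terms and evaluation metrics.

random_map <- function(m, n, h = 3L) {
  ph <- array(rexp(h * m * (n + 1L)), dim = c(h, m, n + 1L))
  for (t in seq_len(h)) ph[t, , ] <- ph[t, , ] / rowSums(ph[t, , , drop = TRUE])
  attention_map(ph)
}

test_that("NCI scores are the real-column attention mass (= 1 - pseudo)", {
  ph <- array(c(0.2, 0.3, 0.5), dim = c(1, 1, 3))
  expect_equal(nci_scores(attention_map(ph)), 0.5)
  ph0 <- array(c(0, 0, 1), dim = c(1, 1, 3))
  expect_equal(nci_scores(attention_map(ph0)), 0)
  set.seed(31)
  for (i in 1:20) {
    map <- random_map(sample(2:9, 1), sample(1:7, 1))
    expect_lt(max(abs(nci_scores(map) +
                        map$weights[, map$pseudo_column] - 1)), 1e-6)
  }
})

test_that("attention regularization loss matches hand arithmetic", {
  mk_map <- function(scores) {
    # one head, two key columns: (score, pseudo)
    ph <- array(0, dim = c(1, length(scores), 2))
    ph[1, , 1] <- scores
    ph[1, , 2] <- 1 - scores
    attention_map(ph)
  }
  expect_equal(attention_regularization_loss(mk_map(c(0.8, 0.1)), c(1, 0)),
               -(log(0.8) + log(0.9)) / 2)
  expect_equal(attention_regularization_loss(mk_map(c(0.5, 0.5, 0.5)),
                                             c(1, 0, 1)),
               log(2), tolerance = 1e-12)
  expect_lt(attention_regularization_loss(mk_map(c(0.9999, 1e-4)), c(1, 0)),
            1e-3)
  expect_error(attention_regularization_loss(mk_map(0.5), c(1, 0)),
               "validation error")
})

test_that("loss is minimized by pushing pseudo weight toward 1 - label", {
  mk_map <- function(scores) {
    ph <- array(0, dim = c(1, length(scores), 2))
    ph[1, , 1] <- scores; ph[1, , 2] <- 1 - scores
    attention_map(ph)
  }
  labels <- c(1, 0, 1, 0)
  aligned <- attention_regularization_loss(mk_map(c(1, 0, 1, 0) * 0.999 +
                                                    5e-4), labels)
  for (i in 1:10) {
    s <- runif(4)
    expect_gte(attention_regularization_loss(mk_map(s), labels), aligned)
  }
})

test_that("affinity loss is the mean squared error", {
  expect_equal(affinity_loss(c(1, 3), c(0, 0)), 5)
  expect_equal(affinity_loss(1:4, 1:4), 0)
  set.seed(2)
  a <- rnorm(9); b <- rnorm(9); p <- sample(9)
  expect_equal(affinity_loss(a, b), affinity_loss(a[p], b[p]))
  expect_error(affinity_loss(numeric(0), numeric(0)), "empty")
})

test_that("total loss composes linearly and alpha = 0 drops the L2 term", {
  expect_identical(total_loss(1.37, 99, 0), 1.37)
  expect_equal(total_loss(1, 0.2, 5), 2)
  expect_error(total_loss(1, 1, -1), "alpha")
})

test_that("regression metrics match closed forms", {
  m <- regression_metrics(c(1, 2), c(2, 4))
  expect_equal(m$rmse, sqrt(2.5))
  expect_equal(m$mae, 1.5)
  y <- c(1, 3, 2, 5)
  m2 <- regression_metrics(2 * y + 1, y)
  expect_equal(m2$pcorr, 1)
  m3 <- regression_metrics(y, y)
  expect_equal(unlist(m3), c(rmse = 0, mae = 0, pcorr = 1))
  expect_error(regression_metrics(c(1, 1), c(2, 3)), "zero-variance")
})

test_that("concordance index matches exhaustive pair enumeration", {
  expect_equal(concordance_index(1:6, 1:6), 1)
  expect_equal(concordance_index(6:1, 1:6), 0)
  brute_ci <- function(yhat, y) {
    num <- 0; den <- 0
    for (i in seq_along(y)) for (j in seq_along(y)) {
      if (y[i] > y[j]) {
        den <- den + 1
        if (yhat[i] > yhat[j]) num <- num + 1
        else if (yhat[i] == yhat[j]) num <- num + 0.5
      }
    }
    num / den
  }
  set.seed(77)
  for (rep in 1:10) {
    y <- round(rnorm(50), 1)        # rounding creates ties in y
    yhat <- round(rnorm(50), 1)     # and in the predictions
    if (length(unique(y)) < 2) next
    expect_equal(concordance_index(yhat, y), brute_ci(yhat, y))
  }
  expect_error(concordance_index(c(1, 2), c(3, 3)), "no comparable pairs")
})

test_that("residue AUROC behaves as a ROC area", {
  lab <- c(0, 1, 0, 1, 1, 0)
  expect_equal(residue_auroc(lab, lab), 1)
  expect_equal(residue_auroc(1 - lab, lab), 0)
  set.seed(99)
  n <- 1e4
  labels <- rbinom(n, 1, 0.5)
  scores <- runif(n)
  expect_lt(abs(residue_auroc(scores, labels) - 0.5), 0.02)
  expect_error(residue_auroc(runif(5), rep(1, 5)), "single-class")
  # accepts per-instance lists and pools them
  expect_equal(residue_auroc(list(lab[1:3], lab[4:6]),
                             list(lab[1:3], lab[4:6])), 1)
})
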