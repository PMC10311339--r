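# Seeded optimization, early stopping, ablation hooks, fine-tuning,
# evaluation.

engine_data <- function(n = 40L, seed = 61L) {
  w <- generate_world(n_motifs = 2L, seed = 17L)
  generate_dataset(w, n, seed = seed, protein_len_range = c(12L, 20L),
                   n_substructures = 5L)
}

test_that("training is bit-reproducible under a fixed seed", {
  insts <- engine_data()
  cfg <- tiny_config(max_epochs = 3L, alpha = 5, lr = 5e-3,
                     dropout_rate = 0.1)
  f1 <- dta_fit(insts[1:30], cfg, val_instances = insts[31:40])
  f2 <- dta_fit(insts[1:30], cfg, val_instances = insts[31:40])
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  cfg2 <- tiny_config(max_epochs = 3L, alpha = 5, lr = 5e-3,
                      dropout_rate = 0.1, seed = 2L)
  f3 <- dta_fit(insts[1:30], cfg2, val_instances = insts[31:40])
  expect_false(identical(f1$history$train_l1, f3$history$train_l1))
})

test_that("patience 0 stops at the first non-improving epoch", {
  insts <- engine_data()
  cfg <- tiny_config(max_epochs = 30L, patience = 0L, lr = 0,
                     alpha = 0)
  # lr 0: validation RMSE can never improve after epoch 1
  fit <- dta_fit(insts[1:30], cfg, val_instances = insts[31:40])
  expect_equal(nrow(fit$history), 2L)
  expect_equal(fit$best_epoch, 1L)
})

test_that("alpha = 0 reproduces pure affinity training and alpha > 0 drives
           the attention loss down", {
  insts <- engine_data(60L)
  cfg0 <- tiny_config(max_epochs = 2L, alpha = 0, lr = 5e-3)
  fit0 <- dta_fit(insts[1:50], cfg0, val_instances = insts[51:60])
  expect_true(all(is.na(fit0$history$train_l2)))
  cfg_big <- tiny_config(max_epochs = 6L, alpha = 100, lr = 5e-3)
  fit_big <- dta_fit(insts[1:50], cfg_big, val_instances = insts[51:60])
  l2 <- fit_big$history$train_l2
  expect_false(any(is.na(l2)))
  expect_lt(l2[length(l2)], l2[1])     # monitored run: L2 decreases
})

test_that("label-free instances train without the L2 term ever appearing", {
  insts <- lapply(engine_data(20L), function(i) {
    i$nci_labels <- NULL
    i
  })
  cfg <- tiny_config(max_epochs = 2L, alpha = 5, lr = 5e-3)
  fit <- dta_fit(insts[1:16], cfg, val_instances = insts[17:20])
  expect_true(all(is.na(fit$history$train_l2)))
})

test_that("divergent training aborts with a state-carrying error", {
  insts <- engine_data(20L)
  cfg <- tiny_config(max_epochs = 5L, alpha = 0, lr = 1e6)
  expect_error(dta_fit(insts[1:16], cfg, val_instances = insts[17:20]),
               "diverged|non-finite")
})

test_that("fine-tuning restarts from the checkpoint and checks shapes", {
  insts <- engine_data(40L)
  cfg <- tiny_config(max_epochs = 2L, alpha = 5, lr = 5e-3)
  fit <- dta_fit(insts[1:30], cfg, val_instances = insts[31:40])
  shifted <- lapply(engine_data(30L, seed = 99L), function(i) {
    i$y <- i$y + 2          # shifted affinity scale, no NCI labels
    i$nci_labels <- NULL
    i
  })
  ft <- finetune(fit, shifted[1:24], val_instances = shifted[25:30],
                 config = tiny_config(max_epochs = 3L, alpha = 5, lr = 5e-3))
  expect_true(all(is.na(ft$history$train_l2)))
  # fine-tuning improves held-out RMSE on the shifted distribution
  before <- evaluate(fit, shifted[25:30])$rmse
  after <- evaluate(ft, shifted[25:30])$rmse
  expect_lt(after, before)
  bad_cfg <- tiny_config(d = 32L, max_epochs = 1L)
  expect_error(finetune(fit, shifted, config = bad_cfg),
               "architecture mismatch")
})

test_that("checkpoints round-trip through a single file", {
  insts <- engine_data(20L)
  cfg <- tiny_config(max_epochs = 1L, lr = 5e-3)
  fit <- dta_fit(insts[1:16], cfg, val_instances = insts[17:20])
  path <- tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, fit$params)
  expect_identical(predict(back, insts[1:5]), predict(fit, insts[1:5]))
})

test_that("evaluation is deterministic and reports the metric bundle", {
  insts <- engine_data(30L)
  cfg <- tiny_config(max_epochs = 1L, lr = 5e-3)
  fit <- dta_fit(insts[1:24], cfg, val_instances = insts[25:30])
  e1 <- evaluate(fit, insts[25:30])
  e2 <- evaluate(fit, insts[25:30])
  expect_identical(e1$rmse, e2$rmse)
  expect_identical(e1$predictions$yhat, e2$predictions$yhat)
  expect_true(all(c("rmse", "mae", "pcorr", "ci", "residue_auroc") %in%
                    names(e1)))
  expect_equal(nrow(e1$predictions), 6L)
})

test_that("fold-wise aggregation matches hand computation", {
  ms <- list(list(rmse = 1, mae = 1, pcorr = .5, ci = .7,
                  residue_auroc = .8),
             list(rmse = 2, mae = 1.5, pcorr = .6, ci = .75,
                  residue_auroc = .9),
             list(rmse = 3, mae = 2, pcorr = .7, ci = .8,
                  residue_auroc = 1))
  agg <- aggregate_fold_metrics(ms)
  expect_equal(agg$mean[agg$metric == "rmse"], 2)
  expect_equal(agg$sd[agg$metric == "rmse"], 1)
  expect_equal(agg$mean[agg$metric == "ci"], mean(c(.7, .75, .8)))
  expect_equal(agg$sd[agg$metric == "residue_auroc"], sd(c(.8, .9, 1)))
})

test_that("the S3 surface behaves like a fitted model object", {
  insts <- engine_data(20L)
  cfg <- tiny_config(max_epochs = 1L, lr = 5e-3)
  fit <- dta_fit(insts[1:16], cfg, val_instances = insts[17:20])
  expect_output(print(fit), "Cross-attention affinity model")
  expect_output(summary(fit), "parameters in")
  expect_type(coef(fit), "list")
  expect_true("pseudo" %in% names(coef(fit)))
  res <- residuals(fit, insts[17:20])
  expect_equal(res, vapply(insts[17:20], `[[`, 0, "y") -
                 predict(fit, insts[17:20]))
  tmp <- tempfile(fileext = ".png")
  grDevices::png(tmp)
  plot(fit)
  grDevices::dev.off()
  expect_true(file.exists(tmp))
})

test_that("measurement types must not be mixed in one run", {
  insts <- engine_data(10L)
  insts[[3]]$measurement <- "IC50"
  expect_error(dta_fit(insts, tiny_config()), "dataset tag check")
})
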