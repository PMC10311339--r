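# Training engine: seeded Adam optimization of the joint objective
# L = MSE(yhat, y) + alpha * BCE(attention NCI scores, NCI labels),
# with early stopping on validation RMSE, fine-tuning from a checkpoint,
# and fold-wise evaluation.

# residue embeddings for one instance under the model's encoder
encoder_R0 <- function(par, cfg, encoder, res_tok, protein = NULL) {
  if (is.null(encoder) || encoder$type == "fallback") {
    R0 <- par$E_res[res_tok, , drop = FALSE]
    if (is.null(encoder) || encoder$positional)
      R0 <- R0 + pos_encoding(length(res_tok), cfg$d)
    return(R0)
  }
  embed_residues(protein, encoder)
}

.adam_state <- function(par) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(par, function(v) v * 0)
  st$v <- lapply(par, function(v) v * 0)
  st$t <- 0L
  st
}

.adam_step <- function(par, acc, st, lr, skip = character(0),
                       b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  corr1 <- 1 - b1^st$t
  corr2 <- 1 - b2^st$t
  for (nm in names(par)) {
    if (nm %in% skip) next
    g <- acc[[nm]]
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    par[[nm]] <- par[[nm]] -
      lr * (st$m[[nm]] / corr1) / (sqrt(st$v[[nm]] / corr2) + eps)
  }
  par
}

.check_measurements <- function(instances) {
  meas <- vapply(instances, `[[`, "", "measurement")
  kikd <- meas %in% c("Ki", "Kd")
  if (any(kikd) && !all(kikd))
    stop("dataset tag check: Ki/Kd and IC50 instances must not be mixed ",
         "in one training run")
  if (all(kikd)) "KIKD" else "IC50"
}

# loss + gradients over one minibatch; returns list(l1, l2, n_labeled)
.train_batch <- function(par, cfg, encoder, batch, acc) {
  B <- length(batch)
  labeled <- which(!vapply(batch, function(i) is.null(i$nci_labels), TRUE))
  nl <- length(labeled)
  caches <- vector("list", B)
  yhat <- numeric(B)
  l2s <- numeric(B)
  for (b in seq_len(B)) {
    inst <- batch[[b]]
    R0 <- encoder_R0(par, cfg, encoder, inst$protein$res_tok, inst$protein)
    fw <- forward_instance(par, cfg, R0, inst$substructures$indices,
                           train = TRUE, keep_cache = TRUE)
    caches[[b]] <- fw$cache
    yhat[b] <- fw$yhat
    dy <- NULL   # backward after loss normalization below
    dAbar <- NULL
    if (cfg$alpha > 0 && b %in% labeled) {
      l2s[b] <- attention_regularization_loss(fw$map, inst$nci_labels)
      dAbar <- attention_loss_grad(fw$map, inst$nci_labels,
                                   scale = cfg$alpha / nl)
    }
    dy <- 2 * (yhat[b] - inst$y) / B
    dR0 <- backward_instance(par, cfg, fw$cache, dy, dAbar, acc)
    if ((is.null(encoder) || encoder$type == "fallback")) {
      gE <- rowsum(dR0, group = inst$protein$res_tok)
      rows <- as.integer(rownames(gE))
      acc$E_res[rows, ] <- acc$E_res[rows, , drop = FALSE] + gE
    }
  }
  y <- vapply(batch, `[[`, 0, "y")
  list(l1 = affinity_loss(yhat, y),
       l2 = if (nl && cfg$alpha > 0) mean(l2s[labeled]) else NA_real_,
       n_labeled = nl)
}

#' Fit the cross-attention affinity model
#'
#' Trains the full network (protein encoder, substructure vocabulary,
#' guided cross-attention block, attention pooling, affinity head) with
#' Adam (weight decay 0) on minibatches, optimizing
#' `L = MSE + alpha * BCE(attention NCI scores, labels)`. Instances without
#' NCI labels contribute only the affinity term. Training stops after
#' `config$max_epochs` or when validation RMSE has not improved for
#' `config$patience` epochs; the parameters with the best validation RMSE
#' are retained. Fully seeded: identical seeds give identical fits.
#'
#' @param instances training instances (list of [affinity_instance()]).
#' @param config a [dta_config()].
#' @param val_instances validation instances; if `NULL`, 5% of `instances`
#'   (at least one) are split off with the config seed.
#' @param encoder an encoder handle; defaults to [encoder_fallback()] with
#'   the config's `d` and seed.
#' @param init optional parameter list (from a previous fit) to continue
#'   from; dimensions must match the config.
#' @param verbose print per-epoch progress.
#' @return object of class `"dta_fit"`: `params`, `config`, `encoder`,
#'   `history` (per-epoch train L1/L2 and validation RMSE/CI),
#'   `best_epoch`, `best_val_rmse`, and the training `instances_used`
#'   bookkeeping.
#' @export
dta_fit <- function(instances, config = dta_config(),
                    val_instances = NULL, encoder = NULL, init = NULL,
                    verbose = FALSE) {
  if (!length(instances)) stop("no training instances")
  measurement <- .check_measurements(instances)
  cfg <- config
  if (is.null(val_instances)) {
    # split off 5% (at least one instance) for validation
    old <- .Random.seed_save()
    set.seed(cfg$seed)
    perm <- sample.int(length(instances))
    .Random.seed_restore(old)
    nv <- max(1L, floor(0.05 * length(instances)))
    val_instances <- instances[perm[seq_len(nv)]]
    instances <- instances[perm[-seq_len(nv)]]
  }
  if (is.null(encoder))
    encoder <- encoder_fallback(cfg$d, positional = cfg$positional,
                                seed = cfg$seed)
  if (encoder$type == "fallback" && cfg$freeze_encoder)
    encoder <- set_encoder_trainable(encoder, FALSE)
  old <- .Random.seed_save()
  set.seed(cfg$seed)
  par <- if (is.null(init)) init_params(cfg) else init
  if (!is.null(init)) .check_architecture(init, cfg)
  if (is.null(init) && encoder$type == "fallback")
    par$E_res <- encoder$table
  if (is.null(init))   # start the affinity head at the target mean
    par$mlp_b2 <- mean(vapply(instances, `[[`, 0, "y"))
  skip <- character(0)
  if (encoder$type != "fallback" || !encoder$trainable ||
      cfg$freeze_encoder)
    skip <- "E_res"
  if (!cfg$strict_eq7)
    skip <- c(skip, "rff2_W1", "rff2_b1", "rff2_W2", "rff2_b2")
  st <- .adam_state(par)
  n <- length(instances)
  hist <- list()
  best <- list(rmse = Inf, par = par, epoch = 0L)
  patience_left <- cfg$patience
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    l1s <- c(); l2s <- c()
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      acc <- zero_grads(par)
      bt <- .train_batch(par, cfg, encoder, instances[idx], acc)
      if (!is.finite(bt$l1) || (!is.na(bt$l2) && !is.finite(bt$l2)))
        stop("training diverged at epoch ", epoch,
             ": non-finite loss (l1=", bt$l1, ", l2=", bt$l2, ")")
      l1s <- c(l1s, bt$l1)
      if (!is.na(bt$l2)) l2s <- c(l2s, bt$l2)
      par <- .adam_step(par, acc, st, cfg$lr, skip = skip)
    }
    vm <- .eval_instances(par, cfg, encoder, val_instances)
    hist[[epoch]] <- data.frame(
      epoch = epoch, train_l1 = mean(l1s),
      train_l2 = if (length(l2s)) mean(l2s) else NA_real_,
      val_rmse = vm$rmse, val_ci = vm$ci)
    if (verbose)
      message(sprintf("epoch %3d  L1 %.4f  L2 %s  val RMSE %.4f  val CI %.3f",
                      epoch, mean(l1s),
                      if (length(l2s)) sprintf("%.4f", mean(l2s)) else "-",
                      vm$rmse, vm$ci))
    if (vm$rmse < best$rmse - 1e-12) {
      best <- list(rmse = vm$rmse, par = par, epoch = epoch)
      patience_left <- cfg$patience
    } else {
      patience_left <- patience_left - 1L
      if (patience_left < 0L) break
    }
  }
  .Random.seed_restore(old)
  if (encoder$type == "fallback") encoder$table <- best$par$E_res
  structure(list(params = best$par, config = cfg, encoder = encoder,
                 history = do.call(rbind, hist),
                 best_epoch = best$epoch, best_val_rmse = best$rmse,
                 measurement = measurement,
                 n_train = n, n_val = length(val_instances)),
            class = "dta_fit")
}

.check_architecture <- function(par, cfg) {
  ref <- NULL
  old <- .Random.seed_save()
  set.seed(0L)
  ref <- init_params(cfg)
  .Random.seed_restore(old)
  for (nm in names(ref)) {
    a <- dim(ref[[nm]]) %||% length(ref[[nm]])
    b <- dim(par[[nm]]) %||% length(par[[nm]])
    if (is.null(par[[nm]]) || !identical(as.integer(a), as.integer(b)))
      stop("architecture mismatch for '", nm, "': checkpoint ",
           paste(b, collapse = "x"), " vs config ",
           paste(a, collapse = "x"))
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.eval_instances <- function(par, cfg, encoder, instances) {
  yhat <- vapply(instances, function(inst) {
    R0 <- encoder_R0(par, cfg, encoder, inst$protein$res_tok, inst$protein)
    forward_instance(par, cfg, R0, inst$substructures$indices)$yhat
  }, 0)
  y <- vapply(instances, `[[`, 0, "y")
  rmse <- sqrt(mean((yhat - y)^2))
  ci <- tryCatch(concordance_index(yhat, y), error = function(e) NA_real_)
  list(rmse = rmse, ci = ci, yhat = yhat, y = y)
}

#' Fine-tune a fitted model on new data
#'
#' Continues training from a checkpoint's parameters on a new dataset
#' (e.g. one without NCI labels, in which case only the affinity loss is
#' optimized). The architecture must match.
#'
#' @param fit a `"dta_fit"` (or checkpoint list with `params` + `config`).
#' @param instances new training instances.
#' @param val_instances optional validation instances.
#' @param config optional new [dta_config()]; defaults to the checkpoint's
#'   config. Dimensions (`d`, `heads`, `u`, `rff_hidden_dim`) must equal
#'   the checkpoint's.
#' @param ... passed to [dta_fit()].
#' @return a new `"dta_fit"`.
#' @export
finetune <- function(fit, instances, val_instances = NULL, config = NULL,
                     ...) {
  cfg <- config %||% fit$config
  for (nm in c("d", "heads", "u", "rff_hidden_dim", "vocab_size"))
    if (!identical(cfg[[nm]], fit$config[[nm]]))
      stop("architecture mismatch: config ", nm, " = ", cfg[[nm]],
           " differs from checkpoint ", fit$config[[nm]])
  dta_fit(instances, config = cfg, val_instances = val_instances,
          encoder = fit$encoder, init = fit$params, ...)
}

#' Evaluate a fitted model
#'
#' Deterministic evaluation-mode forward pass (dropout off) over a set of
#' instances.
#'
#' @param fit a `"dta_fit"`.
#' @param instances instances to evaluate.
#' @return list with `rmse`, `mae`, `pcorr`, `ci`, `residue_auroc` (when
#'   any instance carries NCI labels and both classes occur), and a
#'   `predictions` data frame.
#' @export
evaluate <- function(fit, instances) {
  stopifnot(inherits(fit, "dta_fit"), length(instances) > 0)
  ev <- .eval_instances(fit$params, fit$config, fit$encoder, instances)
  met <- regression_metrics(ev$yhat, ev$y)
  scores <- list(); labels <- list()
  for (inst in instances) {
    if (is.null(inst$nci_labels)) next
    R0 <- encoder_R0(fit$params, fit$config, fit$encoder,
                     inst$protein$res_tok, inst$protein)
    fw <- forward_instance(fit$params, fit$config, R0,
                           inst$substructures$indices)
    scores[[length(scores) + 1L]] <- nci_scores(fw$map)
    labels[[length(labels) + 1L]] <- inst$nci_labels
  }
  auroc <- NA_real_
  if (length(labels) && length(unique(unlist(labels))) == 2L)
    auroc <- residue_auroc(scores, labels)
  list(rmse = met$rmse, mae = met$mae, pcorr = met$pcorr, ci = ev$ci,
       residue_auroc = auroc,
       predictions = data.frame(
         protein_id = vapply(instances, function(i) i$protein$protein_id, ""),
         ligand_id = vapply(instances, `[[`, "", "ligand_id"),
         y = ev$y, yhat = ev$yhat))
}

#' Aggregate fold-wise metrics
#'
#' @param metric_list list of metric bundles from [evaluate()].
#' @return data frame with the mean and standard deviation of each metric
#'   across folds.
#' @export
aggregate_fold_metrics <- function(metric_list) {
  keys <- c("rmse", "mae", "pcorr", "ci", "residue_auroc")
  do.call(rbind, lapply(keys, function(k) {
    v <- vapply(metric_list, function(m) m[[k]] %||% NA_real_, 0)
    data.frame(metric = k, mean = mean(v), sd = stats::sd(v))
  }))
}

#' Save / load a model checkpoint
#'
#' Single-file state: parameters, config echo, encoder, history.
#'
#' @param fit a `"dta_fit"`.
#' @param path file path (`.rds`).
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(unclass(fit), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  structure(readRDS(path), class = "dta_fit")
}

# ---- S3 methods -------------------------------------------------------------

#' @export
print.dta_fit <- function(x, ...) {
  cat("Cross-attention affinity model\n")
  cat(sprintf("  d=%d heads=%d u=%d alpha=%g (%s), encoder: %s\n",
              x$config$d, x$config$heads, x$config$u, x$config$alpha,
              x$measurement, x$encoder$type))
  cat(sprintf("  trained %d epochs (best %d), val RMSE %.4f, %d train / %d val instances\n",
              nrow(x$history), x$best_epoch, x$best_val_rmse, x$n_train,
              x$n_val))
  invisible(x)
}

#' @export
summary.dta_fit <- function(object, ...) {
  print(object)
  cat("\ntraining history (last 5 epochs):\n")
  print(utils::tail(object$history, 5L), row.names = FALSE)
  npar <- sum(vapply(object$params, length, 1L))
  cat(sprintf("\n%d parameters in %d tensors\n", npar,
              length(object$params)))
  invisible(object)
}

#' @export
coef.dta_fit <- function(object, ...) object$params

#' Predict affinities or extract attention
#'
#' @param object a `"dta_fit"`.
#' @param newdata list of [affinity_instance()]s.
#' @param type `"affinity"` for predicted log-affinities, `"attention"` for
#'   per-instance [attention_map()]s.
#' @param ... unused.
#' @return numeric vector or list of attention maps.
#' @export
predict.dta_fit <- function(object, newdata,
                            type = c("affinity", "attention"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "affinity_instance")) newdata <- list(newdata)
  out <- lapply(newdata, function(inst) {
    R0 <- encoder_R0(object$params, object$config, object$encoder,
                     inst$protein$res_tok, inst$protein)
    fw <- forward_instance(object$params, object$config, R0,
                           inst$substructures$indices,
                           residue_ids = strsplit(inst$protein$sequence,
                                                  "")[[1L]])
    fw
  })
  if (type == "affinity") vapply(out, `[[`, 0, "yhat") else
    lapply(out, `[[`, "map")
}

#' @export
residuals.dta_fit <- function(object, newdata, ...) {
  yhat <- predict.dta_fit(object, newdata)
  vapply(newdata, `[[`, 0, "y") - yhat
}

#' @export
plot.dta_fit <- function(x, ...) {
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$train_l1, type = "l", xlab = "epoch",
                 ylab = "train MSE", main = "affinity loss", ...)
  if (!all(is.na(h$train_l2)))
    graphics::plot(h$epoch, h$train_l2, type = "l", xlab = "epoch",
                   ylab = "train BCE", main = "attention regularization",
                   ...)
  else
    graphics::plot(h$epoch, h$val_rmse, type = "l", xlab = "epoch",
                   ylab = "val RMSE", main = "validation RMSE", ...)
  graphics::par(mfrow = c(1, 1))
  invisible(x)
}
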