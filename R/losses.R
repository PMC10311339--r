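# Training objective and evaluation metrics.
#
# L = L1 + alpha * L2, where L1 is the mean squared error of the predicted
# log-affinities and L2 is a binary cross-entropy on the head-averaged
# attention map: each residue's attention mass on the real substructure
# columns (everything but the pseudo column) is read as its predicted
# probability of forming a non-covalent interaction with the ligand.

BCE_EPS <- 1e-7

#' Per-residue NCI scores from an attention map
#'
#' The score of residue `i` is the sum of its head-averaged attention
#' weights over the real substructure columns, i.e. everything except the
#' final pseudo-substructure column. Because every attention row sums to 1,
#' this equals `1 - weights[i, pseudo_column]`.
#'
#' @param map an [attention_map()].
#' @return numeric vector of length `m` in `[0, 1]`.
#' @export
#' @examples
#' ph <- array(c(0.2, 0.3, 0.5), dim = c(1, 1, 3))
#' nci_scores(attention_map(ph))  # 0.5
nci_scores <- function(map) {
  w <- map$weights
  n <- ncol(w) - 1L
  as.vector(rowSums(w[, seq_len(n), drop = FALSE]))
}

#' Attention-regularization loss (binary cross-entropy)
#'
#' Mean over residues of the binary cross-entropy between the attention-derived
#' NCI score and the residue's binary NCI label. Scores are clamped to
#' `[eps, 1 - eps]` before taking logarithms.
#'
#' @param map an [attention_map()].
#' @param labels binary vector of length `m` (1 = residue has at least one
#'   NCI with the ligand).
#' @return a nonnegative scalar.
#' @export
attention_regularization_loss <- function(map, labels) {
  s <- nci_scores(map)
  if (length(s) != length(labels))
    stop("validation error: ", length(labels), " NCI labels for ",
         length(s), " residues")
  if (!all(labels %in% c(0, 1))) stop("NCI labels must be binary")
  s <- pmin(pmax(s, BCE_EPS), 1 - BCE_EPS)
  -mean(labels * log(s) + (1 - labels) * log(1 - s))
}

# gradient of the attention-regularization loss w.r.t. the head-averaged
# map (m x (n+1)); the score is the row sum over real columns, so the
# gradient is constant across real columns and zero on the pseudo column.
attention_loss_grad <- function(map, labels, scale = 1) {
  w <- map$weights
  m <- nrow(w); nk <- ncol(w)
  s <- nci_scores(map)
  sc <- pmin(pmax(s, BCE_EPS), 1 - BCE_EPS)
  ds <- ifelse(s > BCE_EPS & s < 1 - BCE_EPS,
               (-labels / sc + (1 - labels) / (1 - sc)) / m, 0)
  g <- matrix(ds, m, nk)
  g[, nk] <- 0
  g * scale
}

#' Affinity loss (mean squared error)
#'
#' @param yhat,y numeric vectors of equal, positive length.
#' @return mean squared error.
#' @export
affinity_loss <- function(yhat, y) {
  if (length(yhat) == 0L) stop("empty batch")
  if (length(yhat) != length(y)) stop("length mismatch")
  mean((yhat - y)^2)
}

#' Total training loss
#'
#' `l1 + alpha * l2`. With `alpha = 0` the total is exactly the affinity
#' loss (the "remove L2" ablation). Instances without NCI labels contribute
#' no `l2` term; the training engine passes `l2 = 0` for them.
#'
#' @param l1 affinity loss.
#' @param l2 attention-regularization loss.
#' @param alpha nonnegative coefficient.
#' @return scalar total loss.
#' @export
total_loss <- function(l1, l2, alpha) {
  if (alpha < 0) stop("alpha must be >= 0")
  if (alpha == 0) return(l1)
  l1 + alpha * l2
}

#' Regression metrics
#'
#' Root mean squared error, mean absolute error and Pearson correlation.
#'
#' @param yhat predicted values.
#' @param y observed values (length >= 2 with nonzero variance for the
#'   correlation).
#' @return named list with `rmse`, `mae`, `pcorr`.
#' @export
regression_metrics <- function(yhat, y) {
  if (length(yhat) != length(y)) stop("length mismatch")
  if (length(y) < 2L) stop("need at least 2 observations")
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0)
    stop("undefined correlation: zero-variance input")
  list(rmse = sqrt(mean((yhat - y)^2)),
       mae = mean(abs(yhat - y)),
       pcorr = stats::cor(yhat, y))
}

#' Concordance index
#'
#' Over all pairs with distinct observed values, the fraction whose
#' predicted ordering agrees with the observed ordering; prediction ties
#' count 1/2.
#'
#' @param yhat predicted values.
#' @param y observed values.
#' @return scalar in `[0, 1]`.
#' @export
concordance_index <- function(yhat, y) {
  if (length(yhat) != length(y)) stop("length mismatch")
  if (length(y) < 2L) stop("need at least 2 observations")
  dy <- outer(y, y, ">")             # comparable ordered pairs (i > j)
  if (!any(dy)) stop("no comparable pairs: all observed values equal")
  dyh <- outer(yhat, yhat, "-")
  conc <- sum(dy & dyh > 0) + 0.5 * sum(dy & dyh == 0)
  conc / sum(dy)
}

#' Residue-level explainability AUROC
#'
#' Pools per-residue NCI scores and binary labels across instances and
#' computes the area under the ROC curve, quantifying how well attention
#' mass on real substructures identifies interacting residues.
#'
#' @param scores numeric vector (or list of vectors) of NCI scores.
#' @param labels binary vector (or list of vectors) of NCI labels.
#' @return AUROC in `[0, 1]`.
#' @export
residue_auroc <- function(scores, labels) {
  if (is.list(scores)) scores <- unlist(scores, use.names = FALSE)
  if (is.list(labels)) labels <- unlist(labels, use.names = FALSE)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (length(unique(labels)) < 2L)
    stop("single-class labels: AUROC undefined")
  as.numeric(pROC::auc(response = labels, predictor = scores,
                       levels = c(0, 1), direction = "<", quiet = TRUE))
}
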