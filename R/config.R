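#' Model and training configuration
#'
#' Collects every architecture and optimization hyperparameter in one
#' validated list. Defaults follow the published model: base embedding
#' dimension `d = 320`, 4 additive-attention heads, `u = 2` pooling seed
#' vectors, Adam with weight decay 0, batch size 64, at most 100 epochs with
#' early stopping. The learning rate and the auxiliary-loss coefficient
#' `alpha` depend on the measurement type of the training data: Ki/Kd
#' ("KIKD") runs use `lr = 5e-5`, `alpha = 5`; IC50 runs use `lr = 1e-4`,
#' `alpha = 1`. Either can be overridden explicitly.
#'
#' @param d embedding dimension shared by residues, substructures and the
#'   complex embedding. Must be divisible by `heads`.
#' @param heads number of attention heads.
#' @param u number of trainable seed vectors in the attention pooling layer.
#' @param measurement `"KIKD"` or `"IC50"`; selects the published defaults
#'   for `alpha` and `lr`.
#' @param alpha nonnegative coefficient of the attention-regularization loss
#'   (`alpha = 0` disables it, the "remove L2" ablation).
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience in epochs (validation RMSE).
#' @param dropout_rate dropout probability in the affinity head.
#' @param rff_hidden_dim hidden width of the row-wise feed-forward layers;
#'   defaults to `d`.
#' @param radius circular-fingerprint radius (2 = ECFP4-equivalent).
#' @param n_bits fingerprint length; fixed at 1024 by the architecture
#'   (the substructure vocabulary has exactly 1024 rows).
#' @param vocab_size substructure vocabulary size, equal to `n_bits`.
#' @param positional add fixed sinusoidal positional features to the
#'   fallback protein encoder's residue embeddings.
#' @param freeze_encoder if `TRUE` the protein encoder receives no gradient
#'   updates (the "freeze encoder" ablation).
#' @param strict_eq7 if `TRUE` (default) use the residual wiring exactly as
#'   printed in the source architecture: `H = LN(R + RFF1(MultiAttn(R, S+,
#'   S+)))`, `R* = LN(H + RFF2(R))`. If `FALSE`, use the standard multihead
#'   attention block wiring `H = LN(R + MultiAttn(...))`, `R* = LN(H +
#'   RFF1(H))`.
#' @param seed integer seed controlling initialization and all training
#'   randomness.
#' @return an object of class `"dta_config"` (a validated named list).
#' @export
#' @examples
#' cfg <- dta_config(d = 16, heads = 4, max_epochs = 2)
#' cfg$alpha
dta_config <- function(d = 320L, heads = 4L, u = 2L,
                       measurement = c("KIKD", "IC50"),
                       alpha = NULL, lr = NULL,
                       batch_size = 64L, max_epochs = 100L, patience = 10L,
                       dropout_rate = 0.1, rff_hidden_dim = NULL,
                       radius = 2L, n_bits = 1024L, vocab_size = n_bits,
                       positional = TRUE, freeze_encoder = FALSE,
                       strict_eq7 = TRUE, seed = 1L) {
  measurement <- match.arg(measurement)
  if (is.null(alpha)) alpha <- if (measurement == "KIKD") 5.0 else 1.0
  if (is.null(lr)) lr <- if (measurement == "KIKD") 5e-5 else 1e-4
  if (is.null(rff_hidden_dim)) rff_hidden_dim <- d
  d <- as.integer(d); heads <- as.integer(heads); u <- as.integer(u)
  if (d %% heads != 0L)
    stop("config error: embedding dimension d (", d,
         ") must be divisible by the number of heads (", heads, ")")
  if (u < 1L) stop("config error: u must be >= 1")
  if (alpha < 0) stop("config error: alpha must be >= 0")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("config error: dropout_rate must be in [0, 1)")
  if (n_bits != vocab_size)
    stop("config error: vocab_size must equal n_bits")
  cfg <- list(d = d, heads = heads, dh = d %/% heads, u = u,
              measurement = measurement, alpha = alpha, lr = lr,
              batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience),
              dropout_rate = dropout_rate,
              rff_hidden_dim = as.integer(rff_hidden_dim),
              radius = as.integer(radius), n_bits = as.integer(n_bits),
              vocab_size = as.integer(vocab_size),
              positional = isTRUE(positional),
              freeze_encoder = isTRUE(freeze_encoder),
              strict_eq7 = isTRUE(strict_eq7), seed = as.integer(seed))
  class(cfg) <- "dta_config"
  cfg
}

#' Read a configuration from a YAML file
#'
#' Unknown keys are rejected so typos in config files fail loudly.
#'
#' @param path path to a YAML file whose keys are `dta_config()` arguments.
#' @return a `"dta_config"` object.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(dta_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(dta_config, vals)
}

#' @export
print.dta_config <- function(x, ...) {
  cat("DTA model configuration\n")
  cat(sprintf("  d=%d heads=%d (dh=%d) u=%d rff=%d\n",
              x$d, x$heads, x$dh, x$u, x$rff_hidden_dim))
  cat(sprintf("  measurement=%s alpha=%g lr=%g batch=%d epochs<=%d patience=%d\n",
              x$measurement, x$alpha, x$lr, x$batch_size, x$max_epochs,
              x$patience))
  cat(sprintf("  dropout=%g fingerprint: %d bits radius %d\n",
              x$dropout_rate, x$n_bits, x$radius))
  cat(sprintf("  positional=%s freeze_encoder=%s strict_eq7=%s seed=%d\n",
              x$positional, x$freeze_encoder, x$strict_eq7, x$seed))
  invisible(x)
}
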