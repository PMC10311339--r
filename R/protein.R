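# Protein records and pluggable residue encoders.
#
# The published model embeds residues with a pretrained protein language
# model (ESM-2 8M: 6 layers, hidden size 320, matching d = 320). No such
# runtime exists here, so the encoder is pluggable:
#   * encoder_fallback(): a trainable 21-symbol embedding table (20 amino
#     acids + X) with optional fixed sinusoidal positional features; trained
#     jointly with the rest of the network.
#   * encoder_precomputed(): residue-embedding matrices computed offline by
#     a language model and supplied per protein id.
#   * encoder_plm(): the language-model adapter slot; without an embedding
#     source it raises a capability error pointing at the alternatives.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Create a protein record
#'
#' @param protein_id identifier string.
#' @param sequence amino-acid sequence over the 20 canonical letters plus
#'   `X` for unknown residues.
#' @return object of class `"protein_record"` with fields `protein_id`,
#'   `sequence`, `m` (residue count) and `res_tok` (integer tokens 1..21).
#' @export
protein_record <- function(protein_id, sequence) {
  sequence <- toupper(as.character(sequence))
  if (is.na(sequence) || nchar(sequence) < 1L)
    stop("validation error: empty protein sequence for ", protein_id)
  letters_ <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  tok <- match(letters_, AA_ALPHABET)
  if (anyNA(tok))
    stop("validation error: sequence of ", protein_id,
         " contains disallowed characters: ",
         paste(unique(letters_[is.na(tok)]), collapse = ""))
  structure(list(protein_id = protein_id, sequence = sequence,
                 m = length(tok), res_tok = tok),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("protein %s: %d residues\n", x$protein_id, x$m))
  invisible(x)
}

#' Trainable fallback residue encoder
#'
#' A learned 21-symbol embedding table plus optional fixed sinusoidal
#' positional features. This desk-scale encoder stands in for the protein
#' language model so that the full pipeline trains on CPU with no external
#' weights.
#'
#' @param d embedding dimension.
#' @param positional add sinusoidal positional features.
#' @param seed seed for table initialization.
#' @param always_trainable if `TRUE` the encoder ignores
#'   [set_encoder_trainable()] requests to freeze it.
#' @return an encoder handle (class `"dta_encoder"`).
#' @export
encoder_fallback <- function(d, positional = TRUE, seed = 1L,
                             always_trainable = FALSE) {
  old <- .Random.seed_save()
  set.seed(seed)
  table <- matrix(stats::rnorm(21L * d, sd = 0.2), 21L, d,
                  dimnames = list(AA_ALPHABET, NULL))
  .Random.seed_restore(old)
  structure(list(type = "fallback", d = as.integer(d),
                 positional = isTRUE(positional), table = table,
                 trainable = TRUE,
                 always_trainable = isTRUE(always_trainable)),
            class = "dta_encoder")
}

#' Precomputed residue-embedding encoder
#'
#' Serves residue embeddings computed offline (for example by a protein
#' language model) and supplied as one `m x d` matrix per protein id.
#'
#' @param embeddings named list of numeric matrices keyed by protein id.
#' @return an encoder handle.
#' @export
encoder_precomputed <- function(embeddings) {
  stopifnot(is.list(embeddings), !is.null(names(embeddings)))
  d <- unique(vapply(embeddings, ncol, 1L))
  if (length(d) != 1L)
    stop("all precomputed embedding matrices must share one dimension")
  structure(list(type = "precomputed", d = as.integer(d),
                 embeddings = embeddings, trainable = FALSE,
                 always_trainable = FALSE),
            class = "dta_encoder")
}

#' Protein language model adapter slot
#'
#' Placeholder handle for a pretrained protein language model (the published
#' configuration: ESM-2 8M, 6 layers, hidden size 320). No language-model
#' runtime ships with this package, so embedding through this handle raises
#' a capability error unless a checkpoint-derived embedding source is
#' attached; use [encoder_precomputed()] for offline embeddings or
#' [encoder_fallback()] for the trainable desk-scale encoder.
#'
#' @param checkpoint_path optional path to exported per-protein embeddings
#'   (an `.rds` named list of matrices); if supplied, behaves like
#'   [encoder_precomputed()].
#' @return an encoder handle.
#' @export
encoder_plm <- function(checkpoint_path = NULL) {
  if (!is.null(checkpoint_path)) {
    if (!file.exists(checkpoint_path))
      stop("capability error: no language-model weights/embeddings found at '",
           checkpoint_path, "'; use encoder_fallback() or supply ",
           "precomputed embeddings via encoder_precomputed()")
    emb <- readRDS(checkpoint_path)
    enc <- encoder_precomputed(emb)
    enc$type <- "plm"
    return(enc)
  }
  structure(list(type = "plm", d = NA_integer_, embeddings = NULL,
                 trainable = FALSE, always_trainable = FALSE),
            class = "dta_encoder")
}

#' Embed a protein's residues
#'
#' @param p a [protein_record()].
#' @param encoder an encoder handle.
#' @return an `m x d` matrix, one row per residue (no special tokens).
#' @export
embed_residues <- function(p, encoder) {
  stopifnot(inherits(p, "protein_record"), inherits(encoder, "dta_encoder"))
  switch(encoder$type,
    fallback = {
      R0 <- encoder$table[p$res_tok, , drop = FALSE]
      if (encoder$positional) R0 <- R0 + pos_encoding(p$m, encoder$d)
      rownames(R0) <- NULL
      R0
    },
    precomputed = ,
    plm = {
      if (is.null(encoder$embeddings))
        stop("capability error: the language-model adapter has no weights ",
             "on disk; use encoder_fallback() (trainable desk-scale ",
             "encoder) or encoder_precomputed()")
      R0 <- encoder$embeddings[[p$protein_id]]
      if (is.null(R0))
        stop("no precomputed embeddings for protein ", p$protein_id)
      if (nrow(R0) != p$m)
        stop("validation error: embeddings for ", p$protein_id, " have ",
             nrow(R0), " rows for ", p$m, " residues")
      R0
    },
    stop("unknown encoder type: ", encoder$type))
}

#' Toggle encoder trainability
#'
#' With `trainable = FALSE` the training engine leaves the encoder's
#' parameters untouched (the "freeze encoder" ablation). Fallback encoders
#' created with `always_trainable = TRUE` ignore freezing requests.
#'
#' @param encoder an encoder handle.
#' @param trainable logical.
#' @return the updated encoder handle.
#' @export
set_encoder_trainable <- function(encoder, trainable) {
  stopifnot(inherits(encoder, "dta_encoder"))
  if (encoder$type != "fallback") {
    encoder$trainable <- FALSE
    return(encoder)
  }
  if (encoder$always_trainable && !trainable) return(encoder)
  encoder$trainable <- isTRUE(trainable)
  encoder
}

# save/restore the global RNG state so constructors are seed-transparent
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
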