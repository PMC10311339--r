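# Attention-map extraction, truncation and export for qualitative
# inspection of which residues attend to which chemical substructures.

#' Extract the attention map for one instance
#'
#' Single evaluation-mode forward pass. Substructure columns are annotated
#' with fragment strings when the ligand has a real molecule behind it.
#'
#' @param fit a `"dta_fit"`.
#' @param instance an [affinity_instance()].
#' @return list with `map` (an [attention_map()]), `scores` (per-residue
#'   NCI scores), `yhat`, and `annotations` (substructure fragment strings
#'   or bit labels).
#' @export
extract_map <- function(fit, instance) {
  stopifnot(inherits(fit, "dta_fit"), inherits(instance, "affinity_instance"))
  R0 <- encoder_R0(fit$params, fit$config, fit$encoder,
                   instance$protein$res_tok, instance$protein)
  fw <- forward_instance(fit$params, fit$config, R0,
                         instance$substructures$indices,
                         residue_ids = strsplit(instance$protein$sequence,
                                                "")[[1L]])
  s <- instance$substructures
  ann <- if (!is.null(s$provenance)) {
    vapply(s$indices, function(b)
      tryCatch(describe_bit(b, s), error = function(e) paste0("bit", b)), "")
  } else paste0("bit", s$indices)
  list(map = fw$map, scores = nci_scores(fw$map), yhat = fw$yhat,
       annotations = ann)
}

#' Truncate an attention map to informative residues
#'
#' Drops residues deemed negative on BOTH criteria: NCI score below the
#' threshold AND label 0 (or absent). A residue is retained if its score
#' passes the threshold or its label is 1; when no labels are given the
#' score criterion alone applies. Retained residues keep their original
#' 1-based positions; retained weights are unchanged.
#'
#' @param map an [attention_map()].
#' @param scores per-residue NCI scores ([nci_scores()]).
#' @param labels optional binary NCI label vector.
#' @param threshold score threshold in (0, 1); 0.5 (the BCE decision
#'   boundary) by default.
#' @return list with `map` (reduced), `positions` (1-based retained
#'   positions), `scores`, `labels` (or `NULL`).
#' @export
truncate_map <- function(map, scores, labels = NULL, threshold = 0.5) {
  stopifnot(inherits(map, "attention_map"), threshold > 0, threshold < 1)
  m <- nrow(map$weights)
  if (length(scores) != m) stop("scores/map size mismatch")
  lab <- if (is.null(labels)) rep(0L, m) else as.integer(labels)
  keep <- which(scores >= threshold | lab == 1L)
  if (!length(keep))
    warning("all residues negative on both criteria: empty truncated map")
  red <- map
  red$weights <- map$weights[keep, , drop = FALSE]
  red$per_head <- map$per_head[, keep, , drop = FALSE]
  red$residue_ids <- map$residue_ids[keep]
  list(map = red, positions = keep, scores = scores[keep],
       labels = if (is.null(labels)) NULL else lab[keep])
}

#' Export an attention map
#'
#' Writes (a) a TSV in the transposed inspection layout — one row per
#' substructure annotation plus an "NCI Score" row and, when labels are
#' given, an "Actual NCI Label" row; columns are residues headed by their
#' amino-acid letter and 1-based position — and (b) a JSON file with the
#' full-precision weights; optionally (c) a heatmap PNG.
#'
#' @param map an [attention_map()] (possibly truncated).
#' @param path output stem; writes `<path>.tsv` and `<path>.json` (and
#'   `<path>.png` if `heatmap = TRUE`).
#' @param scores per-residue NCI scores aligned with the map rows.
#' @param labels optional aligned binary labels.
#' @param annotations optional substructure annotations (length `n`).
#' @param positions 1-based residue positions (defaults to `1:m`).
#' @param heatmap also render a PNG heatmap.
#' @return invisible character vector of written files.
#' @export
export_map <- function(map, path, scores = nci_scores(map), labels = NULL,
                       annotations = NULL, positions = NULL,
                       heatmap = FALSE) {
  stopifnot(inherits(map, "attention_map"))
  w <- map$weights
  m <- nrow(w); nk <- ncol(w); n <- nk - 1L
  if (m == 0L) stop("map is empty")
  if (is.null(positions)) positions <- seq_len(m)
  letters_ <- map$residue_ids %||% rep("?", m)
  headers <- paste0(letters_, positions)
  ann <- annotations %||%
    (if (!is.null(map$substructure_indices))
      paste0("bit", map$substructure_indices) else paste0("sub", seq_len(n)))
  rows <- rbind(t(w[, seq_len(n), drop = FALSE]),
                `NCI Score` = scores,
                if (!is.null(labels)) rbind(`Actual NCI Label` = labels))
  rownames(rows)[seq_len(n)] <- ann
  df <- data.frame(substructure = rownames(rows), rows, check.names = FALSE)
  colnames(df) <- c("substructure", headers)
  tsv <- paste0(path, ".tsv")
  dir.create(dirname(tsv), showWarnings = FALSE, recursive = TRUE)
  ok <- tryCatch({
    utils::write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) stop("I/O error writing '", tsv, "': ",
                              conditionMessage(e)))
  json <- paste0(path, ".json")
  jsonlite::write_json(
    list(weights = w, per_head = map$per_head, scores = scores,
         labels = labels, positions = positions, residues = letters_,
         substructure_indices = map$substructure_indices,
         annotations = ann, pseudo_column = map$pseudo_column),
    json, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  files <- c(tsv, json)
  if (heatmap) {
    png <- paste0(path, ".png")
    grDevices::png(png, width = 120 + 28 * m, height = 120 + 22 * nk)
    graphics::image(seq_len(m), seq_len(nk), w, xlab = "residue",
                    ylab = "substructure key",
                    main = "residue-to-substructure attention",
                    col = grDevices::hcl.colors(64, "YlGn", rev = TRUE),
                    axes = FALSE)
    graphics::axis(1, at = seq_len(m), labels = headers, las = 2,
                   cex.axis = 0.7)
    graphics::axis(2, at = seq_len(nk), labels = c(ann, "pseudo"), las = 2,
                   cex.axis = 0.7)
    grDevices::dev.off()
    files <- c(files, png)
  }
  invisible(files)
}

#' Read back an exported attention map JSON
#'
#' @param path the `.json` file written by [export_map()].
#' @return list with full-precision `weights` and the other exported
#'   fields.
#' @export
read_map_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$weights <- matrix(as.numeric(x$weights), nrow = nrow(x$weights))
  x
}
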