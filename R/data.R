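# Dataset curation, affinity normalization, NCI-label conversion, splitting
# and batch collation.

#' Construct an affinity instance
#'
#' One (protein, ligand, log-affinity, measurement, optional residue NCI
#' labels) record.
#'
#' @param protein a [protein_record()] (at most 1000 residues).
#' @param substructures a `"substructure_set"`.
#' @param y log-space affinity (pK units: `-log10` of the molar value).
#' @param measurement `"Ki"`, `"Kd"` or `"IC50"`.
#' @param nci_labels optional binary vector of length `protein$m`.
#' @param ligand_id optional ligand identifier.
#' @return object of class `"affinity_instance"`.
#' @export
affinity_instance <- function(protein, substructures, y,
                              measurement = c("Ki", "Kd", "IC50"),
                              nci_labels = NULL,
                              ligand_id = substructures$ligand_id) {
  measurement <- match.arg(measurement)
  stopifnot(inherits(protein, "protein_record"),
            inherits(substructures, "substructure_set"))
  if (protein$m > 1000L)
    stop("invariant violation: protein exceeds 1000 residues")
  if (!is.finite(y)) stop("invariant violation: non-finite affinity")
  if (!is.null(nci_labels)) {
    if (length(nci_labels) != protein$m)
      stop("invariant violation: ", length(nci_labels),
           " NCI labels for ", protein$m, " residues")
    if (!all(nci_labels %in% c(0, 1))) stop("NCI labels must be binary")
    nci_labels <- as.integer(nci_labels)
  }
  structure(list(protein = protein, substructures = substructures,
                 ligand_id = ligand_id, y = as.numeric(y),
                 measurement = measurement, nci_labels = nci_labels),
            class = "affinity_instance")
}

#' @export
print.affinity_instance <- function(x, ...) {
  cat(sprintf("instance %s x %s: m=%d n=%d y=%.3f (%s)%s\n",
              x$protein$protein_id, x$ligand_id, x$protein$m,
              x$substructures$n, x$y, x$measurement,
              if (is.null(x$nci_labels)) "" else
                sprintf(", %d/%d NCI residues", sum(x$nci_labels),
                        x$protein$m)))
  invisible(x)
}

#' Normalize an affinity measurement to log space
#'
#' Converts the value to molar and returns the pK transform
#' `-log10(molar)`, so larger values mean tighter binding (1 nM -> 9).
#' Unit `"pK"` marks values that are already in log space and are passed
#' through unchanged.
#'
#' @param value positive numeric measurement.
#' @param unit one of `"M"`, `"mM"`, `"uM"` (or `"µM"`), `"nM"`,
#'   `"pM"`, or `"pK"`.
#' @return log-space affinity.
#' @export
#' @examples
#' normalize_affinity(1, "uM")  # 6
normalize_affinity <- function(value, unit) {
  if (unit == "pK") return(as.numeric(value))
  factors <- c(M = 1, mM = 1e-3, uM = 1e-6, "µM" = 1e-6, nM = 1e-9,
               pM = 1e-12)
  if (!unit %in% names(factors)) stop("unknown unit: ", unit)
  value <- as.numeric(value)
  if (!is.finite(value) || value <= 0)
    stop("affinity value must be a positive number")
  -log10(value * factors[[unit]])
}

INEQUALITY_RE <- "[<>~≤≥]"

#' Curate a raw affinity table into instances
#'
#' Applies the published curation filters: proteins longer than 1000
#' residues and measurements whose value is an inequality (e.g. ">50000")
#' are rejected; ligands that fail to parse or produce an empty fingerprint
#' are rejected. Sequence letters outside the 20 canonical amino acids are
#' mapped to `X` before validation.
#'
#' @param raw data frame with columns `protein_id`, `sequence`,
#'   `ligand_id`, `smiles`, `value`, `unit`, `measurement`; an optional
#'   `substructure_indices` column (comma-separated bit indices) bypasses
#'   SMILES featurization (synthetic ligands).
#' @param radius,n_bits fingerprint parameters.
#' @return list with `instances` (accepted [affinity_instance()]s) and
#'   `rejections` (data frame `row`, `protein_id`, `ligand_id`, `reason`
#'   with machine-readable codes `TOO_LONG`, `INEXACT_VALUE`, `BAD_SMILES`,
#'   `NO_BITS`).
#' @export
curate <- function(raw, radius = 2L, n_bits = 1024L) {
  stopifnot(is.data.frame(raw))
  instances <- list()
  rej <- list()
  fp_cache <- new.env(parent = emptyenv())
  has_idx <- "substructure_indices" %in% names(raw)
  for (i in seq_len(nrow(raw))) {
    r <- raw[i, ]
    reject <- function(code)
      rej[[length(rej) + 1L]] <<- data.frame(
        row = i, protein_id = r$protein_id, ligand_id = r$ligand_id,
        reason = code, stringsAsFactors = FALSE)
    seq_clean <- gsub(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"),
                      "X", toupper(r$sequence))
    if (nchar(seq_clean) > 1000L) { reject("TOO_LONG"); next }
    vs <- trimws(as.character(r$value))
    if (grepl(INEQUALITY_RE, vs) || is.na(suppressWarnings(as.numeric(vs)))) {
      reject("INEXACT_VALUE"); next
    }
    subs <- NULL
    if (has_idx && !is.na(r$substructure_indices) &&
        nzchar(r$substructure_indices)) {
      subs <- substructure_set(
        as.integer(strsplit(r$substructure_indices, ",")[[1L]]),
        ligand_id = r$ligand_id, n_bits = n_bits)
    } else {
      key <- r$smiles
      if (!is.null(fp_cache[[key]])) {
        subs <- fp_cache[[key]]
      } else {
        subs <- tryCatch(
          smiles_to_substructure_indices(r$smiles, radius = radius,
                                         n_bits = n_bits,
                                         ligand_id = r$ligand_id),
          error = function(e) {
            if (grepl("zero set fingerprint bits", conditionMessage(e)))
              "NO_BITS" else "BAD_SMILES"
          })
        if (is.character(subs)) { reject(subs); next }
        fp_cache[[key]] <- subs
      }
      subs$ligand_id <- r$ligand_id
    }
    meas <- if (toupper(r$measurement) == "IC50") "IC50" else
      c(Ki = "Ki", KI = "Ki", Kd = "Kd", KD = "Kd")[[r$measurement]]
    inst <- affinity_instance(
      protein_record(r$protein_id, seq_clean), subs,
      y = normalize_affinity(as.numeric(vs), r$unit),
      measurement = meas, ligand_id = r$ligand_id)
    instances[[length(instances) + 1L]] <- inst
  }
  list(instances = instances,
       rejections = if (length(rej)) do.call(rbind, rej) else
         data.frame(row = integer(0), protein_id = character(0),
                    ligand_id = character(0), reason = character(0)))
}

#' Pairwise residue-by-atom NCI matrix (sparse)
#'
#' The interaction-profiler output format: positive (residue, atom) pairs
#' of any NCI type, 0-based.
#'
#' @param m number of protein residues.
#' @param n_atoms number of ligand atoms.
#' @param positive_pairs data frame (or 2-column matrix) of 0-based
#'   `residue_index`, `atom_index` pairs.
#' @return object of class `"pairwise_nci_matrix"`.
#' @export
pairwise_nci_matrix <- function(m, n_atoms, positive_pairs) {
  pp <- as.data.frame(positive_pairs)
  if (ncol(pp) >= 2L) names(pp)[1:2] <- c("residue_index", "atom_index")
  else if (nrow(pp) == 0L)
    pp <- data.frame(residue_index = integer(0), atom_index = integer(0))
  if (nrow(pp)) {
    if (any(pp$residue_index < 0L) || any(pp$residue_index >= m) ||
        any(pp$atom_index < 0L) || any(pp$atom_index >= n_atoms))
      stop("invariant violation: NCI pair index out of range")
    if (anyDuplicated(pp[, c("residue_index", "atom_index")]))
      stop("invariant violation: duplicate NCI pairs")
  }
  structure(list(m = as.integer(m), n_atoms = as.integer(n_atoms),
                 positive_pairs = pp),
            class = "pairwise_nci_matrix")
}

#' Collapse a pairwise NCI matrix to residue labels
#'
#' A residue is labeled 1 if it has an NCI of any type with at least one
#' ligand atom.
#'
#' @param mat a [pairwise_nci_matrix()].
#' @return integer 0/1 vector of length `mat$m`.
#' @export
#' @examples
#' mat <- pairwise_nci_matrix(2, 3, data.frame(residue_index = 0,
#'                                             atom_index = 1))
#' pairwise_to_residue_labels(mat)  # c(1, 0)
pairwise_to_residue_labels <- function(mat) {
  stopifnot(inherits(mat, "pairwise_nci_matrix"))
  labels <- integer(mat$m)
  if (nrow(mat$positive_pairs))
    labels[unique(mat$positive_pairs$residue_index) + 1L] <- 1L
  labels
}

.new_split_plan <- function(folds, seed, n) {
  structure(list(k = length(folds), folds = folds, seed = seed, n = n),
            class = "split_plan")
}

#' k-fold split plan
#'
#' Randomly partitions instances into `k` test folds; within each fold,
#' `val_frac` of the non-test instances form the validation set (at least
#' one) and the rest train. Deterministic under `seed`. When instances with
#' ligand SMILES are supplied, each fold also records the test instances
#' whose Bemis-Murcko scaffold appears in no training ligand
#' (`unseen_scaffold`).
#'
#' @param x list of [affinity_instance()]s, or an integer instance count.
#' @param k number of folds.
#' @param val_frac validation fraction of the non-test instances.
#' @param seed integer seed.
#' @return object of class `"split_plan"`: per-fold integer index vectors
#'   `train`, `val`, `test` and optionally `unseen_scaffold`.
#' @export
make_folds <- function(x, k = 5L, val_frac = 0.05, seed = 1L) {
  n <- if (is.numeric(x) && length(x) == 1L) as.integer(x) else length(x)
  if (n < k) stop("too few instances (", n, ") for ", k, " folds")
  old <- .Random.seed_save()
  set.seed(seed)
  perm <- sample.int(n)
  .Random.seed_restore(old)
  # deterministic assignment: fold sizes as equal as possible
  grp <- integer(n)
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  grp[perm] <- rep(seq_len(k), times = sizes)
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    test <- which(grp == f)
    rest <- perm[!perm %in% test]
    nv <- max(1L, floor(val_frac * length(rest)))
    val <- rest[seq_len(nv)]
    train <- setdiff(rest, val)
    folds[[f]] <- list(train = sort(train), val = sort(val),
                       test = sort(test))
  }
  plan <- .new_split_plan(folds, seed, n)
  if (is.list(x)) plan <- add_unseen_scaffolds(plan, x)
  plan
}

#' Single holdout split
#'
#' `test_frac` of the instances form the test set; `val_frac` of the
#' remainder form validation; the rest train.
#'
#' @inheritParams make_folds
#' @param test_frac test fraction.
#' @return a `"split_plan"` with one fold.
#' @export
holdout_split <- function(x, test_frac = 0.2, val_frac = 0.05, seed = 1L) {
  n <- if (is.numeric(x) && length(x) == 1L) as.integer(x) else length(x)
  if (n < 3L) stop("too few instances to split")
  old <- .Random.seed_save()
  set.seed(seed)
  perm <- sample.int(n)
  .Random.seed_restore(old)
  nt <- max(1L, floor(test_frac * n))
  test <- perm[seq_len(nt)]
  rest <- perm[(nt + 1L):n]
  nv <- max(1L, floor(val_frac * length(rest)))
  val <- rest[seq_len(nv)]
  train <- rest[-seq_len(nv)]
  plan <- .new_split_plan(list(list(train = sort(train), val = sort(val),
                                    test = sort(test))), seed, n)
  if (is.list(x)) plan <- add_unseen_scaffolds(plan, x)
  plan
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split plan: %d instances, %d fold(s), seed %d\n",
              x$n, x$k, x$seed))
  for (f in seq_len(x$k))
    cat(sprintf("  fold %d: train %d / val %d / test %d%s\n", f,
                length(x$folds[[f]]$train), length(x$folds[[f]]$val),
                length(x$folds[[f]]$test),
                if (!is.null(x$folds[[f]]$unseen_scaffold))
                  sprintf(" (unseen scaffold: %d)",
                          length(x$folds[[f]]$unseen_scaffold)) else ""))
  invisible(x)
}

#' Test instances with ligand scaffolds unseen in training
#'
#' Returns the test instances whose ligand's Bemis-Murcko scaffold string
#' (canonical, stereo-stripped) matches no training ligand's scaffold.
#' Instances without SMILES are never deemed unseen.
#'
#' @param test,train lists of [affinity_instance()]s.
#' @return the qualifying subset of `test`.
#' @export
unseen_scaffold_subset <- function(test, train) {
  cache <- new.env(parent = emptyenv())
  scaf <- function(inst) {
    smi <- inst$substructures$smiles
    if (is.na(smi)) return(NA_character_)
    if (is.null(cache[[smi]])) cache[[smi]] <- murcko_scaffold(smi)
    cache[[smi]]
  }
  train_scafs <- unique(vapply(train, scaf, ""))
  keep <- vapply(test, function(inst) {
    s <- scaf(inst)
    !is.na(s) && !(s %in% train_scafs)
  }, TRUE)
  test[keep]
}

#' Attach unseen-scaffold subsets to a split plan
#'
#' @param plan a `"split_plan"`.
#' @param instances the instance list the plan indexes into.
#' @return the plan with per-fold `unseen_scaffold` index vectors.
#' @export
add_unseen_scaffolds <- function(plan, instances) {
  has_smiles <- any(vapply(instances,
                           function(i) !is.na(i$substructures$smiles), TRUE))
  if (!has_smiles) return(plan)
  for (f in seq_len(plan$k)) {
    te <- plan$folds[[f]]$test
    tr <- c(plan$folds[[f]]$train, plan$folds[[f]]$val)
    sub <- unseen_scaffold_subset(instances[te], instances[tr])
    ids <- vapply(sub, function(i)
      paste(i$protein$protein_id, i$ligand_id), "")
    all_ids <- vapply(instances[te], function(i)
      paste(i$protein$protein_id, i$ligand_id), "")
    plan$folds[[f]]$unseen_scaffold <- sort(te[all_ids %in% ids])
  }
  plan
}

#' Collate instances into a padded batch
#'
#' Pads residue tokens and substructure indices to the batch maxima and
#' records boolean masks marking real positions. Padded positions are
#' guaranteed not to affect predictions, attention on real positions, or
#' either loss term: the forward pass reads only the unmasked prefix of
#' every row (see [forward_collated()]).
#'
#' @param batch nonempty list of [affinity_instance()]s.
#' @return object of class `"dta_batch"`.
#' @export
collate <- function(batch) {
  if (!length(batch)) stop("empty batch")
  B <- length(batch)
  ms <- vapply(batch, function(i) i$protein$m, 1L)
  ns <- vapply(batch, function(i) i$substructures$n, 1L)
  max_m <- max(ms); max_n <- max(ns)
  res_tok <- matrix(0L, B, max_m)
  sub_idx <- matrix(-1L, B, max_n)
  res_mask <- matrix(FALSE, B, max_m)
  sub_mask <- matrix(FALSE, B, max_n)
  for (b in seq_len(B)) {
    res_tok[b, seq_len(ms[b])] <- batch[[b]]$protein$res_tok
    res_mask[b, seq_len(ms[b])] <- TRUE
    sub_idx[b, seq_len(ns[b])] <- batch[[b]]$substructures$indices
    sub_mask[b, seq_len(ns[b])] <- TRUE
  }
  structure(list(B = B, res_tok = res_tok, res_mask = res_mask,
                 sub_idx = sub_idx, sub_mask = sub_mask,
                 y = vapply(batch, `[[`, 0, "y"),
                 labels = lapply(batch, `[[`, "nci_labels"),
                 instances = batch),
            class = "dta_batch")
}

#' Forward pass over a collated batch
#'
#' Runs the model on every instance of a padded batch using the masks to
#' recover the true lengths, so padded positions provably contribute
#' nothing.
#'
#' @param fit a fitted `"dta_fit"` model (or a bare parameter list plus
#'   config via the `params`/`config` arguments of the internal API).
#' @param batch a `"dta_batch"` from [collate()].
#' @return list with `yhat` (length `B`), `maps` (attention maps), `l1`
#'   (MSE against the batch affinities) and `l2` (mean
#'   attention-regularization loss over labeled instances, `NA` if none).
#' @export
forward_collated <- function(fit, batch) {
  stopifnot(inherits(batch, "dta_batch"))
  par <- fit$params; cfg <- fit$config
  yhat <- numeric(batch$B)
  maps <- vector("list", batch$B)
  l2s <- c()
  for (b in seq_len(batch$B)) {
    tok <- batch$res_tok[b, batch$res_mask[b, ]]
    sub <- batch$sub_idx[b, batch$sub_mask[b, ]]
    R0 <- encoder_R0(par, cfg, fit$encoder, tok,
                     batch$instances[[b]]$protein)
    fw <- forward_instance(par, cfg, R0, sub)
    yhat[b] <- fw$yhat
    maps[[b]] <- fw$map
    lab <- batch$labels[[b]]
    if (!is.null(lab))
      l2s <- c(l2s, attention_regularization_loss(fw$map, lab))
  }
  list(yhat = yhat, maps = maps,
       l1 = affinity_loss(yhat, batch$y),
       l2 = if (length(l2s)) mean(l2s) else NA_real_)
}

# ---- file formats ----------------------------------------------------------

#' Read proteins from FASTA
#'
#' @param path FASTA file.
#' @return named list of [protein_record()]s.
#' @export
read_protein_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  recs <- lapply(seq_along(ss), function(i)
    protein_record(names(ss)[i], as.character(ss[[i]])))
  names(recs) <- names(ss)
  recs
}

#' Write proteins to FASTA
#'
#' @param records list of [protein_record()]s.
#' @param path output path.
#' @export
write_protein_fasta <- function(records, path) {
  ss <- Biostrings::AAStringSet(vapply(records, `[[`, "", "sequence"))
  names(ss) <- vapply(records, `[[`, "", "protein_id")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a raw affinity table (TSV)
#'
#' Columns: `protein_id`, `ligand_id`, `smiles`, `value`, `unit`,
#' `measurement` (and optionally `substructure_indices`).
#'
#' @param path TSV path.
#' @return data frame.
#' @export
read_affinity_table <- function(path)
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(value = "character"))

#' Read an NCI pair list (TSV)
#'
#' Columns: `instance_id`, `residue_index`, `atom_index`, `nci_type`
#' (0-based indices). The type is carried but collapsed to "any" when
#' converting to residue labels.
#'
#' @param path TSV path.
#' @return data frame.
#' @export
read_nci_pairs <- function(path)
  utils::read.delim(path, stringsAsFactors = FALSE)

#' Export a split plan to JSON
#'
#' @param plan a `"split_plan"`.
#' @param path output path.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(list(k = plan$k, seed = plan$seed, n = plan$n,
                            folds = plan$folds),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a split plan from JSON
#'
#' @param path JSON path written by [write_split_plan()].
#' @return a `"split_plan"`.
#' @export
read_split_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  folds <- lapply(seq_len(x$k), function(f) {
    fl <- lapply(x$folds[f, , drop = FALSE], function(col) col[[1]])
    lapply(fl, as.integer)
  })
  if (is.list(x$folds) && !is.data.frame(x$folds))
    folds <- lapply(x$folds, function(fl) lapply(fl, as.integer))
  .new_split_plan(folds, x$seed, x$n)
}
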