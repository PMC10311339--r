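# Synthetic protein-ligand worlds with planted residue-motif/substructure
# interaction rules.
#
# Each world holds a table of (amino-acid k-mer motif, substructure index)
# rules. An instance plants copies of each motif in a random sequence
# and samples a ligand substructure set that contains each rule's partner
# index with probability 1/2. A residue's NCI label is 1 exactly when it
# lies inside a planted motif whose partner substructure is present in the
# ligand, and the affinity is an affine function of the number of such
# active residues plus Gaussian noise. This gives the cross-attention a
# learnable residue<->substructure signal analogous to binding pockets, and
# ties the regression target to the same mechanism.
#
# Motifs are built from small per-rule letter sets (2 letters by default,
# disjoint across rules), and by default the background sequence is drawn
# from the REMAINING letters, so motif residues are identifiable from their
# identity — a toy analogue of the compositional bias of binding pockets.
# What remains to be learned is the conditional part: a motif residue is
# active only when its partner substructure is present in the ligand, which
# is exactly the residue<->substructure interaction the cross-attention must
# express. A uniform background (motif letters also appearing by chance
# outside motifs, i.e. label noise) is available via `background`.

#' Generate a synthetic interaction world
#'
#' @param n_motifs number of interaction rules.
#' @param seed integer seed.
#' @param base_affinity intercept of the affinity rule (pK units).
#' @param per_interaction_bonus affinity increment per active residue.
#' @param noise_sd standard deviation of the Gaussian affinity noise.
#' @param motif_lengths candidate motif lengths (within 3-6).
#' @param letters_per_motif size of the per-rule letter alphabet; small
#'   values make motif residues identifiable from their letter alone.
#' @param background `"reserved"` (default): background residues are drawn
#'   from the letters no motif uses, so motif membership is decidable from
#'   residue identity; `"uniform"`: background over all 20 letters, which
#'   adds label noise from chance motif-letter occurrences.
#' @param copy_probs probabilities of planting 0, 1, 2, ... copies of each
#'   motif per instance.
#' @param n_common_bits number of "scaffold" substructure indices shared by
#'   every generated ligand, emulating the ubiquitous fingerprint bits
#'   (phenyl, methyl, ...) that almost all drug-like molecules set.
#' @return object of class `"synthetic_world"` with the rule table and the
#'   affinity parameters.
#' @export
generate_world <- function(n_motifs = 8L, seed = 1L, base_affinity = 5,
                           per_interaction_bonus = 0.5, noise_sd = 0.25,
                           motif_lengths = 4:6, letters_per_motif = 2L,
                           background = c("reserved", "uniform"),
                           copy_probs = c(0.65, 0.35),
                           n_common_bits = 6L) {
  background <- match.arg(background)
  stopifnot(length(copy_probs) >= 1, all(copy_probs >= 0))
  if (n_motifs < 1L) stop("n_motifs must be >= 1")
  stopifnot(all(motif_lengths >= 3L), all(motif_lengths <= 6L),
            noise_sd >= 0)
  old <- .Random.seed_save()
  set.seed(seed)
  aa20 <- setdiff(AA_ALPHABET, "X")
  # disjoint small alphabets keep rules distinguishable at the residue level
  n_letters <- min(letters_per_motif, max(1L, 20L %/% n_motifs))
  pool <- sample(aa20)
  motifs <- character(n_motifs)
  for (r in seq_len(n_motifs)) {
    take <- pool[seq_len(n_letters)]
    pool <- c(pool[-seq_len(n_letters)], take)  # recycle if rules > 6
    len <- if (length(motif_lengths) == 1L) motif_lengths else
      sample(motif_lengths, 1L)
    repeat {
      motif <- paste(sample(take, len, replace = TRUE), collapse = "")
      if (!motif %in% motifs) break
    }
    motifs[r] <- motif
  }
  pick <- sample(0:1023, n_motifs + n_common_bits)
  sub_idx <- pick[seq_len(n_motifs)]
  common_bits <- sort(pick[-seq_len(n_motifs)])
  .Random.seed_restore(old)
  motif_letters <- sort(unique(unlist(strsplit(motifs, ""))))
  bg_letters <- if (background == "reserved" &&
                      length(setdiff(aa20, motif_letters)) >= 4L)
    setdiff(aa20, motif_letters) else aa20
  structure(list(motif_table = data.frame(motif = motifs,
                                          substructure_index = sub_idx,
                                          stringsAsFactors = FALSE),
                 base_affinity = base_affinity,
                 per_interaction_bonus = per_interaction_bonus,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 background = background, bg_letters = bg_letters,
                 copy_probs = copy_probs, common_bits = common_bits),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("synthetic world: %d rules, y = %.2f + %.2f * actives + N(0, %.2f)\n",
              nrow(x$motif_table), x$base_affinity,
              x$per_interaction_bonus, x$noise_sd))
  print(x$motif_table)
  invisible(x)
}

# plant `motif` at a free position; returns list(seq_letters, positions)
.plant <- function(seq_letters, occupied, motif) {
  lm <- nchar(motif)
  m <- length(seq_letters)
  if (lm > m) return(NULL)
  starts <- which(!vapply(seq_len(m - lm + 1L), function(s)
    any(occupied[s:(s + lm - 1L)]), TRUE))
  if (!length(starts)) return(NULL)
  s <- if (length(starts) == 1L) starts else sample(starts, 1L)
  span <- s:(s + lm - 1L)
  seq_letters[span] <- strsplit(motif, "")[[1L]]
  list(seq_letters = seq_letters, span = span)
}

#' Generate one synthetic affinity instance
#'
#' @param world a [generate_world()] world.
#' @param protein_len residue count (<= 1000).
#' @param n_substructures number of background substructure indices in the
#'   ligand (rule partners are added on top with probability 1/2 each).
#' @param id instance identifier stem.
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @return an [affinity_instance()] with NCI labels.
#' @export
generate_instance <- function(world, protein_len = 60L,
                              n_substructures = 40L, id = "syn",
                              seed = NULL) {
  stopifnot(inherits(world, "synthetic_world"), protein_len <= 1000L)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  bg_alpha <- world$bg_letters %||% setdiff(AA_ALPHABET, "X")
  letters_ <- sample(bg_alpha, protein_len, replace = TRUE)
  rules <- world$motif_table
  occupied <- logical(protein_len)
  planted <- vector("list", nrow(rules))
  for (r in seq_len(nrow(rules))) {
    cp <- world$copy_probs %||% c(0.65, 0.35)
    copies <- sample(seq_along(cp) - 1L, 1L, prob = cp)
    spans <- integer(0)
    for (cpy in seq_len(copies)) {
      pl <- .plant(letters_, occupied, rules$motif[r])
      if (is.null(pl)) break
      letters_ <- pl$seq_letters
      occupied[pl$span] <- TRUE
      spans <- c(spans, pl$span)
    }
    planted[[r]] <- spans
  }
  # ligand: shared scaffold bits, random background, and each rule partner
  # with probability 1/2
  present <- rules$substructure_index[stats::runif(nrow(rules)) < 0.5]
  common <- world$common_bits %||% integer(0)
  bg_pool <- setdiff(0:1023, c(rules$substructure_index, common))
  bg <- sample(bg_pool, n_substructures)
  indices <- sort(unique(c(common, bg, present)))
  labels <- integer(protein_len)
  for (r in seq_len(nrow(rules)))
    if (rules$substructure_index[r] %in% present && length(planted[[r]]))
      labels[planted[[r]]] <- 1L
  n_active <- sum(labels)
  y <- world$base_affinity + world$per_interaction_bonus * n_active +
    stats::rnorm(1L, 0, world$noise_sd)
  affinity_instance(
    protein_record(id, paste(letters_, collapse = "")),
    substructure_set(indices, ligand_id = paste0(id, "_lig")),
    y = y, measurement = "Kd", nci_labels = labels)
}

#' Generate a synthetic dataset
#'
#' @param world a [generate_world()] world.
#' @param n number of instances.
#' @param seed integer seed (reproducible).
#' @param protein_len_range residue-count range sampled per instance. The
#'   default is a fixed length (a controlled benchmark); configuring a wide
#'   range decorrelates the active-residue RATIO from affinity while the
#'   COUNT stays perfectly predictive.
#' @param n_substructures background ligand size.
#' @return list of [affinity_instance()]s.
#' @export
generate_dataset <- function(world, n, seed = 1L,
                             protein_len_range = c(60L, 60L),
                             n_substructures = 40L) {
  if (n < 1L) stop("n must be >= 1")
  old <- .Random.seed_save()
  set.seed(seed)
  lens <- sample(protein_len_range[1L]:protein_len_range[2L], n,
                 replace = TRUE)
  out <- lapply(seq_len(n), function(i)
    generate_instance(world, protein_len = lens[i],
                      n_substructures = n_substructures,
                      id = sprintf("syn%05d", i)))
  .Random.seed_restore(old)
  out
}

#' Write a dataset in the standard file layout
#'
#' Emits exactly what the loaders read: `proteins.fasta`, `affinity.tsv`
#' (protein_id, ligand_id, smiles, value, unit, measurement,
#' substructure_indices) and `nci_pairs.tsv` (instance_id, residue_index,
#' atom_index, nci_type; 0-based). Log-space affinities are written with
#' unit `"pK"` at full precision so the round trip is exact.
#'
#' @param instances list of [affinity_instance()]s.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(instances, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prots <- lapply(instances, `[[`, "protein")
  ids <- vapply(prots, `[[`, "", "protein_id")
  write_protein_fasta(prots[!duplicated(ids)],
                      file.path(dir, "proteins.fasta"))
  aff <- data.frame(
    protein_id = ids,
    ligand_id = vapply(instances, `[[`, "", "ligand_id"),
    smiles = vapply(instances, function(i) i$substructures$smiles, ""),
    value = vapply(instances, function(i)
      format(i$y, digits = 17L, scientific = FALSE), ""),
    unit = "pK",
    measurement = vapply(instances, `[[`, "", "measurement"),
    substructure_indices = vapply(instances, function(i)
      paste(i$substructures$indices, collapse = ","), ""),
    stringsAsFactors = FALSE)
  utils::write.table(aff, file.path(dir, "affinity.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  pairs <- list()
  for (i in seq_along(instances)) {
    lab <- instances[[i]]$nci_labels
    if (is.null(lab) || !any(lab == 1L)) next
    pairs[[length(pairs) + 1L]] <- data.frame(
      instance_id = i, residue_index = which(lab == 1L) - 1L,
      atom_index = 0L, nci_type = "any")
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(instance_id = integer(0), residue_index = integer(0),
               atom_index = integer(0), nci_type = character(0))
  utils::write.table(pairs, file.path(dir, "nci_pairs.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' Also accepts real datasets in the same layout (SMILES ligands, molar
#' units); rows failing curation are dropped with their reason codes
#' attached as the `"rejections"` attribute.
#'
#' @param dir dataset directory.
#' @return list of [affinity_instance()]s.
#' @export
read_dataset <- function(dir) {
  prots <- read_protein_fasta(file.path(dir, "proteins.fasta"))
  aff <- read_affinity_table(file.path(dir, "affinity.tsv"))
  aff$sequence <- vapply(aff$protein_id, function(id)
    prots[[id]]$sequence, "")
  cur <- curate(aff)
  instances <- cur$instances
  pf <- file.path(dir, "nci_pairs.tsv")
  if (file.exists(pf)) {
    pairs <- read_nci_pairs(pf)
    # rows surviving curation keep their original row numbers
    surviving <- setdiff(seq_len(nrow(aff)), cur$rejections$row)
    for (j in seq_along(instances)) {
      orig <- surviving[j]
      m <- instances[[j]]$protein$m
      pp <- pairs[pairs$instance_id == orig, , drop = FALSE]
      mat <- pairwise_nci_matrix(m, max(1L, max(pp$atom_index + 1L, 0L)),
                                 pp[, c("residue_index", "atom_index")])
      instances[[j]]$nci_labels <- pairwise_to_residue_labels(mat)
    }
  }
  attr(instances, "rejections") <- cur$rejections
  instances
}
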