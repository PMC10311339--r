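# Ligand chemistry: SMILES parsing/canonicalization through OpenBabel
# (ChemmineOB), an ECFP-style hashed circular fingerprint with per-bit
# environment provenance, and Bemis-Murcko scaffolds.
#
# The fingerprint is computed in-package (rather than through an opaque
# toolkit call) because the model's interpretability unit is the fingerprint
# bit: describe_bit() must map a bit back to the atom environment that set
# it, which requires provenance no installed R toolkit exposes. The
# algorithm is the standard circular-fingerprint construction: iterated
# neighborhood hashing of atom invariants (element, heavy degree, attached
# hydrogens, formal charge, ring membership) with per-radius deduplication
# of environments covering identical bond sets, folded to 1024 bits. Bit
# values are deterministic but, as with any hashed fingerprint, specific to
# this implementation's hash.

OB_OPTS_H <- data.frame(names = "h", args = "", stringsAsFactors = FALSE)

# canonical SMILES via OpenBabel; NULL if unparsable
ob_canonical <- function(smiles) {
  out <- suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles))
  out <- sub("[\t ].*$", "", trimws(out))
  if (!nzchar(out)) return(NULL)
  out
}

# atoms of a SMILES string in order, with aromatic (lowercase) flags
.smiles_atom_flags <- function(smi) {
  chars <- strsplit(smi, "", fixed = TRUE)[[1L]]
  arom <- logical(0)
  i <- 1L
  n <- length(chars)
  two_letter <- c("Cl", "Br", "Si", "Se", "As", "Na", "Li", "Ca", "Mg",
                  "Al", "Zn", "Fe", "Cu", "Mn", "Sn")
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (chars[j] != "]") j <- j + 1L
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      first <- regmatches(body, regexpr("[A-Za-z]", body))
      arom <- c(arom, first %in% letters)
      i <- j + 1L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      if (i < n && paste0(ch, chars[i + 1L]) %in% two_letter) {
        arom <- c(arom, FALSE)
        i <- i + 2L
      } else {
        arom <- c(arom, FALSE)
        i <- i + 1L
      }
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      arom <- c(arom, TRUE)
      i <- i + 1L
    } else {
      i <- i + 1L   # bonds, digits, branches, dots, stereo marks
    }
  }
  arom
}

# bridges (non-ring bonds) of the heavy-atom graph by DFS low-link
.ring_bonds <- function(n_atoms, bonds) {
  if (nrow(bonds) == 0L) return(logical(0))
  adj <- vector("list", n_atoms)
  for (b in seq_len(nrow(bonds))) {
    adj[[bonds$a[b]]] <- rbind(adj[[bonds$a[b]]], c(bonds$b[b], b))
    adj[[bonds$b[b]]] <- rbind(adj[[bonds$b[b]]], c(bonds$a[b], b))
  }
  disc <- integer(n_atoms); low <- integer(n_atoms)
  is_bridge <- logical(nrow(bonds))
  timer <- 0L
  dfs <- function(u, parent_edge) {
    timer <<- timer + 1L
    disc[u] <<- timer; low[u] <<- timer
    nb <- adj[[u]]
    if (!is.null(nb)) for (r in seq_len(nrow(nb))) {
      v <- nb[r, 1L]; e <- nb[r, 2L]
      if (e == parent_edge) next
      if (disc[v] == 0L) {
        dfs(v, e)
        low[u] <<- min(low[u], low[v])
        if (low[v] > disc[u]) is_bridge[e] <<- TRUE
      } else low[u] <<- min(low[u], disc[v])
    }
  }
  for (u in seq_len(n_atoms)) if (disc[u] == 0L) dfs(u, 0L)
  !is_bridge
}

ELEMENT_Z <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12,
               Al = 13, Si = 14, P = 15, S = 16, Cl = 17, K = 19, Ca = 20,
               Fe = 26, Cu = 29, Zn = 30, As = 33, Se = 34, Br = 35,
               Sn = 50, I = 53)

#' Parse a SMILES string into a molecular graph
#'
#' Canonicalizes through OpenBabel, then reads back the heavy-atom graph
#' with explicit-hydrogen counts, formal charges, ring-bond perception and
#' aromaticity flags.
#'
#' @param smiles a SMILES string.
#' @return a list with `canonical`, `elements`, `arom`, `charge`, `nH`,
#'   `bonds` (data frame `a`, `b`, `order`, `ring`, `arom`) and `n_atoms`.
#' @export
parse_molecule <- function(smiles) {
  can <- ob_canonical(smiles)
  if (is.null(can))
    stop("SMILES parse error: cannot interpret '", smiles, "'")
  arom <- .smiles_atom_flags(can)
  sdf <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", "SDF", can, options = OB_OPTS_H))
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1L]]
  counts <- lines[4L]
  na <- as.integer(substr(counts, 1L, 3L))
  nb <- as.integer(substr(counts, 4L, 6L))
  atom_lines <- lines[5L:(4L + na)]
  elements <- trimws(substr(atom_lines, 32L, 34L))
  bond_lines <- if (nb > 0L) lines[(5L + na):(4L + na + nb)] else character(0)
  ba <- as.integer(substr(bond_lines, 1L, 3L))
  bb <- as.integer(substr(bond_lines, 4L, 6L))
  bo <- as.integer(substr(bond_lines, 7L, 9L))
  charge <- integer(na)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1L]])
    k <- f[1L]
    for (t in seq_len(k)) charge[f[2L * t]] <- f[2L * t + 1L]
  }
  heavy <- which(elements != "H")
  if (length(heavy) == 0L)
    stop("SMILES parse error: no heavy atoms in '", smiles, "'")
  remap <- integer(na); remap[heavy] <- seq_along(heavy)
  nH <- integer(length(heavy))
  keep <- logical(length(ba))
  for (b in seq_along(ba)) {
    ea <- elements[ba[b]]; eb <- elements[bb[b]]
    if (ea == "H" && eb != "H") nH[remap[bb[b]]] <- nH[remap[bb[b]]] + 1L
    else if (eb == "H" && ea != "H") nH[remap[ba[b]]] <- nH[remap[ba[b]]] + 1L
    else if (ea != "H" && eb != "H") keep[b] <- TRUE
  }
  bonds <- data.frame(a = remap[ba[keep]], b = remap[bb[keep]],
                      order = bo[keep])
  ring <- .ring_bonds(length(heavy), bonds)
  if (length(arom) != length(heavy))   # tokenizer/graph disagreement guard
    arom <- rep(FALSE, length(heavy))
  bond_arom <- if (nrow(bonds)) ring & arom[bonds$a] & arom[bonds$b] else
    logical(0)
  bonds$ring <- ring
  bonds$arom <- bond_arom
  list(canonical = can, elements = elements[heavy], arom = arom,
       charge = charge[heavy], nH = nH, bonds = bonds,
       n_atoms = length(heavy))
}

# deterministic polynomial hash of an integer vector, exact in doubles
HASH_P <- 2147483629
.hash_ints <- function(x) {
  h <- 17
  for (v in x) h <- (h * 31 + (v %% HASH_P)) %% HASH_P
  h
}

# all-pairs graph distances by BFS (small molecules)
.bfs_dist <- function(n_atoms, bonds) {
  adj <- vector("list", n_atoms)
  for (b in seq_len(nrow(bonds))) {
    adj[[bonds$a[b]]] <- c(adj[[bonds$a[b]]], bonds$b[b])
    adj[[bonds$b[b]]] <- c(adj[[bonds$b[b]]], bonds$a[b])
  }
  D <- matrix(Inf, n_atoms, n_atoms)
  for (s in seq_len(n_atoms)) {
    D[s, s] <- 0
    frontier <- s
    dist <- 0
    while (length(frontier)) {
      dist <- dist + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[D[s, nxt] == Inf]
      D[s, nxt] <- dist
      frontier <- nxt
    }
  }
  D
}

# core circular-fingerprint computation with provenance
.circular_features <- function(mol, radius) {
  n <- mol$n_atoms
  bonds <- mol$bonds
  z <- unname(ELEMENT_Z[mol$elements])
  z[is.na(z)] <- 0
  deg <- integer(n)
  in_ring <- logical(n)
  if (nrow(bonds)) {
    tb <- table(factor(c(bonds$a, bonds$b), levels = seq_len(n)))
    deg <- as.integer(tb)
    in_ring[unique(c(bonds$a[bonds$ring], bonds$b[bonds$ring]))] <- TRUE
  }
  bcode <- if (nrow(bonds)) ifelse(bonds$arom, 4L, bonds$order) else integer(0)
  ids <- vapply(seq_len(n), function(a)
    .hash_ints(c(z[a], deg[a], mol$nH[a], mol$charge[a],
                 as.integer(in_ring[a]), as.integer(mol$arom[a]))), 0)
  D <- if (n > 1L && nrow(bonds)) .bfs_dist(n, bonds) else
    matrix(0, n, n)
  feats <- data.frame(id = ids, atom = seq_len(n), radius = 0L)
  seen_sets <- character(0)
  cur <- ids
  if (radius >= 1L && nrow(bonds)) for (r in seq_len(radius)) {
    nxt <- cur
    for (a in seq_len(n)) {
      inc <- which(bonds$a == a | bonds$b == a)
      if (!length(inc)) next
      nb <- ifelse(bonds$a[inc] == a, bonds$b[inc], bonds$a[inc])
      o <- order(bcode[inc], cur[nb])
      nxt[a] <- .hash_ints(c(r, cur[a],
                             as.vector(rbind(bcode[inc][o], cur[nb][o]))))
      # environment = bonds inside the radius-r ball around a
      env <- which(pmin(D[a, bonds$a], D[a, bonds$b]) <= r - 1 &
                     pmax(D[a, bonds$a], D[a, bonds$b]) <= r)
      key <- paste(sort(env), collapse = ",")
      if (key %in% seen_sets) next
      seen_sets <- c(seen_sets, key)
      feats <- rbind(feats,
                     data.frame(id = nxt[a], atom = a, radius = r))
    }
    cur <- nxt
  }
  feats
}

#' Substructure indices of a ligand
#'
#' Computes the ligand's 1024-bit hashed circular fingerprint at the given
#' radius (2 = ECFP4-equivalent) and returns the ascending indices of its
#' set bits: the chemical substructures whose trainable embeddings form the
#' keys and values of the cross-attention.
#'
#' @param smiles ligand SMILES (canonicalized internally, so input dialects
#'   collapse to one representation).
#' @param radius neighborhood radius.
#' @param n_bits fingerprint length (the architecture fixes 1024).
#' @param ligand_id optional identifier.
#' @return object of class `"substructure_set"`: `ligand_id`, `smiles`
#'   (canonical), `indices` (0-based, strictly increasing), `n`, and a
#'   provenance table mapping each bit to its atom environments.
#' @export
#' @examples
#' \dontrun{
#' s <- smiles_to_substructure_indices("CCO")
#' s$indices
#' }
smiles_to_substructure_indices <- function(smiles, radius = 2L,
                                           n_bits = 1024L,
                                           ligand_id = smiles) {
  mol <- parse_molecule(smiles)
  feats <- .circular_features(mol, radius)
  feats$bit <- feats$id %% n_bits
  idx <- sort(unique(feats$bit))
  if (length(idx) < 1L)
    stop("rejection error: ligand '", smiles,
         "' has zero set fingerprint bits and cannot be encoded")
  structure(list(ligand_id = ligand_id, smiles = mol$canonical,
                 indices = as.integer(idx), n = length(idx),
                 radius = as.integer(radius), n_bits = as.integer(n_bits),
                 provenance = feats, mol = mol),
            class = "substructure_set")
}

#' Build a substructure set directly from bit indices
#'
#' Used by the synthetic-data generator, whose ligands are abstract index
#' sets rather than molecules.
#'
#' @param indices integer vector of bit indices in `[0, n_bits - 1]`.
#' @param ligand_id identifier.
#' @param n_bits vocabulary size.
#' @return a `"substructure_set"`.
#' @export
substructure_set <- function(indices, ligand_id = "synthetic",
                             n_bits = 1024L) {
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) < 1L)
    stop("rejection error: empty substructure index set")
  if (any(indices < 0L) || any(indices >= n_bits))
    stop("invariant violation: substructure index outside [0, ",
         n_bits - 1L, "]")
  structure(list(ligand_id = ligand_id, smiles = NA_character_,
                 indices = indices, n = length(indices),
                 radius = NA_integer_, n_bits = as.integer(n_bits),
                 provenance = NULL, mol = NULL),
            class = "substructure_set")
}

#' @export
print.substructure_set <- function(x, ...) {
  cat(sprintf("substructure set %s: n=%d of %d bits\n",
              x$ligand_id, x$n, x$n_bits))
  invisible(x)
}

#' Substructure vocabulary
#'
#' The 1024 trainable substructure embeddings plus the single trainable
#' pseudo-substructure vector (a separate parameter, appended last to the
#' attention keys/values).
#'
#' @param d embedding dimension.
#' @param size vocabulary size (1024).
#' @param seed initialization seed.
#' @return list with `size`, `d`, `table` (`size x d`) and `pseudo`
#'   (length `d`), class `"substructure_vocabulary"`.
#' @export
substructure_vocabulary <- function(d, size = 1024L, seed = 1L) {
  old <- .Random.seed_save()
  set.seed(seed)
  v <- structure(list(size = as.integer(size), d = as.integer(d),
                      table = matrix(stats::rnorm(size * d, sd = 0.2),
                                     size, d),
                      pseudo = stats::rnorm(d, sd = 0.2)),
                 class = "substructure_vocabulary")
  .Random.seed_restore(old)
  v
}

#' Look up substructure embeddings
#'
#' @param s a `"substructure_set"`.
#' @param v a [substructure_vocabulary()].
#' @return an `n x d` matrix whose row `i` is the table row for
#'   `s$indices[i]`.
#' @export
embed_substructures <- function(s, v) {
  stopifnot(inherits(s, "substructure_set"))
  if (s$n < 1L) stop("empty substructure set")
  if (any(s$indices >= v$size))
    stop("invariant violation: substructure index >= vocabulary size ",
         v$size)
  v$table[s$indices + 1L, , drop = FALSE]
}

# minimal fragment-string writer: DFS spanning tree with ring-closure
# digits; aromatic atoms lowercase; display-oriented, SMILES-like
.fragment_string <- function(mol, atoms, bonds_idx) {
  sub_atoms <- sort(atoms)
  amap <- match(seq_len(mol$n_atoms), sub_atoms)
  bs <- mol$bonds[bonds_idx, , drop = FALSE]
  n <- length(sub_atoms)
  adj <- vector("list", n)
  for (b in seq_len(nrow(bs))) {
    i <- amap[bs$a[b]]; j <- amap[bs$b[b]]
    sym <- if (bs$arom[b]) "" else c("", "=", "#", "")[bs$order[b]]
    adj[[i]] <- rbind(adj[[i]], data.frame(to = j, sym = sym))
    adj[[j]] <- rbind(adj[[j]], data.frame(to = i, sym = sym))
  }
  atom_token <- function(k) {
    a <- sub_atoms[k]
    el <- mol$elements[a]
    tok <- if (mol$arom[a] && el %in% c("B", "C", "N", "O", "P", "S"))
      tolower(el) else el
    if (mol$charge[a] != 0)
      tok <- paste0("[", tok,
                    if (mol$charge[a] > 0) strrep("+", mol$charge[a]) else
                      strrep("-", -mol$charge[a]), "]")
    tok
  }
  visited <- logical(n)
  pos <- integer(n)
  counter <- 0L
  ring_id <- 0L
  closure <- vector("list", n)
  tree <- vector("list", n)
  # first pass: spanning tree + ring-closure back edges
  walk <- function(u, parent) {
    visited[u] <<- TRUE
    counter <<- counter + 1L
    pos[u] <<- counter
    nb <- adj[[u]]
    skipped_parent <- FALSE
    if (!is.null(nb)) for (r in seq_len(nrow(nb))) {
      v <- nb$to[r]
      if (v == parent && !skipped_parent) {
        skipped_parent <- TRUE
        next
      }
      if (!visited[v]) {
        tree[[u]] <<- rbind(tree[[u]], nb[r, ])
        walk(v, u)
      } else if (pos[v] < pos[u] &&
                 !any(vapply(closure[[u]], function(cl) cl$to == v, TRUE))) {
        ring_id <<- ring_id + 1L
        closure[[u]] <<- c(closure[[u]],
                           list(list(to = v, id = ring_id, sym = nb$sym[r])))
        closure[[v]] <<- c(closure[[v]],
                           list(list(to = u, id = ring_id, sym = "")))
      }
    }
  }
  emit <- function(u) {
    out <- atom_token(u)
    for (cl in closure[[u]]) out <- paste0(out, cl$sym, cl$id)
    br <- tree[[u]]
    if (!is.null(br)) {
      k <- nrow(br)
      for (r in seq_len(k)) {
        piece <- paste0(br$sym[r], emit(br$to[r]))
        out <- paste0(out, if (r < k) paste0("(", piece, ")") else piece)
      }
    }
    out
  }
  walk(1L, 0L)
  emit(1L)
}

#' Describe the atom environment behind a fingerprint bit
#'
#' Returns a human-readable SMILES-like fragment for the atom environment of
#' the given ligand that hashes to the given bit; used when exporting
#' attention maps so substructure columns carry chemical annotations.
#'
#' @param index bit index in `[0, n_bits - 1]`.
#' @param smiles the ligand's SMILES, or an existing `"substructure_set"`
#'   computed from one.
#' @param radius,n_bits fingerprint parameters (ignored when a set is given).
#' @return a non-empty fragment string.
#' @export
describe_bit <- function(index, smiles, radius = 2L, n_bits = 1024L) {
  s <- if (inherits(smiles, "substructure_set")) smiles else
    smiles_to_substructure_indices(smiles, radius = radius, n_bits = n_bits)
  if (is.null(s$provenance))
    stop("lookup error: substructure set has no molecule behind it")
  hit <- s$provenance[s$provenance$bit == index, , drop = FALSE]
  if (nrow(hit) == 0L)
    stop("lookup error: bit ", index, " is not set for ligand '",
         s$ligand_id, "'")
  a <- hit$atom[1L]; r <- hit$radius[1L]
  mol <- s$mol
  if (r == 0L || nrow(mol$bonds) == 0L) {
    tok <- mol$elements[a]
    if (mol$arom[a]) tok <- tolower(tok)
    return(tok)
  }
  D <- .bfs_dist(mol$n_atoms, mol$bonds)
  env <- which(pmin(D[a, mol$bonds$a], D[a, mol$bonds$b]) <= r - 1 &
                 pmax(D[a, mol$bonds$a], D[a, mol$bonds$b]) <= r)
  atoms <- unique(c(a, mol$bonds$a[env], mol$bonds$b[env]))
  .fragment_string(mol, atoms, env)
}

#' Bemis-Murcko scaffold of a molecule
#'
#' Ring systems plus the linkers connecting them: side-chain atoms are
#' pruned iteratively (terminal atoms attached by single bonds), keeping
#' exocyclic multiple-bonded atoms. Acyclic molecules have the empty
#' scaffold `""`. The scaffold is returned as a canonical (achiral) SMILES
#' string so scaffold identity reduces to string equality.
#'
#' @param smiles ligand SMILES.
#' @return canonical scaffold SMILES (possibly `""`).
#' @export
murcko_scaffold <- function(smiles) {
  mol <- parse_molecule(smiles)
  keep <- rep(TRUE, mol$n_atoms)
  bonds <- mol$bonds
  if (nrow(bonds) == 0L || !any(bonds$ring)) return("")
  repeat {
    deg <- integer(mol$n_atoms)
    live <- keep[bonds$a] & keep[bonds$b]
    tb <- table(factor(c(bonds$a[live], bonds$b[live]),
                       levels = seq_len(mol$n_atoms)))
    deg <- as.integer(tb)
    drop <- which(keep & deg <= 1L)
    # keep terminal atoms attached by a multiple bond (e.g. carbonyl O)
    if (length(drop)) {
      multi <- vapply(drop, function(a) {
        inc <- which(live & (bonds$a == a | bonds$b == a))
        length(inc) == 1L && bonds$order[inc] > 1L
      }, TRUE)
      drop <- drop[!multi]
    }
    drop <- drop[vapply(drop, function(a) {
      inc <- which(live & (bonds$a == a | bonds$b == a))
      length(inc) <= 1L
    }, TRUE)]
    if (!length(drop)) break
    keep[drop] <- FALSE
  }
  atoms <- which(keep)
  live <- keep[bonds$a] & keep[bonds$b]
  sdf <- .write_sdf(mol, atoms, which(live))
  can <- sub("[\t ].*$", "",
             trimws(suppressWarnings(
               ChemmineOB::convertFormat("SDF", "CAN", sdf))))
  can
}

# minimal V2000 writer for a heavy-atom subgraph
.write_sdf <- function(mol, atoms, bonds_idx) {
  amap <- match(seq_len(mol$n_atoms), sort(atoms))
  atoms <- sort(atoms)
  na <- length(atoms); nb <- length(bonds_idx)
  hdr <- c("scaffold", "  ncidta", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  al <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                0, 0, 0, mol$elements[atoms])
  bl <- if (nb) sprintf("%3d%3d%3d  0  0  0  0",
                        amap[mol$bonds$a[bonds_idx]],
                        amap[mol$bonds$b[bonds_idx]],
                        mol$bonds$order[bonds_idx]) else character(0)
  chg <- which(mol$charge[atoms] != 0)
  cl <- if (length(chg))
    vapply(chg, function(k) sprintf("M  CHG  1 %3d %3d", k,
                                    mol$charge[atoms[k]]), "") else
    character(0)
  paste(c(hdr, al, bl, cl, "M  END", "$$$$", ""), collapse = "\n")
}
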