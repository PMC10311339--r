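# Curation, normalization, label conversion, splitting, collation, I/O.

toy_affinity_table <- function() {
  seqs <- c(strrep("A", 1001),                       # too long
            strrep("M", 1000),                       # boundary: accepted
            "MKVLA", "ACDEF", "MMMM", "KKKKK",
            "AYAYK", "MKWVT", "PLIVM", "GGSGG")
  data.frame(
    protein_id = paste0("P", 1:10),
    sequence = seqs,
    ligand_id = paste0("L", 1:10),
    smiles = c("CCO", "c1ccccc1", "CCN", "CC(=O)O", "CCCC", "c1ccncc1",
               "CO", "CC", "CCC", "C"),
    value = c("5", "10", ">50000", "2.5", "1", "7", "3", "8", "100", "40"),
    unit = c("nM", "uM", "M", "uM", "nM", "nM", "uM", "nM", "nM", "uM"),
    measurement = "Kd", stringsAsFactors = FALSE)
}

test_that("curation applies the published filters with reason codes", {
  cur <- curate(toy_affinity_table())
  expect_length(cur$instances, 8L)
  expect_equal(nrow(cur$rejections), 2L)
  expect_equal(cur$rejections$reason[cur$rejections$row == 1], "TOO_LONG")
  expect_equal(cur$rejections$reason[cur$rejections$row == 3],
               "INEXACT_VALUE")
  # the 1000-residue protein with an exact value is retained ("exceeds")
  kept <- vapply(cur$instances, function(i) i$protein$protein_id, "")
  expect_true("P2" %in% kept)
  # idempotent and order-independent
  tab <- toy_affinity_table()
  cur2 <- curate(tab[sample(nrow(tab)), ])
  expect_setequal(vapply(cur2$instances,
                         function(i) i$protein$protein_id, ""), kept)
})

test_that("unparsable SMILES carry the BAD_SMILES code", {
  tab <- toy_affinity_table()[4:6, ]
  tab$smiles[2] <- "xx(("
  cur <- curate(tab)
  expect_equal(cur$rejections$reason, "BAD_SMILES")
  expect_length(cur$instances, 2L)
})

test_that("affinity normalization follows the pK convention", {
  expect_equal(normalize_affinity(1, "uM"), 6)
  expect_equal(normalize_affinity(1, "nM"), 9)
  expect_equal(normalize_affinity(1, "M"), 0)
  expect_equal(normalize_affinity(50, "pM"), -log10(50e-12))
  expect_equal(normalize_affinity(7.3, "pK"), 7.3)
  expect_error(normalize_affinity(-1, "nM"), "positive")
  expect_error(normalize_affinity(1, "furlongs"), "unknown unit")
  # strictly decreasing in the molar value
  vals <- sort(10^runif(20, -12, 0))
  ys <- vapply(vals, normalize_affinity, 0, unit = "M")
  expect_true(all(diff(ys) < 0))
})

test_that("pairwise NCI matrices collapse to residue labels", {
  m1 <- pairwise_nci_matrix(2, 3, data.frame(residue_index = 0L,
                                             atom_index = 1L))
  expect_equal(pairwise_to_residue_labels(m1), c(1L, 0L))
  m2 <- pairwise_nci_matrix(4, 2, data.frame(residue_index = integer(0),
                                             atom_index = integer(0)))
  expect_equal(pairwise_to_residue_labels(m2), rep(0L, 4))
  m3 <- pairwise_nci_matrix(3, 2, expand.grid(residue_index = 0:2,
                                              atom_index = 0:1))
  expect_equal(pairwise_to_residue_labels(m3), rep(1L, 3))
  # multiple NCIs on one residue still yield a single 1
  m4 <- pairwise_nci_matrix(2, 3, data.frame(residue_index = c(1L, 1L),
                                             atom_index = c(0L, 2L)))
  expect_equal(pairwise_to_residue_labels(m4), c(0L, 1L))
  expect_error(pairwise_nci_matrix(2, 2, data.frame(residue_index = 2L,
                                                    atom_index = 0L)),
               "out of range")
  expect_error(pairwise_nci_matrix(2, 2, data.frame(residue_index = c(1, 1),
                                                    atom_index = c(0, 0))),
               "duplicate")
})

test_that("5-fold plans partition the data with 5% validation", {
  plan <- make_folds(100L, k = 5L, seed = 3L)
  expect_equal(plan$k, 5L)
  all_test <- integer(0)
  for (f in plan$folds) {
    expect_length(f$test, 20L)
    expect_length(f$val, 4L)     # floor(0.05 * 80)
    expect_length(f$train, 76L)
    expect_length(intersect(f$train, f$val), 0L)
    expect_length(intersect(f$train, f$test), 0L)
    expect_length(intersect(f$val, f$test), 0L)
    all_test <- c(all_test, f$test)
  }
  expect_setequal(all_test, 1:100)           # exhaustive, disjoint
  expect_equal(length(all_test), 100L)
  plan2 <- make_folds(100L, k = 5L, seed = 3L)
  expect_identical(plan, plan2)              # deterministic under seed
  expect_false(identical(plan, make_folds(100L, k = 5L, seed = 4L)))
  expect_error(make_folds(3L, k = 5L), "too few")
})

test_that("holdout split is an 80/20 partition with 5% validation", {
  plan <- holdout_split(100L, seed = 9L)
  f <- plan$folds[[1]]
  expect_length(f$test, 20L)
  expect_length(f$val, 4L)
  expect_length(f$train, 76L)
  expect_setequal(c(f$train, f$val, f$test), 1:100)
  expect_identical(plan, holdout_split(100L, seed = 9L))
})

test_that("split plans survive a JSON round trip", {
  plan <- make_folds(23L, k = 3L, seed = 2L)
  path <- tempfile(fileext = ".json")
  write_split_plan(plan, path)
  back <- read_split_plan(path)
  expect_equal(back$k, plan$k)
  for (f in seq_len(plan$k))
    for (part in c("train", "val", "test"))
      expect_equal(back$folds[[f]][[part]], plan$folds[[f]][[part]])
})

test_that("unseen-scaffold subsets match brute-force scaffold comparison", {
  smis <- drug_smiles()
  set.seed(14)
  mk <- function(smi, id) affinity_instance(
    random_protein(8), smiles_to_substructure_indices(smi, ligand_id = id),
    y = rnorm(1, 6), measurement = "Kd", ligand_id = id)
  insts <- mapply(mk, smis, names(smis), SIMPLIFY = FALSE)
  test <- insts[1:8]; train <- insts[9:20]
  got <- unseen_scaffold_subset(test, train)
  # brute force: compare scaffold strings pairwise
  train_sc <- vapply(train, function(i) murcko_scaffold(i$substructures$smiles), "")
  keep <- vapply(test, function(i) {
    sc <- murcko_scaffold(i$substructures$smiles)
    !any(sc == train_sc)
  }, TRUE)
  expect_equal(vapply(got, `[[`, "", "ligand_id"),
               vapply(test[keep], `[[`, "", "ligand_id"))
  # a test ligand identical to a training ligand is never unseen
  got2 <- unseen_scaffold_subset(insts[1], c(train, insts[1]))
  expect_length(got2, 0L)
  # toluene vs a training set containing any benzene-scaffold compound
  tol <- mk("Cc1ccccc1", "tol")
  benz_train <- list(mk("CCc1ccccc1", "ethylbenzene"))
  expect_length(unseen_scaffold_subset(list(tol), benz_train), 0L)
  # pyridine scaffold absent from a benzene-only training set
  pyr <- mk("c1ccncc1", "pyr")
  expect_length(unseen_scaffold_subset(list(pyr), benz_train), 1L)
})

test_that("murcko scaffolds strip side chains and keep ring assemblies", {
  expect_equal(murcko_scaffold("Cc1ccccc1"), murcko_scaffold("c1ccccc1"))
  expect_equal(murcko_scaffold("CCCC"), "")          # acyclic -> empty
  expect_false(murcko_scaffold("c1ccncc1") == murcko_scaffold("c1ccccc1"))
  # ring-linker-ring stays connected
  bip <- murcko_scaffold("c1ccc(cc1)Cc1ccccc1C")
  expect_equal(bip, murcko_scaffold("c1ccc(cc1)Cc1ccccc1"))
})

test_that("collation pads with masks and never changes single predictions", {
  set.seed(51)
  insts <- replicate(6, random_instance(m = sample(3:14, 1),
                                        n = sample(2:7, 1)),
                     simplify = FALSE)
  model <- tiny_model()
  b1 <- collate(insts[1])
  expect_true(all(b1$res_mask))
  out1 <- forward_collated(model, b1)
  expect_equal(out1$yhat, predict(model, insts[1]), tolerance = 1e-12)
  # same instance inside a padded batch
  ball <- collate(insts)
  outall <- forward_collated(model, ball)
  expect_equal(outall$yhat[1], out1$yhat[1], tolerance = 1e-5)
  expect_equal(outall$yhat, predict(model, insts), tolerance = 1e-5)
  # batch L2 equals the mean of per-instance L2 (loop oracle)
  per <- vapply(insts, function(i) {
    m <- predict(model, list(i), type = "attention")[[1]]
    attention_regularization_loss(m, i$nci_labels)
  }, 0)
  expect_equal(outall$l2, mean(per), tolerance = 1e-12)
  expect_error(collate(list()), "empty")
})

test_that("FASTA and dataset files round-trip instances exactly", {
  world <- small_world()
  insts <- generate_dataset(world, 12L, seed = 31L)
  dir <- tempfile("synds")
  write_dataset(insts, dir)
  expect_true(file.exists(file.path(dir, "proteins.fasta")))
  back <- read_dataset(dir)
  expect_length(back, length(insts))
  for (i in seq_along(insts)) {
    expect_identical(back[[i]]$protein$sequence, insts[[i]]$protein$sequence)
    expect_identical(back[[i]]$substructures$indices,
                     insts[[i]]$substructures$indices)
    expect_equal(back[[i]]$y, insts[[i]]$y)          # exact round trip
    expect_identical(back[[i]]$nci_labels, insts[[i]]$nci_labels)
  }
  # writing twice gives identical files
  dir2 <- tempfile("synds")
  write_dataset(insts, dir2)
  for (f in c("proteins.fasta", "affinity.tsv", "nci_pairs.tsv"))
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
})
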