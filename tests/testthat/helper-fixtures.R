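# Shared fixture builders: everything is generated in code at test time.

tiny_config <- function(...) {
  defaults <- list(d = 16L, heads = 4L, u = 2L, dropout_rate = 0,
                   max_epochs = 2L, batch_size = 8L, seed = 1L)
  args <- utils::modifyList(defaults, list(...))
  do.call(dta_config, args)
}

tiny_model <- function(cfg = tiny_config()) dta_model(cfg)

random_protein <- function(m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa <- setdiff(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                  "R","S","T","V","W","Y"), character(0))
  protein_record(paste0("P", m), paste(sample(aa, m, replace = TRUE),
                                       collapse = ""))
}

random_instance <- function(m = 12L, n = 6L, labeled = TRUE) {
  p <- random_protein(m)
  s <- substructure_set(sort(sample(0:1023, n)))
  affinity_instance(p, s, y = rnorm(1, 6), measurement = "Kd",
                    nci_labels = if (labeled) rbinom(m, 1, 0.3))
}

# a seeded synthetic world + dataset shared across tests
small_world <- function(seed = 5L) generate_world(n_motifs = 3L, seed = seed)

# drug-like SMILES for chemistry tests: the first 20 entries of the
# bundled list (inst/extdata/drug_smiles.tsv)
drug_smiles <- function(n = 20L) {
  tab <- utils::read.delim(system.file("extdata", "drug_smiles.tsv",
                                       package = "ncidta"))
  utils::head(stats::setNames(tab$smiles, tab$name), n)
}
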