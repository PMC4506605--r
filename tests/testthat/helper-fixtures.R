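# random canonical evidence tables for filter/property tests
random_evidence <- function(n, seed, n_channels = 3, n_proteins = 60) {
  set.seed(seed)
  nodes <- sprintf("PR%03d", seq_len(n_proteins))
  pairs <- t(combn(nodes, 2))
  pairs <- pairs[sample(nrow(pairs), n), , drop = FALSE]
  ev <- data.frame(protein_a = pairs[, 1], protein_b = pairs[, 2],
                   stringsAsFactors = FALSE)
  for (j in seq_len(n_channels)) {
    ev[[sprintf("score_ch%d", j)]] <- runif(n)
  }
  ev$mi_score <- runif(n)
  ev$n_publications <- rpois(n, 3)
  ev$is_physical <- runif(n) < 0.5
  ev$n_conserved_species <- rpois(n, 1.5)
  as_evidence(ev)
}

write_annotation_file <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# annotation table covering the given accessions, all membrane by default
simple_annotations <- function(accessions, membrane = TRUE) {
  data.frame(
    accession = accessions,
    gene_symbol = paste0("g", accessions),
    has_signal_peptide = rep(membrane, length.out = length(accessions)),
    has_transmembrane = FALSE,
    compartments = "sperm;egg",
    stringsAsFactors = FALSE
  )
}

# centrality table from the bundled reference hub rows plus filler nodes
reference_plus_filler <- function(filler_degrees) {
  ref <- reference_hub_table()
  tbl <- data.frame(
    gene_symbol = ref$gene_symbol,
    degree = ref$degree,
    betweenness = ref$betweenness,
    closeness = ref$closeness,
    stringsAsFactors = FALSE
  )
  if (length(filler_degrees)) {
    filler <- data.frame(
      gene_symbol = sprintf("FILLER%03d", seq_along(filler_degrees)),
      degree = as.integer(filler_degrees),
      betweenness = 0.001,
      closeness = 0.3,
      stringsAsFactors = FALSE
    )
    tbl <- rbind(tbl, filler)
  }
  tbl
}
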