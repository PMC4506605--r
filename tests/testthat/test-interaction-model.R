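test_that("annotation tables parse field by field", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    "accession\tgene_symbol\tsignal_peptide\ttransmembrane\tcompartments",
    "P05556\tITGB1\t1\t1\tsperm;egg",
    "P08648\tITGA5\tfalse\tYES\tsperm",
    "Q14108\tSCARB2\t0\t0\tegg"
  ), f)
  ann <- read_annotations(f)
  expect_equal(nrow(ann), 3)
  expect_equal(ann$accession[1], "P05556")
  expect_equal(ann$gene_symbol[1], "ITGB1")
  expect_true(ann$has_signal_peptide[1] && ann$has_transmembrane[1])
  expect_equal(ann$compartments[1], "sperm;egg")
  expect_false(ann$has_signal_peptide[2])
  expect_true(ann$has_transmembrane[2])
  expect_false(ann$has_signal_peptide[3] || ann$has_transmembrane[3])
})

test_that("annotation reading rejects bad tables and accepts empty ones", {
  f <- tempfile(fileext = ".tsv")
  writeLines("accession\tgene_symbol\tsignal_peptide\ttransmembrane\tcompartments", f)
  expect_equal(nrow(read_annotations(f)), 0)

  writeLines(c(
    "accession\tgene_symbol\tsignal_peptide\ttransmembrane\tcompartments",
    "P05556\tITGB1\t1\t1\tsperm",
    "P05556\tITGB1\t1\t0\tegg"
  ), f)
  expect_error(read_annotations(f), "P05556")

  writeLines(c("accession\tgene_symbol\tsignal_peptide\ttransmembrane",
               "P05556\tITGB1\t1\t1"), f)
  expect_error(read_annotations(f), "compartments")
})

test_that("evidence records are canonicalized and duplicates merged", {
  f <- tempfile(fileext = ".tsv")
  hdr <- "protein_a\tprotein_b\tscore_exp\tscore_db\tmi_score\tn_publications\tis_physical\tn_conserved_species"
  writeLines(c(hdr,
    "A\tB\t0.5\t0.2\t0.3\t2\t1\t0",
    "B\tA\t0.4\t0.9\t0.5\t5\t0\t3"
  ), f)
  ev <- read_evidence(f)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$protein_a, "A")
  expect_equal(ev$protein_b, "B")
  expect_equal(ev$mi_score, 0.5)
  expect_equal(ev$score_exp, 0.5)
  expect_equal(ev$score_db, 0.9)
  expect_equal(ev$n_publications, 5L)
  expect_equal(ev$n_conserved_species, 3L)
  expect_true(ev$is_physical)

  writeLines(hdr, f)
  expect_equal(nrow(read_evidence(f)), 0)

  writeLines(c(hdr, "A\tB\t1.3\t0.2\t0.3\t2\t1\t0"), f)
  expect_error(read_evidence(f), "score_exp.*row.*1")

  writeLines(c(hdr, "A\tB\t0.1\t0.2\t0.3\t2\t1\t0",
               "C\tC\t0.1\t0.2\t0.3\t2\t1\t0"), f)
  expect_error(read_evidence(f), "self-interaction")
})

test_that("evidence merging is idempotent and independent of row order", {
  ev <- random_evidence(80, seed = 11)
  expect_identical(as_evidence(ev), ev)
  set.seed(3)
  shuffled <- ev[sample(nrow(ev)), , drop = FALSE]
  # also swap pair orientation on half the rows
  flip <- seq_len(nrow(shuffled)) %% 2 == 0
  tmp <- shuffled$protein_a[flip]
  shuffled$protein_a[flip] <- shuffled$protein_b[flip]
  shuffled$protein_b[flip] <- tmp
  expect_identical(as_evidence(shuffled), ev)
})

test_that("networks round-trip through SIF and edge-TSV exactly", {
  net <- pin_network(c("A", "B", "C", "D", "E"),
                     rbind(c("A", "B"), c("B", "C"), c("A", "C")))
  for (fmt in c("sif", "edge-tsv")) {
    f <- tempfile()
    write_network(net, f, fmt)
    expect_true(network_identical(read_network(f, fmt), net))
  }
  # triangle gives one SIF line per edge; D and E appear as bare lines
  f <- tempfile()
  write_network(net, f, "sif")
  lines <- readLines(f)
  expect_equal(sum(grepl("\tpp\t", lines)), 3)
  expect_setequal(lines[!grepl("\tpp\t", lines)], c("D", "E"))

  empty <- pin_network()
  for (fmt in c("sif", "edge-tsv")) {
    f <- tempfile()
    write_network(empty, f, fmt)
    expect_true(network_identical(read_network(f, fmt), empty))
  }
  expect_error(write_network(net, tempfile(), "graphml"))
})

test_that("round-trip holds on random networks with isolated nodes", {
  for (seed in 1:5) {
    net <- random_test_network(25, 0.08, seed)
    for (fmt in c("sif", "edge-tsv")) {
      f <- tempfile()
      write_network(net, f, fmt)
      expect_true(network_identical(read_network(f, fmt), net))
    }
  }
})

test_that("build_network yields a simple graph covering all records", {
  expect_true(network_identical(build_network(data.frame()), pin_network()))
  ev <- random_evidence(2, seed = 1)
  ev$protein_a <- c("A", "B"); ev$protein_b <- c("B", "C")
  net <- build_network(ev)
  expect_equal(igraph::vcount(net), 3)
  expect_equal(igraph::ecount(net), 2)

  for (seed in 1:5) {
    ev <- random_evidence(100, seed = seed)
    net <- build_network(ev)
    expect_true(igraph::is_simple(net))
    expect_equal(igraph::ecount(net), nrow(ev))
    expect_setequal(igraph::V(net)$name, unique(c(ev$protein_a, ev$protein_b)))
  }
})

test_that("a full-scale record set reproduces its node and edge counts", {
  # 1484 distinct pairs over 106 proteins, every protein covered
  set.seed(99)
  nodes <- sprintf("P%03d", 1:106)
  ring <- cbind(nodes, nodes[c(2:106, 1)])
  all_pairs <- t(combn(nodes, 2))
  key <- paste(pmin(all_pairs[, 1], all_pairs[, 2]),
               pmax(all_pairs[, 1], all_pairs[, 2]))
  ring_key <- paste(pmin(ring[, 1], ring[, 2]), pmax(ring[, 1], ring[, 2]))
  extra <- all_pairs[!(key %in% ring_key), , drop = FALSE]
  pairs <- rbind(ring, extra[sample(nrow(extra), 1484 - nrow(ring)), ])
  ev <- data.frame(protein_a = pairs[, 1], protein_b = pairs[, 2],
                   score_ch1 = 0.5, mi_score = 0.5, n_publications = 3L,
                   is_physical = TRUE, n_conserved_species = 1L)
  net <- build_network(as_evidence(ev))
  expect_equal(igraph::vcount(net), 106)
  expect_equal(igraph::ecount(net), 1484)
})
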