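#' Distribution specification for the study generator
#'
#' A small declarative wrapper so that a [study_spec()] is fully serializable:
#' `"beta"` (shape1, shape2), `"pois"` (lambda) or `"const"` (value).
#'
#' @param type one of `"beta"`, `"pois"`, `"const"`.
#' @param ... distribution parameters (see above).
#' @return An object of class `dist_spec`.
#' @export
dist_spec <- function(type = c("beta", "pois", "const"), ...) {
  type <- match.arg(type)
  par <- list(...)
  ok <- switch(type,
    beta = all(c("shape1", "shape2") %in% names(par)),
    pois = "lambda" %in% names(par),
    const = "value" %in% names(par)
  )
  if (!ok) stop("missing parameter(s) for dist_spec type '", type, "'",
                call. = FALSE)
  structure(c(list(type = type), par), class = "dist_spec")
}

.sample_dist <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$type,
    beta = rbeta(n, spec$shape1, spec$shape2),
    pois = rpois(n, spec$lambda),
    const = rep(spec$value, n)
  )
}

#' Specification of a synthetic two-compartment interaction study
#'
#' Describes a sperm/egg protein-interaction study with a shared scale-free
#' core, planted membrane hubs, and per-edge evidence fields, at a scale the
#' test suite can run repeatedly.  Defaults emulate the structure of the
#' published study at roughly one-fifth scale: a sperm compartment about
#' five times the size of the egg compartment, a shared core of 80 proteins
#' of which 8 are planted hubs, and a membrane-annotation fraction of 0.63.
#'
#' @param n_sperm,n_egg,n_shared compartment sizes and shared-core size;
#'   `n_shared <= min(n_sperm, n_egg)`.
#' @param attachment_edges_per_node preferential-attachment parameter `m`.
#' @param membrane_fraction probability a protein is membrane-annotated
#'   (planted hubs are always membrane).
#' @param n_planted_hubs number of shared membrane proteins wired to high
#'   degree in the shared core; at most `n_shared`.
#' @param hub_degree_fraction target shared-core degree of each planted hub
#'   as a fraction of `n_shared`.
#' @param true_edge_channel_dist,noise_edge_channel_dist per-channel score
#'   distributions for true and spurious edges ([dist_spec()]).
#' @param n_channels number of evidence channels.
#' @param physical_prob probability an edge is flagged physical.
#' @param publication_dist distribution of supporting-publication counts.
#' @param mi_given_physical_dist MI-score distribution for physical edges
#'   (non-physical edges carry no MI score).
#' @param conservation_dist distribution of conserved-species counts.
#' @param noise_edge_fraction spurious edges added per compartment, as a
#'   fraction of its true edge count.
#' @param seed integer seed governing all randomness.
#' @return An object of class `study_spec`.
#' @export
study_spec <- function(n_sperm = 400L,
                       n_egg = 120L,
                       n_shared = 80L,
                       attachment_edges_per_node = 2L,
                       membrane_fraction = 0.63,
                       n_planted_hubs = 8L,
                       hub_degree_fraction = 0.45,
                       true_edge_channel_dist = dist_spec("beta", shape1 = 8, shape2 = 2),
                       noise_edge_channel_dist = dist_spec("beta", shape1 = 2, shape2 = 8),
                       n_channels = 3L,
                       physical_prob = 0.6,
                       publication_dist = dist_spec("pois", lambda = 4),
                       mi_given_physical_dist = dist_spec("beta", shape1 = 5, shape2 = 3),
                       conservation_dist = dist_spec("pois", lambda = 2),
                       noise_edge_fraction = 0.3,
                       seed = 1L) {
  spec <- list(
    n_sperm = as.integer(n_sperm), n_egg = as.integer(n_egg),
    n_shared = as.integer(n_shared),
    attachment_edges_per_node = as.integer(attachment_edges_per_node),
    membrane_fraction = membrane_fraction,
    n_planted_hubs = as.integer(n_planted_hubs),
    hub_degree_fraction = hub_degree_fraction,
    true_edge_channel_dist = true_edge_channel_dist,
    noise_edge_channel_dist = noise_edge_channel_dist,
    n_channels = as.integer(n_channels),
    physical_prob = physical_prob,
    publication_dist = publication_dist,
    mi_given_physical_dist = mi_given_physical_dist,
    conservation_dist = conservation_dist,
    noise_edge_fraction = noise_edge_fraction,
    seed = as.integer(seed)
  )
  with(spec, {
    if (n_shared > min(n_sperm, n_egg))
      stop("n_shared must not exceed min(n_sperm, n_egg)", call. = FALSE)
    if (n_planted_hubs > n_shared)
      stop("n_planted_hubs must not exceed n_shared", call. = FALSE)
    if (membrane_fraction < 0 || membrane_fraction > 1 ||
        physical_prob < 0 || physical_prob > 1 ||
        hub_degree_fraction <= 0 || hub_degree_fraction > 1 ||
        noise_edge_fraction < 0)
      stop("probability parameter outside its range", call. = FALSE)
    if (attachment_edges_per_node < 1 ||
        attachment_edges_per_node >= min(n_shared, n_sperm, n_egg))
      stop("attachment_edges_per_node out of range", call. = FALSE)
  })
  structure(spec, class = "study_spec")
}

#' Seeded preferential-attachment network
#'
#' Barabasi-Albert-style growth: each new vertex attaches to `m` existing
#' vertices with probability proportional to degree.  The graph is simple
#' and connected with `m * (n - m) + choose(m, 2)` edges (the first `m + 1`
#' vertices contribute `choose(m + 1, 2) - ...` growth edges, i.e. vertex
#' `i` attaches `min(i - 1, m)` edges).
#'
#' @param n number of vertices (`n > m`).
#' @param m edges attached per new vertex.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @param labels optional character vector of `n` vertex names; defaults to
#'   `v1..vn`.
#' @return A network ([pin_network()]).
#' @export
generate_powerlaw_network <- function(n, m, seed = NULL, labels = NULL) {
  n <- as.integer(n); m <- as.integer(m)
  if (m < 1 || m >= n) stop("need 1 <= m < n", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  g <- igraph::sample_pa(n, m = m, directed = FALSE)
  if (is.null(labels)) labels <- paste0("v", seq_len(n))
  stopifnot(length(labels) == n)
  igraph::V(g)$name <- labels
  g
}

# wire planted hubs up to a target degree by adding edges to random
# non-neighbors; returns the augmented graph
.plant_hubs <- function(core, hubs, target_degree) {
  nodes <- .node_names(core)
  for (h in hubs) {
    need <- target_degree - igraph::degree(core, h)
    if (need <= 0) next
    nbrs <- names(igraph::neighbors(core, h))
    candidates <- setdiff(nodes, c(h, nbrs))
    partners <- sample(candidates, min(need, length(candidates)))
    core <- igraph::add_edges(core, rbind(rep(h, length(partners)), partners))
  }
  core
}

# sample k distinct node pairs that are not edges of g (and not self-pairs)
.sample_non_edges <- function(g, k) {
  nodes <- .node_names(g)
  existing <- .edge_df(g)
  have <- paste(existing$protein_a, existing$protein_b, sep = "\r")
  out_a <- character(); out_b <- character()
  guard <- 0L
  while (length(out_a) < k && guard < 50L) {
    need <- k - length(out_a)
    a <- sample(nodes, 2L * need + 10L, replace = TRUE)
    b <- sample(nodes, 2L * need + 10L, replace = TRUE)
    ok <- a != b
    a <- a[ok]; b <- b[ok]
    lo <- pmin(a, b); hi <- pmax(a, b)
    key <- paste(lo, hi, sep = "\r")
    new <- !(key %in% have) & !duplicated(key)
    take <- which(new)[seq_len(min(need, sum(new)))]
    out_a <- c(out_a, lo[take]); out_b <- c(out_b, hi[take])
    have <- c(have, key[take])
    guard <- guard + 1L
  }
  data.frame(protein_a = out_a, protein_b = out_b, stringsAsFactors = FALSE)
}

# evidence table for a set of edges with truth labels
.emit_evidence <- function(edges, truth, spec) {
  n <- nrow(edges)
  ev <- edges
  for (j in seq_len(spec$n_channels)) {
    s <- numeric(n)
    s[truth] <- .sample_dist(spec$true_edge_channel_dist, sum(truth))
    s[!truth] <- .sample_dist(spec$noise_edge_channel_dist, sum(!truth))
    ev[[sprintf("score_ch%d", j)]] <- pmin(pmax(s, 0), 1)
  }
  ev$is_physical <- runif(n) < spec$physical_prob
  ev$mi_score <- NA_real_
  nphys <- sum(ev$is_physical)
  ev$mi_score[ev$is_physical] <-
    pmin(pmax(.sample_dist(spec$mi_given_physical_dist, nphys), 0), 1)
  ev$n_publications <- as.integer(.sample_dist(spec$publication_dist, n))
  ev$n_conserved_species <- as.integer(.sample_dist(spec$conservation_dist, n))
  ev <- ev[, c("protein_a", "protein_b",
               sprintf("score_ch%d", seq_len(spec$n_channels)),
               "mi_score", "n_publications", "is_physical",
               "n_conserved_species")]
  as_evidence(ev)
}

#' Generate a synthetic two-compartment interaction study
#'
#' Builds a shared scale-free core by preferential attachment, plants
#' `n_planted_hubs` membrane-annotated hub proteins wired to
#' `hub_degree_fraction * n_shared` shared-core partners, embeds the core in
#' a sperm and an egg compartment network (each a preferential-attachment
#' graph over its own proteins unioned with the core), adds spurious edges
#' at `noise_edge_fraction`, and emits each edge as an evidence record whose
#' channel scores are drawn from the true- or noise-edge distribution
#' according to its ground-truth label.  Fully reproducible from
#' `spec$seed`.
#'
#' @param spec a [study_spec()].
#' @return An object of class `gamete_study`: a list with `sperm_evidence`,
#'   `egg_evidence` (canonical evidence tables), `annotations` (data frame
#'   as from [read_annotations()]), `ground_truth` (list with
#'   `planted_hubs`, `planted_hub_symbols`, `true_edges`) and `spec`.
#' @export
generate_study <- function(spec = study_spec()) {
  stopifnot(inherits(spec, "study_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  n_total <- spec$n_sperm + spec$n_egg - spec$n_shared
  acc <- sprintf("P%05d", seq_len(n_total))
  sym <- sprintf("GENE%05d", seq_len(n_total))
  shared <- acc[seq_len(spec$n_shared)]
  sperm_only <- acc[spec$n_shared + seq_len(spec$n_sperm - spec$n_shared)]
  egg_only <- acc[spec$n_sperm + seq_len(spec$n_egg - spec$n_shared)]
  sperm_nodes <- c(shared, sperm_only)
  egg_nodes <- c(shared, egg_only)

  m <- spec$attachment_edges_per_node
  core <- generate_powerlaw_network(spec$n_shared, m, labels = sample(shared))
  hubs <- sort(sample(shared, spec$n_planted_hubs))
  target_degree <- ceiling(spec$hub_degree_fraction * spec$n_shared)
  core <- .plant_hubs(core, hubs, target_degree)

  compartment_graph <- function(nodes) {
    g <- generate_powerlaw_network(length(nodes), m, labels = sample(nodes))
    union_networks(g, core)
  }
  sperm_true <- compartment_graph(sperm_nodes)
  egg_true <- compartment_graph(egg_nodes)

  emit <- function(gtrue) {
    true_edges <- .edge_df(gtrue)
    n_noise <- round(spec$noise_edge_fraction * nrow(true_edges))
    noise_edges <- .sample_non_edges(gtrue, n_noise)
    edges <- rbind(true_edges, noise_edges)
    truth <- rep(c(TRUE, FALSE), c(nrow(true_edges), nrow(noise_edges)))
    list(evidence = .emit_evidence(edges, truth, spec), true_edges = true_edges)
  }
  sperm <- emit(sperm_true)
  egg <- emit(egg_true)

  membrane <- runif(n_total) < spec$membrane_fraction
  membrane[acc %in% hubs] <- TRUE
  sp_flag <- membrane & (runif(n_total) < 0.5)
  tm_flag <- membrane & !sp_flag
  tm_flag <- tm_flag | (membrane & (runif(n_total) < 0.3))
  compartments <- ifelse(acc %in% shared, "sperm;egg",
                         ifelse(acc %in% sperm_only, "sperm", "egg"))
  annotations <- data.frame(
    accession = acc, gene_symbol = sym,
    has_signal_peptide = sp_flag, has_transmembrane = tm_flag,
    compartments = compartments, stringsAsFactors = FALSE
  )

  structure(
    list(
      sperm_evidence = sperm$evidence,
      egg_evidence = egg$evidence,
      annotations = annotations,
      ground_truth = list(
        planted_hubs = hubs,
        planted_hub_symbols = sym[match(hubs, acc)],
        true_edges = rbind(
          cbind(sperm$true_edges, compartment = "sperm"),
          cbind(egg$true_edges, compartment = "egg")
        )
      ),
      spec = spec
    ),
    class = "gamete_study"
  )
}

#' @export
print.gamete_study <- function(x, ...) {
  cat("Synthetic two-compartment interaction study\n")
  cat(sprintf("  sperm evidence: %d records; egg evidence: %d records\n",
              nrow(x$sperm_evidence), nrow(x$egg_evidence)))
  cat(sprintf("  proteins annotated: %d; planted hubs: %d; seed: %d\n",
              nrow(x$annotations), length(x$ground_truth$planted_hubs),
              x$spec$seed))
  invisible(x)
}

#' Write a generated study to disk
#'
#' Emits `sperm_evidence.tsv`, `egg_evidence.tsv`, `annotations.tsv`, a
#' `ground_truth.json` and a `study_spec.json` sidecar recording the full
#' generating specification for provenance.
#'
#' @param study a `gamete_study` from [generate_study()].
#' @param outdir output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_study <- function(study, outdir) {
  stopifnot(inherits(study, "gamete_study"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    sperm_evidence = file.path(outdir, "sperm_evidence.tsv"),
    egg_evidence = file.path(outdir, "egg_evidence.tsv"),
    annotations = file.path(outdir, "annotations.tsv"),
    ground_truth = file.path(outdir, "ground_truth.json"),
    spec = file.path(outdir, "study_spec.json")
  )
  write_evidence(study$sperm_evidence, paths[["sperm_evidence"]])
  write_evidence(study$egg_evidence, paths[["egg_evidence"]])
  ann <- study$annotations
  out <- data.frame(accession = ann$accession, gene_symbol = ann$gene_symbol,
                    signal_peptide = as.integer(ann$has_signal_peptide),
                    transmembrane = as.integer(ann$has_transmembrane),
                    compartments = ann$compartments)
  write.table(out, paths[["annotations"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(study$ground_truth, paths[["ground_truth"]],
                       auto_unbox = TRUE, digits = NA)
  spec_plain <- lapply(unclass(study$spec), function(x)
    if (inherits(x, "dist_spec")) unclass(x) else x)
  jsonlite::write_json(spec_plain, paths[["spec"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
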