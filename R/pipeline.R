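.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

.log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

.counts <- function(net) {
  c(nodes = igraph::vcount(net), edges = igraph::ecount(net))
}

#' Run the full sperm-egg drug-target discovery pipeline
#'
#' Executes, in order: build the sperm and egg networks from their evidence
#' tables; intersect them into the overlap network; restrict to the
#' membrane (signal-peptide/transmembrane) subnetwork; apply the
#' combined-score and physical/MI high-confidence filters to the membrane
#' network's evidence; build the two high-confidence networks and merge
#' them into a union network retaining every membrane protein (so proteins
#' whose every interaction was filtered out remain visible as isolated
#' nodes); compute centrality, shortest-path and power-law statistics on
#' the union; classify hubs and bottlenecks by the half-of-maximum
#' criterion; and attach known drugs.
#'
#' Evidence inputs may be file paths (read with [read_evidence()] /
#' [read_annotations()]) or in-memory data frames.  With `filter_first =
#' TRUE` the high-confidence filters are applied to each compartment's
#' evidence *before* network assembly instead of after membrane
#' restriction.
#'
#' Artifacts (networks in SIF, centrality/target TSVs, path histogram,
#' power-law fit and run summary as JSON) are written only when `outdir` is
#' given, and only on success.
#'
#' @param sperm_evidence,egg_evidence evidence tables or TSV paths.
#' @param annotations annotation table or TSV path.
#' @param drug_associations association list ([drug_association_table()]) or
#'   TSV path; defaults to the bundled table.
#' @param filters a [filter_config()].
#' @param outdir optional output directory for artifacts.
#' @param filter_first apply confidence filters before network assembly.
#' @param verbose emit one log line per stage.
#' @return An object of class `pin_run`: a list with the networks
#'   (`sperm`, `egg`, `overlap`, `membrane`, `functional`, `physical`,
#'   `union`), `centrality`, `paths`, `powerlaw` (or `NULL` when the union
#'   degree spectrum cannot support a fit), `targets`, and a `summary` list
#'   of per-stage node/edge counts and the thresholds used.
#' @export
run_pipeline <- function(sperm_evidence, egg_evidence, annotations,
                         drug_associations = NULL,
                         filters = filter_config(),
                         outdir = NULL,
                         filter_first = FALSE,
                         verbose = TRUE) {
  stopifnot(inherits(filters, "filter_config"))
  if (is.character(sperm_evidence))
    sperm_evidence <- .stage("read sperm evidence", read_evidence(sperm_evidence))
  if (is.character(egg_evidence))
    egg_evidence <- .stage("read egg evidence", read_evidence(egg_evidence))
  if (is.character(annotations))
    annotations <- .stage("read annotations", read_annotations(annotations))
  assoc <- if (is.null(drug_associations)) drug_association_table()
           else if (is.character(drug_associations)) drug_association_table(drug_associations)
           else drug_associations
  sperm_evidence$combined_score <- NULL
  egg_evidence$combined_score <- NULL
  sperm_evidence <- .stage("validate sperm evidence", as_evidence(sperm_evidence))
  egg_evidence <- .stage("validate egg evidence", as_evidence(egg_evidence))

  if (filter_first) {
    pre <- function(ev) {
      fun <- filter_functional(ev, filters)
      phy <- filter_physical(ev, filters)
      fun$combined_score <- NULL
      as_evidence(unique(rbind(fun, phy)))
    }
    sperm_evidence <- .stage("pre-filter sperm evidence", pre(sperm_evidence))
    egg_evidence <- .stage("pre-filter egg evidence", pre(egg_evidence))
  }

  sperm_net <- .stage("build sperm network", build_network(sperm_evidence))
  egg_net <- .stage("build egg network", build_network(egg_evidence))
  .log_stage(verbose, "sperm network: %d nodes, %d edges",
             igraph::vcount(sperm_net), igraph::ecount(sperm_net))
  .log_stage(verbose, "egg network: %d nodes, %d edges",
             igraph::vcount(egg_net), igraph::ecount(egg_net))

  overlap <- .stage("overlap network", overlap_network(sperm_net, egg_net))
  .log_stage(verbose, "overlap network: %d nodes, %d edges",
             igraph::vcount(overlap), igraph::ecount(overlap))

  membrane <- .stage("membrane subnetwork",
                     membrane_subnetwork(overlap, annotations))
  .log_stage(verbose, "membrane subnetwork: %d nodes, %d edges",
             igraph::vcount(membrane), igraph::ecount(membrane))

  # evidence restricted to membrane-network edges, merged across compartments
  mem_edges <- .edge_df(membrane)
  mem_key <- paste(mem_edges$protein_a, mem_edges$protein_b, sep = "\r")
  pool <- .stage("merge evidence",
                 as_evidence(rbind(sperm_evidence, egg_evidence)))
  pool$combined_score <- NULL
  pool_key <- paste(pool$protein_a, pool$protein_b, sep = "\r")
  mem_evidence <- pool[pool_key %in% mem_key, , drop = FALSE]

  functional <- .stage("functional filter",
                       filter_functional(mem_evidence, filters))
  physical <- .stage("physical filter", filter_physical(mem_evidence, filters))
  .log_stage(verbose, "high-confidence functional: %d of %d records",
             nrow(functional), nrow(mem_evidence))
  .log_stage(verbose, "high-confidence physical: %d of %d records",
             nrow(physical), nrow(mem_evidence))

  net_fun <- build_network(functional)
  net_phy <- build_network(physical)
  union_hc <- .stage("union network", union_networks(net_fun, net_phy))
  # retain every membrane protein: nodes whose interactions were all
  # filtered out stay in the analysis with degree 0
  union_hc <- union_networks(union_hc, pin_network(.node_names(membrane)))
  .log_stage(verbose, "high-confidence union: %d nodes, %d edges",
             igraph::vcount(union_hc), igraph::ecount(union_hc))

  centrality <- .stage("topology metrics",
                       centrality_table(union_hc, annotations))
  paths <- .stage("path statistics", path_stats(union_hc))
  powerlaw <- tryCatch(fit_power_law(node_degrees(union_hc)),
                       error = function(e) NULL)

  targets <- if (igraph::vcount(union_hc) > 0) {
    t0 <- .stage("classify targets", classify_targets(centrality))
    .stage("map drugs", map_drugs(t0, assoc))
  } else {
    NULL
  }
  .log_stage(verbose, "putative targets (hubs): %d",
             if (is.null(targets)) 0L else sum(targets$is_hub))

  summary <- list(
    stage_counts = list(
      sperm = .counts(sperm_net), egg = .counts(egg_net),
      overlap = .counts(overlap), membrane = .counts(membrane),
      functional = .counts(net_fun), physical = .counts(net_phy),
      union = .counts(union_hc)
    ),
    evidence_counts = list(
      sperm = nrow(sperm_evidence), egg = nrow(egg_evidence),
      membrane = nrow(mem_evidence),
      functional_kept = nrow(functional), physical_kept = nrow(physical)
    ),
    filters = unclass(filters),
    filter_first = filter_first,
    n_targets = if (is.null(targets)) 0L else sum(targets$is_hub),
    characteristic_path_length = paths$characteristic_path_length,
    powerlaw = if (is.null(powerlaw)) NULL else
      list(exponent = powerlaw$exponent, r_squared = powerlaw$r_squared,
           n_points = powerlaw$n_points),
    package_version = as.character(utils::packageVersion("gametePIN"))
  )

  run <- structure(
    list(sperm = sperm_net, egg = egg_net, overlap = overlap,
         membrane = membrane, functional = net_fun, physical = net_phy,
         union = union_hc, centrality = centrality, paths = paths,
         powerlaw = powerlaw, targets = targets, summary = summary),
    class = "pin_run"
  )
  if (!is.null(outdir)) write_run_artifacts(run, outdir)
  run
}

#' Write the artifacts of a pipeline run
#'
#' @param run a `pin_run` from [run_pipeline()].
#' @param outdir output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_run_artifacts <- function(run, outdir) {
  stopifnot(inherits(run, "pin_run"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- character()
  for (nm in c("sperm", "egg", "overlap", "membrane", "union")) {
    f <- file.path(outdir, paste0(nm, "_network.sif"))
    write_network(run[[nm]], f, "sif")
    p <- c(p, f)
  }
  f <- file.path(outdir, "centrality.tsv")
  write.table(run$centrality, f, sep = "\t", quote = FALSE, row.names = FALSE)
  p <- c(p, f)
  f <- file.path(outdir, "path_histogram.tsv")
  hist_df <- data.frame(path_length = names(run$paths$histogram),
                        n_pairs = as.integer(run$paths$histogram))
  write.table(hist_df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  p <- c(p, f)
  if (!is.null(run$powerlaw)) {
    f <- file.path(outdir, "powerlaw_fit.json")
    jsonlite::write_json(
      list(exponent = run$powerlaw$exponent,
           intercept = run$powerlaw$intercept,
           r_squared = run$powerlaw$r_squared,
           n_points = run$powerlaw$n_points),
      f, auto_unbox = TRUE, digits = NA)
    p <- c(p, f)
  }
  if (!is.null(run$targets)) {
    f <- file.path(outdir, "targets.tsv")
    target_report(run$targets, f)
    p <- c(p, f)
  }
  f <- file.path(outdir, "run_summary.json")
  jsonlite::write_json(run$summary, f, auto_unbox = TRUE, digits = NA)
  p <- c(p, f)
  invisible(p)
}

#' @export
print.pin_run <- function(x, ...) {
  cat("Sperm-egg interaction network pipeline run\n")
  sc <- x$summary$stage_counts
  for (nm in names(sc)) {
    cat(sprintf("  %-11s %5d nodes %6d edges\n", nm, sc[[nm]]["nodes"],
                sc[[nm]]["edges"]))
  }
  cat(sprintf("  putative targets (hubs): %d\n", x$summary$n_targets))
  if (!is.na(x$summary$characteristic_path_length))
    cat(sprintf("  characteristic path length: %.3f\n",
                x$summary$characteristic_path_length))
  if (!is.null(x$summary$powerlaw))
    cat(sprintf("  degree-distribution fit: exponent %.3f (R2 = %.3f)\n",
                x$summary$powerlaw$exponent, x$summary$powerlaw$r_squared))
  invisible(x)
}

#' @export
summary.pin_run <- function(object, ...) {
  object$summary
}
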