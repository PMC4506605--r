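#' Load a drug-association table
#'
#' Reads a two-column TSV (`gene_symbol`, `drug`; one row per association)
#' into a named list mapping gene symbols to character vectors of drug
#' names.  With no argument, the table bundled with the package is loaded:
#' the known-drug associations for the putative sperm-egg interaction
#' targets (FN1, EGFR, ITGAV, ITGB3, COL1A1, ITGB5).  Drug names are kept
#' verbatim as curated; no brand/generic normalization is attempted.
#'
#' @param path path to an association TSV; default is the bundled table.
#' @return Named list: gene symbol -> character vector of drug names.
#' @export
drug_association_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "drug_associations.tsv",
                        package = "gametePIN", mustWork = TRUE)
  }
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("gene_symbol", "drug") %in% names(tab))) {
    stop("drug association table needs columns gene_symbol, drug",
         call. = FALSE)
  }
  split(tab$drug, factor(tab$gene_symbol, levels = unique(tab$gene_symbol)))
}

#' Reference hub centrality table
#'
#' The curated degree/betweenness/closeness values of the 13 high-degree
#' proteins of the published sperm-egg interaction network (integrin,
#' fibronectin, EGF-receptor, collagen and tetraspanin families), as a data
#' frame suitable for [classify_targets()].  Values are as printed (one
#' decimal for betweenness/closeness).  Note the published drug table lists
#' EGFR at degree 25 while this centrality table lists 26; the discrepancy
#' is preserved as curated, not reconciled.
#'
#' @return Data frame with columns `gene_symbol`, `protein_family`,
#'   `degree`, `betweenness`, `closeness`.
#' @export
reference_hub_table <- function() {
  path <- system.file("extdata", "reference_hub_centrality.tsv",
                      package = "gametePIN", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Classify hub and bottleneck proteins by the half-of-maximum criterion
#'
#' A protein is a *hub* if its degree is at least half the maximum degree in
#' the table, and a *bottleneck* if its betweenness is at least half the
#' maximum betweenness.  Both thresholds are inclusive: printed centrality
#' tables are typically rounded, and a strict rule would drop boundary
#' values created by rounding.  Putative drug targets are the hubs;
#' bottleneck status is reported alongside.
#'
#' @param tbl centrality data frame with columns `gene_symbol`, `degree`,
#'   `betweenness`, `closeness` (and optionally `accession`), e.g. from
#'   [centrality_table()].
#' @return An object of class `target_calls`: the input rows ordered by
#'   degree (desc), betweenness (desc), gene symbol (asc), with added
#'   logical columns `is_hub`, `is_bottleneck` and a list column `drugs`
#'   (empty until [map_drugs()] is applied).
#' @export
classify_targets <- function(tbl) {
  if (NROW(tbl) == 0) stop("empty centrality table", call. = FALSE)
  required <- c("gene_symbol", "degree", "betweenness", "closeness")
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    stop("centrality table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tbl <- as.data.frame(tbl, stringsAsFactors = FALSE)
  if (is.null(tbl$accession)) tbl$accession <- tbl$gene_symbol
  max_deg <- max(tbl$degree)
  max_bc <- max(tbl$betweenness)
  tbl$is_hub <- tbl$degree >= max_deg / 2
  tbl$is_bottleneck <- if (max_bc > 0) tbl$betweenness >= max_bc / 2 else
    rep(TRUE, nrow(tbl))
  ord <- order(-tbl$degree, -tbl$betweenness, tbl$gene_symbol)
  tbl <- tbl[ord, c("accession", "gene_symbol", "degree", "betweenness",
                    "closeness", "is_hub", "is_bottleneck")]
  tbl$drugs <- rep(list(character()), nrow(tbl))
  rownames(tbl) <- NULL
  class(tbl) <- c("target_calls", "data.frame")
  tbl
}

#' Attach known drugs to classified targets
#'
#' Populates the `drugs` column by gene-symbol lookup in a drug-association
#' table; symbols without an entry get an empty list.  Row order and all
#' other columns are unchanged.
#'
#' @param calls a `target_calls` object from [classify_targets()].
#' @param assoc association list from [drug_association_table()].
#' @return The updated `target_calls` object.
#' @export
map_drugs <- function(calls, assoc = drug_association_table()) {
  stopifnot(inherits(calls, "target_calls"))
  calls$drugs <- lapply(calls$gene_symbol, function(s) {
    d <- assoc[[s]]
    if (is.null(d)) character() else as.character(d)
  })
  calls
}

#' Write a target report as TSV
#'
#' One row per target call, drugs serialized semicolon-separated.
#'
#' @param calls a `target_calls` object.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
target_report <- function(calls, path) {
  stopifnot(inherits(calls, "target_calls"))
  out <- as.data.frame(calls[, c("accession", "gene_symbol", "degree",
                                 "betweenness", "closeness",
                                 "is_hub", "is_bottleneck")])
  out$drugs <- vapply(calls$drugs, paste, character(1), collapse = ";")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.target_calls <- function(x, ...) {
  # column-subset views lose the call structure; print them plainly
  if (!all(c("is_hub", "is_bottleneck", "drugs") %in% names(x))) {
    y <- x
    class(y) <- "data.frame"
    return(print(y, ...))
  }
  hubs <- sum(x$is_hub)
  cat(sprintf("Target calls: %d proteins, %d putative targets (hubs), %d bottlenecks\n",
              nrow(x), hubs, sum(x$is_bottleneck)))
  show <- as.data.frame(head(x[x$is_hub, ], 15))
  show$drugs <- vapply(show$drugs, function(d) {
    if (length(d) == 0) "" else if (length(d) <= 2) paste(d, collapse = ";")
    else sprintf("%s;... (%d)", d[1], length(d))
  }, character(1))
  print(show)
  if (hubs > 15) cat(sprintf("  ... and %d more hubs\n", hubs - 15))
  invisible(x)
}
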