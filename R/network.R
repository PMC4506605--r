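#' Construct a protein interaction network
#'
#' Networks are undirected simple `igraph` graphs whose vertex names are
#' protein accessions.  Self-loops and duplicate edges are disallowed;
#' isolated vertices are permitted.
#'
#' @param nodes character vector of accessions.
#' @param edges two-column character matrix or data frame of accession pairs;
#'   endpoints must appear in `nodes`.
#' @return An undirected simple `igraph` graph.
#' @export
pin_network <- function(nodes = character(), edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names", call. = FALSE)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (!is.null(edges) && NROW(edges) > 0) {
    em <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(em) <- "character"
    if (any(em[, 1] == em[, 2])) stop("self-loop in edge list", call. = FALSE)
    if (!all(em %in% nodes)) {
      stop("edge endpoint(s) not in node set: ",
           paste(head(setdiff(as.vector(em), nodes), 5), collapse = ", "),
           call. = FALSE)
    }
    g <- igraph::add_edges(g, t(em))
    g <- igraph::simplify(g)
  }
  g
}

.check_network <- function(net) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::is_directed(net)) stop("network must be undirected", call. = FALSE)
  if (!igraph::is_simple(net)) stop("network must be simple", call. = FALSE)
  if (igraph::vcount(net) > 0 && is.null(igraph::V(net)$name)) {
    stop("network vertices must be named", call. = FALSE)
  }
  invisible(net)
}

.node_names <- function(net) {
  if (igraph::vcount(net) == 0) character() else igraph::V(net)$name
}

# canonical edge data frame (a < b), sorted; empty graphs give 0 rows
.edge_df <- function(net) {
  el <- igraph::as_edgelist(net, names = TRUE)
  if (nrow(el) == 0) {
    return(data.frame(protein_a = character(), protein_b = character(),
                      stringsAsFactors = FALSE))
  }
  a <- pmin(el[, 1], el[, 2])
  b <- pmax(el[, 1], el[, 2])
  df <- data.frame(protein_a = a, protein_b = b, stringsAsFactors = FALSE)
  df <- df[order(df$protein_a, df$protein_b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Test two networks for equality (same node set, same edge set)
#'
#' @param a,b networks.
#' @return `TRUE` or `FALSE`.
#' @export
network_identical <- function(a, b) {
  setequal(.node_names(a), .node_names(b)) &&
    identical(.edge_df(a), .edge_df(b))
}

#' Build a network from an evidence table
#'
#' Nodes are all accessions appearing in any record; edges are the distinct
#' canonical pairs.
#'
#' @param ev canonicalized evidence data frame (see [as_evidence()]).
#' @return A network ([pin_network()]).
#' @export
build_network <- function(ev) {
  if (NROW(ev) == 0) return(pin_network())
  nodes <- sort(unique(c(ev$protein_a, ev$protein_b)))
  pin_network(nodes, cbind(ev$protein_a, ev$protein_b))
}

#' Write a network to SIF or two-column edge TSV
#'
#' The SIF dialect is `node<TAB>pp<TAB>node`, one line per edge, plus one
#' bare line per isolated node.  The edge-TSV format has a header
#' `protein_a<TAB>protein_b`; isolated nodes are written as rows with an
#' empty second field so that the round trip through [read_network()]
#' reproduces the network exactly.
#'
#' @param net a network.
#' @param path output path.
#' @param fmt `"sif"` or `"edge-tsv"`.
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path, fmt = c("sif", "edge-tsv")) {
  fmt <- match.arg(fmt)
  .check_network(net)
  ed <- .edge_df(net)
  iso <- sort(.node_names(net)[igraph::degree(net) == 0])
  if (fmt == "sif") {
    edge_lines <- if (nrow(ed)) paste(ed$protein_a, "pp", ed$protein_b,
                                      sep = "\t") else character()
    lines <- c(edge_lines, iso)
  } else {
    lines <- c("protein_a\tprotein_b",
               paste(ed$protein_a, ed$protein_b, sep = "\t"),
               if (length(iso)) paste0(iso, "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path input path.
#' @param fmt `"sif"` or `"edge-tsv"`.
#' @return A network.
#' @export
read_network <- function(path, fmt = c("sif", "edge-tsv")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("network file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (fmt == "edge-tsv") {
    if (length(lines) == 0 || lines[1] != "protein_a\tprotein_b") {
      stop("edge-tsv file lacks the expected header", call. = FALSE)
    }
    lines <- lines[-1]
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  iso <- character(); a <- character(); b <- character()
  for (p in parts) {
    p <- p[p != ""]
    if (length(p) == 0) next
    if (length(p) == 1) {
      iso <- c(iso, p)
    } else if (fmt == "sif") {
      if (length(p) != 3 || p[2] != "pp") {
        stop("malformed SIF line: ", paste(p, collapse = "\t"), call. = FALSE)
      }
      a <- c(a, p[1]); b <- c(b, p[3])
    } else {
      a <- c(a, p[1]); b <- c(b, p[2])
    }
  }
  nodes <- sort(unique(c(a, b, iso)))
  pin_network(nodes, if (length(a)) cbind(a, b))
}
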