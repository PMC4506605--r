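#' Overlap (intersection) network of two compartment networks
#'
#' The overlap network contains the nodes present in *both* inputs, and the
#' union of the two edge sets restricted to pairs whose endpoints are both
#' shared.  Edge-union on shared nodes (rather than edge-intersection) is
#' used so that an interaction observed in either compartment between two
#' shared proteins is retained; it is the only semantics under which the
#' overlap can carry more edges than the smaller input network.
#'
#' @param net_a,net_b networks ([pin_network()]).
#' @return A network on the shared node set.
#' @export
overlap_network <- function(net_a, net_b) {
  .check_network(net_a); .check_network(net_b)
  shared <- intersect(.node_names(net_a), .node_names(net_b))
  ed <- rbind(.edge_df(net_a), .edge_df(net_b))
  keep <- ed$protein_a %in% shared & ed$protein_b %in% shared
  ed <- unique(ed[keep, , drop = FALSE])
  pin_network(sort(shared), ed)
}

#' Union of two networks
#'
#' Node union and deduplicated edge union.
#'
#' @param net_a,net_b networks.
#' @return A network.
#' @export
union_networks <- function(net_a, net_b) {
  .check_network(net_a); .check_network(net_b)
  nodes <- sort(unique(c(.node_names(net_a), .node_names(net_b))))
  ed <- unique(rbind(.edge_df(net_a), .edge_df(net_b)))
  pin_network(nodes, ed)
}

#' Membrane-protein induced subnetwork
#'
#' Restricts a network to the proteins annotated with a signal peptide
#' and/or a transmembrane domain, keeping every edge whose endpoints are
#' both retained.  A network node absent from the annotation table is an
#' error: silently treating unannotated proteins as non-membrane would
#' change downstream target lists invisibly.
#'
#' @param net a network.
#' @param annotations annotation data frame from [read_annotations()].
#' @return The induced subgraph on membrane-annotated nodes.
#' @export
membrane_subnetwork <- function(net, annotations) {
  .check_network(net)
  nodes <- .node_names(net)
  missing <- setdiff(nodes, annotations$accession)
  if (length(missing)) {
    stop("network node(s) missing from annotation table: ",
         paste(head(missing, 10), collapse = ", "), call. = FALSE)
  }
  memb <- annotations$accession[.membrane_flag(annotations)]
  keep <- intersect(nodes, memb)
  igraph::induced_subgraph(net, keep)
}
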