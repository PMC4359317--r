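#' Build the bipartite miRNA-pathway association network
#'
#' Creates an edge for every association with a q-value at or below the
#' threshold; nodes are the miRNAs and pathways incident to at least one
#' edge (isolated nodes are omitted). The network is bipartite by
#' construction and carries at most one edge per pathway, since each
#' pathway has a single best miRNA.
#'
#' @param object an \linkS4class{AssociationSet}
#' @param qThreshold edge-inclusion threshold on the q-value (default 0.05;
#'   use 1 to keep every association)
#' @return an \linkS4class{AssociationNetwork}
#' @export
buildNetwork <- function(object, qThreshold = 0.05) {
  stopifnot(is(object, "AssociationSet"))
  df <- object@table
  keep <- !is.na(df$mirna_id) & !is.na(df$q_value) & df$q_value <= qThreshold
  edges <- data.frame(mirna_id = df$mirna_id[keep],
                      pathway_id = df$pathway_id[keep],
                      q_value = df$q_value[keep], stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  um <- unique(edges$mirna_id); up <- unique(edges$pathway_id)
  nodes <- data.frame(id = c(um, up),
                      type = c(rep("mirna", length(um)),
                               rep("pathway", length(up))),
                      stringsAsFactors = FALSE)
  new("AssociationNetwork", nodes = nodes, edges = edges,
      qThreshold = qThreshold)
}

#' Export a network for Cytoscape
#'
#' SIF: one line per edge, \code{mirna targets_pathway pathway}. GraphML:
#' written through igraph with a \code{type} node attribute, re-readable by
#' any generic GraphML parser.
#'
#' @param net an \linkS4class{AssociationNetwork}
#' @param path output file path
#' @param format \code{"sif"} or \code{"graphml"}
#' @return invisibly, \code{path}
#' @export
exportNetwork <- function(net, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  e <- net@edges
  if (format == "sif") {
    lines <- if (nrow(e))
      paste(e$mirna_id, "targets_pathway", e$pathway_id) else character()
    writeLines(lines, path)
  } else {
    g <- igraph::graph_from_data_frame(
      e[c("mirna_id", "pathway_id")], directed = FALSE,
      vertices = net@nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
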