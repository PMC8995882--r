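#' @keywords internal
"_PACKAGE"

#' Edge categories of the regulatory network
#'
#' The four classes of directed regulation that make up the typed network:
#' TF represses/activates a miRNA (\code{TF_MIRNA}), TF regulates a gene
#' (\code{TF_GENE}), miRNA represses a gene (\code{MIRNA_GENE}) and miRNA
#' represses a TF (\code{MIRNA_TF}).
#'
#' @export
EDGE_CATEGORIES <- c("TF_MIRNA", "TF_GENE", "MIRNA_GENE", "MIRNA_TF")

#' Node roles of the regulatory network
#'
#' \code{TF_AND_GENE} marks a node present in both the TF universe and the
#' gene universe (a transcription factor that is itself a regulated gene of
#' interest, e.g. ESR1 in immune gene lists).
#'
#' @export
NODE_ROLES <- c("TF", "MIRNA", "GENE", "TF_AND_GENE")

REGULATION_MODES <- c("activation", "repression", "unspecified")

#' Construct a typed regulatory network
#'
#' A `typed_network` holds a role map (node -> TF / MIRNA / GENE /
#' TF_AND_GENE) and a set of categorised directed edges. Edges are simple per
#' (source, target, category); self-edges are forbidden. This is the container
#' for the merged TF-miRNA-gene network and all of its sub-networks.
#'
#' @param nodes data.frame with columns `node`, `role`.
#' @param edges data.frame with columns `source`, `target`, `category` and
#'   optionally `mode` (defaults to "unspecified").
#' @return An object of class `typed_network`.
#' @export
typed_network <- function(nodes, edges) {
  stopifnot(is.data.frame(nodes), all(c("node", "role") %in% names(nodes)))
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(source = character(), target = character(),
                        category = character(), mode = character(),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("source", "target", "category") %in% names(edges)))
  if (!"mode" %in% names(edges)) edges$mode <- rep("unspecified", nrow(edges))
  nodes <- data.frame(node = as.character(nodes$node),
                      role = as.character(nodes$role),
                      stringsAsFactors = FALSE)
  edges <- data.frame(source = as.character(edges$source),
                      target = as.character(edges$target),
                      category = as.character(edges$category),
                      mode = as.character(edges$mode),
                      stringsAsFactors = FALSE)
  bad_role <- setdiff(unique(nodes$role), NODE_ROLES)
  if (length(bad_role))
    stop("unknown node role(s): ", paste(bad_role, collapse = ", "))
  bad_cat <- setdiff(unique(edges$category), EDGE_CATEGORIES)
  if (length(bad_cat))
    stop("unknown edge category(ies): ", paste(bad_cat, collapse = ", "))
  if (anyDuplicated(nodes$node))
    stop("duplicate node ids in role table")
  if (any(edges$source == edges$target))
    stop("self-edges are not allowed in a typed network")
  key <- paste(edges$source, edges$target, edges$category, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (source, target, category) edges")
  missing_ep <- setdiff(unique(c(edges$source, edges$target)), nodes$node)
  if (length(missing_ep))
    stop("edge endpoints missing from node table: ",
         paste(utils::head(missing_ep, 5), collapse = ", "))
  # deterministic storage order
  nodes <- nodes[order(nodes$node), , drop = FALSE]
  edges <- edges[order(edges$category, edges$source, edges$target), , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "typed_network")
}

#' @export
print.typed_network <- function(x, ...) {
  census <- table(factor(x$nodes$role, levels = NODE_ROLES))
  cat(sprintf("typed_network: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  cat("  roles:", paste(sprintf("%s=%d", names(census), census), collapse = " "), "\n")
  ecat <- table(factor(x$edges$category, levels = EDGE_CATEGORIES))
  cat("  edges:", paste(sprintf("%s=%d", names(ecat), ecat), collapse = " "), "\n")
  invisible(x)
}

#' Number of nodes / edges of a typed network
#' @param network a `typed_network`
#' @return integer count
#' @export
n_nodes <- function(network) nrow(network$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(network) nrow(network$edges)

node_roles <- function(network) {
  stats::setNames(network$nodes$role, network$nodes$node)
}

# Undirected simple projection (any category, any direction) as an igraph
# object; used for topology statistics and triad enumeration support.
as_undirected_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(
    network$edges[, c("source", "target")],
    directed = FALSE,
    vertices = network$nodes$node
  )
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

# Induced typed sub-network on a node set.
induce_subnetwork <- function(network, nodes) {
  nodes <- intersect(network$nodes$node, nodes)
  keep <- network$edges$source %in% nodes & network$edges$target %in% nodes
  typed_network(
    nodes = network$nodes[network$nodes$node %in% nodes, , drop = FALSE],
    edges = network$edges[keep, , drop = FALSE]
  )
}
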