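# Weighted PPI filtering, hub identification and MCODE-style module
# detection. The clustering follows the three-phase MCODE algorithm of
# Bader & Hogue (2003): local k-core based vertex weighting, greedy seeded
# complex expansion, and post-processing (k-core filter + haircut), with the
# cluster score defined as size x density = 2E/(N-1).

#' MCODE configuration
#'
#' Defaults match the Cytoscape MCODE plugin run with
#' score >= 5, node score cutoff 0.2, max depth 100, degree cutoff 2 and
#' k-core 3 (haircut on, fluff off).
#'
#' @param min_cluster_score minimum cluster score to keep a cluster.
#' @param node_score_cutoff fraction of the seed weight a neighbour may fall
#'   short of and still join the growing cluster (in [0, 1]).
#' @param max_depth maximum expansion depth from the seed vertex.
#' @param degree_cutoff vertices below this degree get weight 0.
#' @param k_core clusters that do not contain a k-core of this order are
#'   discarded.
#' @param haircut remove singly-connected vertices from final clusters.
#' @param fluff not implemented beyond the off default (kept for interface
#'   completeness).
#' @return list of class `mcode_config`.
#' @export
mcode_config <- function(min_cluster_score = 5, node_score_cutoff = 0.2,
                         max_depth = 100, degree_cutoff = 2, k_core = 3,
                         haircut = TRUE, fluff = FALSE) {
  stopifnot(node_score_cutoff >= 0, node_score_cutoff <= 1, k_core >= 2,
            max_depth >= 1, degree_cutoff >= 0)
  if (fluff) stop("fluff post-processing is not implemented", call. = FALSE)
  structure(list(min_cluster_score = min_cluster_score,
                 node_score_cutoff = node_score_cutoff,
                 max_depth = max_depth, degree_cutoff = degree_cutoff,
                 k_core = k_core, haircut = haircut, fluff = fluff),
            class = "mcode_config")
}

#' PPI analysis configuration
#'
#' @param min_combined_score keep interactions with combined score strictly
#'   greater than this (default 0.9).
#' @param hub_min_degree hub genes have degree strictly greater than this
#'   (default 30).
#' @param mcode an [mcode_config()].
#' @return list of class `ppi_config`.
#' @export
ppi_config <- function(min_combined_score = 0.9, hub_min_degree = 30,
                       mcode = mcode_config()) {
  stopifnot(min_combined_score >= 0, min_combined_score <= 1,
            hub_min_degree >= 0)
  structure(list(min_combined_score = min_combined_score,
                 hub_min_degree = hub_min_degree, mcode = mcode),
            class = "ppi_config")
}

#' Filter a weighted PPI edge list into a graph
#'
#' Keeps edges with combined score strictly greater than the threshold and
#' returns the undirected simple graph on the surviving edges (isolated
#' nodes are dropped).
#'
#' @param edges data.frame as returned by [read_ppi_table()].
#' @param min_combined_score strict lower bound on the combined score.
#' @return an undirected `igraph` graph.
#' @export
filter_ppi <- function(edges, min_combined_score = 0.9) {
  stopifnot(is.data.frame(edges),
            all(c("protein_a", "protein_b", "combined_score") %in% names(edges)))
  keep <- edges$combined_score > min_combined_score
  e <- edges[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    e[, c("protein_a", "protein_b")], directed = FALSE)
  igraph::E(g)$combined_score <- e$combined_score
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = "max")
}

#' Hub genes by connectivity degree
#'
#' Nodes with degree strictly greater than `min_degree`, sorted by degree
#' descending with ties broken lexicographically by node id.
#'
#' @param graph an undirected `igraph` graph.
#' @param min_degree strict degree threshold (default 30).
#' @return character vector of hub node ids.
#' @export
hub_genes <- function(graph, min_degree = 30) {
  deg <- igraph::degree(graph)
  hubs <- deg[deg > min_degree]
  if (!length(hubs)) return(character())
  names(hubs)[order(-hubs, names(hubs))]
}

#' MCODE cluster score
#'
#' Score of a cluster with `n_nodes` nodes and `n_edges` edges:
#' n_nodes x density, with density = 2 * n_edges / (n_nodes * (n_nodes - 1)),
#' which simplifies to 2 * n_edges / (n_nodes - 1).
#'
#' @param n_nodes number of nodes (>= 2).
#' @param n_edges number of edges (0 <= n_edges <= choose(n_nodes, 2)).
#' @return numeric score.
#' @export
cluster_score <- function(n_nodes, n_edges) {
  if (n_nodes < 2) stop("cluster score needs at least 2 nodes", call. = FALSE)
  if (n_edges < 0 || n_edges > choose(n_nodes, 2))
    stop("n_edges outside [0, choose(n_nodes, 2)]", call. = FALSE)
  2 * n_edges / (n_nodes - 1)
}

graph_density2 <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

# MCODE phase 1: vertex weighting. The weight of v is k * density of the
# highest k-core of the immediate neighbourhood graph of v (v included);
# vertices with degree below degree_cutoff get weight 0.
mcode_vertex_weights <- function(graph, config) {
  n <- igraph::vcount(graph)
  w <- numeric(n)
  deg <- igraph::degree(graph)
  for (i in seq_len(n)) {
    if (deg[i] < config$degree_cutoff) next
    nb <- igraph::neighbors(graph, i)
    sub <- igraph::induced_subgraph(graph, c(i, as.integer(nb)))
    core <- igraph::coreness(sub)
    kmax <- max(core)
    if (kmax < 1) next
    top <- igraph::induced_subgraph(sub, which(core >= kmax))
    w[i] <- kmax * graph_density2(top)
  }
  stats::setNames(w, igraph::V(graph)$name)
}

# MCODE phase 2: greedy expansion from the highest-weight unused seed.
# Breadth-first from the seed; a neighbour joins when its weight is at least
# (1 - node_score_cutoff) * seed weight; every visited vertex is consumed.
mcode_expand <- function(graph, weights, config) {
  nm <- igraph::V(graph)$name
  order_idx <- order(-weights, nm)
  used <- logical(length(nm))
  adj <- igraph::adjacent_vertices(graph, igraph::V(graph))
  clusters <- list()
  for (seed in order_idx) {
    if (used[seed]) next
    threshold <- weights[seed] * (1 - config$node_score_cutoff)
    members <- seed
    used[seed] <- TRUE
    frontier <- seed
    depth <- 0L
    while (length(frontier) && depth < config$max_depth) {
      nxt <- integer()
      for (v in frontier) {
        for (u in as.integer(adj[[v]])) {
          if (!used[u] && weights[u] >= threshold) {
            used[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    if (length(members) > 1L) clusters[[length(clusters) + 1L]] <- members
  }
  clusters
}

#' Detect dense modules MCODE-style
#'
#' Three-phase MCODE: (1) vertex weighting by the highest k-core of each
#' vertex's immediate neighbourhood, (2) greedy seeded expansion admitting
#' neighbours whose weight is within `node_score_cutoff` of the seed weight
#' (each vertex belongs to at most one cluster), (3) post-processing:
#' clusters that do not contain a `k_core`-core are discarded and, with
#' haircut, singly-connected vertices are trimmed. Clusters scoring below
#' `min_cluster_score` are dropped. The procedure is deterministic; ties in
#' seed order are broken by node id.
#'
#' @param graph an undirected simple `igraph` graph (e.g. [filter_ppi()]).
#' @param config an [mcode_config()].
#' @return data.frame with one row per cluster, columns `cluster`,
#'   `n_nodes`, `n_edges`, `score` and a list-column `members`, sorted by
#'   score descending.
#' @export
mcode_clusters <- function(graph, config = mcode_config()) {
  stopifnot(inherits(config, "mcode_config"))
  empty <- data.frame(cluster = integer(), n_nodes = integer(),
                      n_edges = integer(), score = numeric())
  empty$members <- list()
  if (igraph::vcount(graph) == 0) return(empty)

  weights <- mcode_vertex_weights(graph, config)
  raw <- mcode_expand(graph, weights, config)

  out <- list()
  for (members in raw) {
    sub <- igraph::induced_subgraph(graph, members)
    if (max(igraph::coreness(sub)) < config$k_core) next
    if (config$haircut) {
      repeat {
        d <- igraph::degree(sub)
        drop <- which(d < 2)
        if (!length(drop) || igraph::vcount(sub) - length(drop) < 2) break
        sub <- igraph::delete_vertices(sub, drop)
      }
    }
    nn <- igraph::vcount(sub)
    ne <- igraph::ecount(sub)
    if (nn < 2) next
    sc <- cluster_score(nn, ne)
    if (sc < config$min_cluster_score) next
    out[[length(out) + 1L]] <- list(members = sort(igraph::V(sub)$name),
                                    n_nodes = as.integer(nn),
                                    n_edges = as.integer(ne), score = sc)
  }
  if (!length(out)) return(empty)
  df <- data.frame(
    cluster = seq_along(out),
    n_nodes = vapply(out, `[[`, integer(1), "n_nodes"),
    n_edges = vapply(out, `[[`, integer(1), "n_edges"),
    score = vapply(out, `[[`, numeric(1), "score")
  )
  ord <- order(-df$score, df$n_nodes)
  df <- df[ord, , drop = FALSE]
  df$members <- lapply(out, `[[`, "members")[ord]
  df$cluster <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}
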