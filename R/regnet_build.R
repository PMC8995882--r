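# Assembly of the TF-miRNA-gene network from the four pair categories,
# plus its topology profile and the log-log power-law degree fit.

# role each side of a category must be able to play
category_role_constraints <- function(category) {
  switch(category,
    TF_MIRNA   = list(source = "TF", target = "MIRNA"),
    TF_GENE    = list(source = "TF", target = "GENE"),
    MIRNA_GENE = list(source = "MIRNA", target = "GENE"),
    MIRNA_TF   = list(source = "MIRNA", target = "TF"),
    stop("unknown edge category: ", category)
  )
}

role_is_compatible <- function(role, needed) {
  role == needed | (role == "TF_AND_GENE" & needed %in% c("TF", "GENE"))
}

#' Build the typed TF-miRNA-gene network from pair tables
#'
#' Merges the four regulatory pair categories into one typed directed
#' network. Node roles are assigned from the universes: a node present in
#' both the TF and gene universes becomes `TF_AND_GENE`. Duplicate
#' (source, target, category) pairs are collapsed; the same (source, target)
#' appearing under two different categories is kept as two edges and the
#' cross-category multiplicity is reported via `message()`. Nodes with no
#' edges are omitted.
#'
#' @param pairs data.frame of regulatory pairs (columns `source`, `target`,
#'   `category`, `mode`), e.g. `rbind()` of [read_pair_table()] outputs.
#' @param tf_universe,gene_universe,mirna_universe character vectors of
#'   identifiers defining each role universe (normalised internally with the
#'   same rules as the readers).
#' @return a `typed_network`.
#' @export
build_network <- function(pairs, tf_universe, gene_universe, mirna_universe) {
  stopifnot(is.data.frame(pairs),
            all(c("source", "target", "category") %in% names(pairs)))
  if (!"mode" %in% names(pairs)) pairs$mode <- "unspecified"
  tf_universe <- unique(normalize_gene_id(tf_universe))
  gene_universe <- unique(normalize_gene_id(gene_universe))
  mirna_universe <- unique(normalize_mirna_id(mirna_universe))

  role_of <- function(ids) {
    out <- rep(NA_character_, length(ids))
    dual <- ids %in% tf_universe & ids %in% gene_universe
    out[dual] <- "TF_AND_GENE"
    out[!dual & ids %in% tf_universe] <- "TF"
    out[!dual & ids %in% gene_universe] <- "GENE"
    out[is.na(out) & ids %in% mirna_universe] <- "MIRNA"
    out
  }

  # drop self-pairs defensively, collapse within-category duplicates
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  key <- paste(pairs$source, pairs$target, pairs$category, sep = "\r")
  pairs <- pairs[!duplicated(key), , drop = FALSE]

  all_nodes <- unique(c(pairs$source, pairs$target))
  roles <- role_of(all_nodes)
  if (anyNA(roles)) {
    offenders <- all_nodes[is.na(roles)]
    stop("network endpoints found in no universe: ",
         paste(utils::head(offenders, 10), collapse = ", "), call. = FALSE)
  }
  names(roles) <- all_nodes

  # endpoint-role / category compatibility
  for (cat in unique(pairs$category)) {
    cons <- category_role_constraints(cat)
    sel <- pairs$category == cat
    bad_s <- !role_is_compatible(roles[pairs$source[sel]], cons$source)
    bad_t <- !role_is_compatible(roles[pairs$target[sel]], cons$target)
    if (any(bad_s) || any(bad_t)) {
      offenders <- unique(c(pairs$source[sel][bad_s], pairs$target[sel][bad_t]))
      stop(sprintf("endpoint role incompatible with category %s: %s", cat,
                   paste(utils::head(offenders, 10), collapse = ", ")),
           call. = FALSE)
    }
  }

  xkey <- paste(pairs$source, pairs$target, sep = "\r")
  n_cross <- sum(duplicated(xkey))
  if (n_cross > 0)
    message(sprintf(
      "%d (source, target) pair(s) occur under more than one category; kept as separate edges",
      n_cross))

  typed_network(
    nodes = data.frame(node = all_nodes, role = unname(roles[all_nodes]),
                       stringsAsFactors = FALSE),
    edges = pairs[, c("source", "target", "category", "mode")]
  )
}

#' Role census of a typed network
#'
#' Counts nodes per role; the per-role counts always sum to the total.
#'
#' @param network a `typed_network`.
#' @return named list with one count per role plus `total`.
#' @export
node_census <- function(network) {
  stopifnot(inherits(network, "typed_network"))
  tab <- table(factor(network$nodes$role, levels = NODE_ROLES))
  out <- as.list(as.integer(tab))
  names(out) <- NODE_ROLES
  out$total <- nrow(network$nodes)
  out
}

#' Per-node topology profile
#'
#' Computes, on the undirected simple projection of the network, the four
#' node statistics commonly reported for regulatory networks: degree, local
#' clustering coefficient, topological coefficient and neighbourhood
#' connectivity (mean degree of a node's neighbours). Conventions follow
#' Cytoscape's NetworkAnalyzer: nodes with fewer than two neighbours have
#' clustering and topological coefficient 0.
#'
#' The topological coefficient of node n is the mean, over all other nodes m
#' sharing at least one neighbour with n, of (number of shared neighbours,
#' plus 1 if n and m are adjacent) divided by the degree of n.
#'
#' @param network a `typed_network`.
#' @return data.frame with columns `node`, `degree`,
#'   `clustering_coefficient`, `topological_coefficient`,
#'   `neighborhood_connectivity`.
#' @export
topology_profile <- function(network) {
  stopifnot(inherits(network, "typed_network"))
  g <- as_undirected_igraph(network)
  nodes <- igraph::V(g)$name
  deg <- igraph::degree(g)

  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[deg <= 1] <- 0

  # neighbourhood connectivity: mean degree of neighbours
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  nsum <- as.numeric(A %*% deg)
  nc <- ifelse(deg > 0, nsum / deg, 0)

  # topological coefficient via shared-neighbour counts S = A %*% A
  S <- A %*% A
  Sm <- as.matrix(S)
  Am <- as.matrix(A)
  n <- length(nodes)
  tc <- numeric(n)
  for (i in seq_len(n)) {
    if (deg[i] < 2) { tc[i] <- 0; next }
    partners <- which(Sm[i, ] > 0)
    partners <- partners[partners != i]
    if (!length(partners)) { tc[i] <- 0; next }
    tc[i] <- mean((Sm[i, partners] + (Am[i, partners] > 0)) / deg[i])
  }

  data.frame(node = nodes, degree = as.integer(deg),
             clustering_coefficient = as.numeric(cc),
             topological_coefficient = tc,
             neighborhood_connectivity = nc,
             stringsAsFactors = FALSE)
}

#' Fit a power law to a degree distribution
#'
#' Fits f(k) = a * k^b to the node-degree distribution by least squares on
#' (log10 k, log10 n(k)) over the distinct degrees k >= 1 with count
#' n(k) > 0 — the log-log regression used by Cytoscape's NetworkAnalyzer.
#'
#' @param degrees integer vector of node degrees (a multiset).
#' @return list with `a` (scale, 10^intercept), `b` (exponent, the slope)
#'   and `r_squared` of the log-log regression.
#' @export
fit_power_law <- function(degrees) {
  degrees <- degrees[degrees >= 1]
  tab <- table(degrees)
  k <- as.numeric(names(tab))
  nk <- as.numeric(tab)
  if (length(k) < 2)
    stop("need at least 2 distinct degree values >= 1 to fit a power law",
         call. = FALSE)
  fit <- stats::lm(y ~ x, data = data.frame(x = log10(k), y = log10(nk)))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((log10(nk) - mean(log10(nk)))^2)
  r2 <- if (ss_res < 1e-12) 1 else 1 - ss_res / ss_tot
  list(a = 10^unname(stats::coef(fit)[1]),
       b = unname(stats::coef(fit)[2]),
       r_squared = max(0, min(1, r2)))
}

#' First-neighbour sub-network around a centre node
#'
#' Returns the induced typed sub-network on the centre node and its first
#' neighbours (union of in- and out-neighbours across all edge categories),
#' as used to spotlight high-degree regulators such as TP53 or VEGFA.
#'
#' @param network a `typed_network`.
#' @param center node identifier.
#' @return a `typed_network`.
#' @export
ego_subnetwork <- function(network, center) {
  stopifnot(inherits(network, "typed_network"))
  if (!center %in% network$nodes$node)
    stop("node not in network: ", center, call. = FALSE)
  e <- network$edges
  nb <- unique(c(e$target[e$source == center], e$source[e$target == center]))
  induce_subnetwork(network, c(center, nb))
}
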