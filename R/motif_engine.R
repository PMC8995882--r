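# Exhaustive census of role-coloured connected 3-node subgraphs, motif
# significance against a degree-preserving edge-switching null, and
# extraction of the composite-FFL motif-specific sub-network.
#
# A triad class is identified by a canonical signature built from the roles
# the three nodes play in the instance plus the categorised adjacency
# structure, minimised over all 6 node orderings. Dual-role (TF_AND_GENE)
# nodes are canonicalised under the role they actually play in the triad:
# the edge categories incident to a node within the triad imply whether it
# acts as a TF, as a regulated gene, or (ambiguously) as both.

CATEGORY_BITS <- c(TF_MIRNA = 1L, TF_GENE = 2L, MIRNA_GENE = 4L, MIRNA_TF = 8L)
ROLE_CODES <- c(TF = 0L, MIRNA = 1L, GENE = 2L, TF_AND_GENE = 3L)

# Effective role codes given global role codes and the combined out-/in-edge
# category masks of a node within a triad. A TF_AND_GENE node acting only on
# the TF side becomes TF, only on the gene side becomes GENE, on both sides
# it keeps the ambiguous TF_AND_GENE code.
effective_role_code <- function(global_code, out_mask, in_mask) {
  tf_side <- bitwAnd(out_mask, 3L) > 0L | bitwAnd(in_mask, 8L) > 0L
  gene_side <- bitwAnd(in_mask, 6L) > 0L
  r <- global_code
  dual <- global_code == 3L
  r[dual & tf_side & !gene_side] <- 0L
  r[dual & gene_side & !tf_side] <- 2L
  r[dual & !tf_side & !gene_side] <- 0L
  r
}

# Signature code for one ordering: roles base-4, then the 6 ordered-pair
# category masks base-16. Fits exactly in a double (< 2^31).
perm_code <- function(r1, r2, r3, m12, m13, m21, m23, m31, m32) {
  (((r1 * 4 + r2) * 4 + r3) * 16^6 +
    ((((m12 * 16 + m13) * 16 + m21) * 16 + m23) * 16 + m31) * 16 + m32)
}

# Canonical code = minimum over the 6 node orderings (vectorised over
# parallel triple vectors).
canonical_code <- function(ra, rb, rc, mab, mac, mba, mbc, mca, mcb) {
  pmin(
    perm_code(ra, rb, rc, mab, mac, mba, mbc, mca, mcb),
    perm_code(ra, rc, rb, mac, mab, mca, mcb, mba, mbc),
    perm_code(rb, ra, rc, mba, mbc, mab, mac, mcb, mca),
    perm_code(rb, rc, ra, mbc, mba, mcb, mca, mab, mac),
    perm_code(rc, ra, rb, mca, mcb, mac, mab, mbc, mba),
    perm_code(rc, rb, ra, mcb, mca, mbc, mba, mac, mab)
  )
}

# Human-readable signature string from a canonical code:
# "ROLE1,ROLE2,ROLE3|xxxxxx" with the 6 pair masks as hex digits in the
# order (1,2)(1,3)(2,1)(2,3)(3,1)(3,2).
code_to_signature <- function(code) {
  masks_part <- code %% 16^6
  roles_part <- (code - masks_part) / 16^6
  r3 <- roles_part %% 4; roles_part <- (roles_part - r3) / 4
  r2 <- roles_part %% 4; r1 <- (roles_part - r2) / 4
  role_names <- names(ROLE_CODES)
  hex <- character(length(code))
  m <- masks_part
  digits <- matrix(0L, length(code), 6)
  for (j in 6:1) {
    digits[, j] <- m %% 16
    m <- (m - digits[, j]) / 16
  }
  hexchr <- c(0:9, letters[1:6])
  hex <- apply(digits, 1, function(d) paste(hexchr[d + 1], collapse = ""))
  paste0(role_names[r1 + 1], ",", role_names[r2 + 1], ",", role_names[r3 + 1],
         "|", hex)
}

# Dense matrix of per-ordered-pair category masks plus global role codes.
network_mask_matrix <- function(network) {
  nodes <- network$nodes$node
  n <- length(nodes)
  A <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  e <- network$edges
  if (nrow(e)) {
    si <- match(e$source, nodes)
    ti <- match(e$target, nodes)
    bits <- CATEGORY_BITS[e$category]
    for (k in seq_len(nrow(e)))
      A[si[k], ti[k]] <- bitwOr(A[si[k], ti[k]], bits[[k]])
  }
  list(A = A, roles = ROLE_CODES[network$nodes$role], nodes = nodes)
}

# All connected (unordered) node triples as an m x 3 index matrix.
connected_triples <- function(network) {
  nodes <- network$nodes$node
  n <- length(nodes)
  if (n < 3 || nrow(network$edges) == 0) return(matrix(integer(), 0, 3))
  g <- as_undirected_igraph(network)
  perm <- match(igraph::V(g)$name, nodes)
  el <- igraph::as_edgelist(g, names = FALSE)
  el <- matrix(perm[el], ncol = 2)
  adj <- lapply(seq_len(n), function(i) integer())
  for (k in seq_len(nrow(el))) {
    u <- el[k, 1]; v <- el[k, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  us <- integer(); vs <- integer(); ws <- integer()
  for (k in seq_len(nrow(el))) {
    u <- min(el[k, ]); v <- max(el[k, ])
    cand <- setdiff(unique(c(adj[[u]], adj[[v]])), c(u, v))
    if (length(cand)) {
      us <- c(us, rep.int(u, length(cand)))
      vs <- c(vs, rep.int(v, length(cand)))
      ws <- c(ws, cand)
    }
  }
  if (!length(us)) return(matrix(integer(), 0, 3))
  x1 <- pmin(us, vs, ws)
  x3 <- pmax(us, vs, ws)
  x2 <- us + vs + ws - x1 - x3
  key <- (as.numeric(x1) * n + x2) * n + x3
  keep <- !duplicated(key)
  cbind(x1[keep], x2[keep], x3[keep])
}

# Core census: canonical code per connected triple.
triple_codes <- function(network) {
  mm <- network_mask_matrix(network)
  trip <- connected_triples(network)
  if (nrow(trip) == 0)
    return(list(triples = trip, codes = numeric(), mm = mm))
  a <- trip[, 1]; b <- trip[, 2]; c <- trip[, 3]
  A <- mm$A
  mab <- A[cbind(a, b)]; mac <- A[cbind(a, c)]
  mba <- A[cbind(b, a)]; mbc <- A[cbind(b, c)]
  mca <- A[cbind(c, a)]; mcb <- A[cbind(c, b)]
  gr <- mm$roles
  ra <- effective_role_code(gr[a], bitwOr(mab, mac), bitwOr(mba, mca))
  rb <- effective_role_code(gr[b], bitwOr(mba, mbc), bitwOr(mab, mcb))
  rc <- effective_role_code(gr[c], bitwOr(mca, mcb), bitwOr(mac, mbc))
  codes <- canonical_code(ra, rb, rc, mab, mac, mba, mbc, mca, mcb)
  list(triples = trip, codes = codes, mm = mm)
}

instance_from_triple <- function(network, node_ids) {
  keep <- network$edges$source %in% node_ids & network$edges$target %in% node_ids
  roles <- node_roles(network)[node_ids]
  structure(list(nodes = node_ids, roles = roles,
                 edges = network$edges[keep, , drop = FALSE]),
            class = "motif_instance")
}

#' Census all connected role-coloured triads
#'
#' Exhaustively enumerates every unordered node triple whose induced
#' subgraph is weakly connected, assigns each to its canonical motif class
#' and collects the instances per class.
#'
#' @param network a `typed_network`.
#' @return object of class `triad_census`: list with `counts` (named count
#'   vector, names are canonical class signatures), `instances` (named list
#'   of `motif_instance` lists) and `network`.
#' @export
enumerate_triads <- function(network) {
  stopifnot(inherits(network, "typed_network"))
  tc <- triple_codes(network)
  if (!length(tc$codes)) {
    return(structure(list(counts = stats::setNames(numeric(), character()),
                          instances = list(), network = network),
                     class = "triad_census"))
  }
  sig <- code_to_signature(tc$codes)
  counts <- table(sig)
  nodes <- network$nodes$node
  inst <- split(seq_along(sig), sig)
  instances <- lapply(inst, function(rows) {
    lapply(rows, function(r) {
      instance_from_triple(network, nodes[tc$triples[r, ]])
    })
  })
  structure(list(counts = stats::setNames(as.numeric(counts), names(counts)),
                 instances = instances, network = network),
            class = "triad_census")
}

# Counts only — used on the randomised networks where instances are not
# needed.
triad_counts <- function(network) {
  tc <- triple_codes(network)
  if (!length(tc$codes)) return(stats::setNames(numeric(), character()))
  counts <- table(tc$codes)
  stats::setNames(as.numeric(counts), code_to_signature(as.numeric(names(counts))))
}

#' Canonical motif class of a role-coloured triad
#'
#' Computes the canonical signature of a 3-node role-coloured subgraph:
#' the minimum over all 6 node orderings of the (role triple, categorised
#' adjacency) encoding. TF_AND_GENE nodes canonicalise under the role they
#' play within the instance.
#'
#' @param roles named character vector (node -> role) of length 3.
#' @param edges data.frame with columns `source`, `target`, `category`
#'   among the three nodes.
#' @return signature string.
#' @export
canonical_class <- function(roles, edges) {
  stopifnot(length(roles) == 3, !is.null(names(roles)))
  net <- typed_network(
    nodes = data.frame(node = names(roles), role = unname(roles),
                       stringsAsFactors = FALSE),
    edges = edges
  )
  und <- as_undirected_igraph(net)
  if (igraph::ecount(und) < 2)
    stop("triad is not connected", call. = FALSE)
  tc <- triple_codes(net)
  if (nrow(tc$triples) != 1)
    stop("triad is not connected", call. = FALSE)
  code_to_signature(tc$codes)
}

#' Test whether a motif instance is a composite feed-forward loop
#'
#' A composite FFL contains exactly one TF(-capable) node, one miRNA and
#' one common target gene(-capable) node, with all four regulation
#' categories present among them: TF->miRNA, miRNA->TF, TF->gene and
#' miRNA->gene. A TF_AND_GENE node may serve as the TF or as the target
#' gene of an instance, but not both at once.
#'
#' @param instance a `motif_instance` (see [enumerate_triads()]).
#' @return logical.
#' @export
is_composite_ffl <- function(instance) {
  nrow(composite_ffl_assignments(instance)) > 0
}

# All valid (tf, mirna, gene) assignments of an instance's nodes.
composite_ffl_assignments <- function(instance) {
  nodes <- instance$nodes
  roles <- instance$roles
  e <- instance$edges
  has_edge <- function(s, t, cat)
    any(e$source == s & e$target == t & e$category == cat)
  out <- list()
  for (m in nodes[roles == "MIRNA"]) {
    rest <- setdiff(nodes, m)
    for (tf in rest) {
      g <- setdiff(rest, tf)
      if (!roles[tf] %in% c("TF", "TF_AND_GENE")) next
      if (!roles[g] %in% c("GENE", "TF_AND_GENE")) next
      if (has_edge(tf, m, "TF_MIRNA") && has_edge(m, tf, "MIRNA_TF") &&
          has_edge(tf, g, "TF_GENE") && has_edge(m, g, "MIRNA_GENE"))
        out[[length(out) + 1L]] <- c(tf = tf, mirna = m, gene = g)
    }
  }
  if (!length(out))
    return(data.frame(tf = character(), mirna = character(),
                      gene = character(), stringsAsFactors = FALSE))
  df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  names(df) <- c("tf", "mirna", "gene")
  df
}

#' Motif analysis configuration
#'
#' @param z_min minimum Z-score for significance (default 2.0).
#' @param p_max maximum empirical p-value for significance (default 0.05).
#' @param n_random number of randomised networks for the null (default 1000).
#' @param swaps_per_edge attempted double-edge swaps per edge (default 3).
#' @param seed integer seed driving the randomisation.
#' @return list of class `motif_config`.
#' @export
motif_config <- function(z_min = 2.0, p_max = 0.05, n_random = 1000,
                         swaps_per_edge = 3, seed = 1L) {
  stopifnot(n_random >= 1, p_max > 0, p_max < 1, swaps_per_edge >= 1)
  structure(list(z_min = z_min, p_max = p_max, n_random = n_random,
                 swaps_per_edge = swaps_per_edge, seed = as.integer(seed)),
            class = "motif_config")
}

#' Degree-preserving randomization of a typed network
#'
#' Applies repeated double-edge swaps within each edge category
#' (swap a->b, c->d into a->d, c->b), which preserves every node's
#' per-category in- and out-degree and all role assignments. Swaps that
#' would create a self-loop or duplicate an existing edge of the same
#' category are rejected. The number of attempted swaps per category is
#' `swaps_per_edge` times the category's edge count.
#'
#' @param network a `typed_network`.
#' @param seed integer seed.
#' @param swaps_per_edge attempted swaps per edge (default 3).
#' @return a randomised `typed_network` with identical nodes and roles.
#' @export
randomize_network <- function(network, seed, swaps_per_edge = 3) {
  stopifnot(inherits(network, "typed_network"))
  set.seed(as.integer(seed))
  nodes <- network$nodes$node
  n <- length(nodes)
  out_edges <- list()
  for (cat in EDGE_CATEGORIES) {
    e <- network$edges[network$edges$category == cat, , drop = FALSE]
    ne <- nrow(e)
    if (ne == 0) next
    if (ne >= 2) {
      s <- match(e$source, nodes)
      t <- match(e$target, nodes)
      keyset <- new.env(hash = TRUE, parent = emptyenv())
      ekey <- function(a, b) sprintf("%d_%d", a, b)
      for (k in seq_len(ne)) assign(ekey(s[k], t[k]), TRUE, envir = keyset)
      attempts <- swaps_per_edge * ne
      ij <- matrix(sample.int(ne, 2 * attempts, replace = TRUE), ncol = 2)
      for (row in seq_len(attempts)) {
        i <- ij[row, 1]; j <- ij[row, 2]
        if (i == j) next
        a <- s[i]; b <- t[i]; c2 <- s[j]; d <- t[j]
        if (a == d || c2 == b) next
        if (exists(ekey(a, d), envir = keyset, inherits = FALSE)) next
        if (exists(ekey(c2, b), envir = keyset, inherits = FALSE)) next
        rm(list = c(ekey(a, b), ekey(c2, d)), envir = keyset)
        assign(ekey(a, d), TRUE, envir = keyset)
        assign(ekey(c2, b), TRUE, envir = keyset)
        t[i] <- d; t[j] <- b
      }
      e$source <- nodes[s]
      e$target <- nodes[t]
    }
    out_edges[[cat]] <- e
  }
  edges <- if (length(out_edges)) do.call(rbind, out_edges) else NULL
  typed_network(network$nodes, edges)
}

#' Motif Z-scores and empirical p-values against the switching null
#'
#' Runs the triad census on the real network and on `n_random`
#' independently randomised copies (degree-preserving within-category edge
#' switching), then scores every class observed in the real network:
#' Z = (real count - null mean) / null SD, and the add-one empirical
#' p-value p = (#\{null count >= real count\} + 1) / (n_random + 1).
#' Classes whose null SD is zero are flagged (`sd_zero`) and excluded from
#' significance rather than given an arbitrary Z.
#'
#' @param network a `typed_network`.
#' @param config a [motif_config()].
#' @param census optional pre-computed [enumerate_triads()] result for
#'   `network` (recomputed when omitted).
#' @return data.frame with one row per observed class: `signature`,
#'   `count_real`, `null_mean`, `null_sd`, `z_score`, `p_value`,
#'   `n_random`, `sd_zero`, `is_composite_ffl`, `significant`.
#' @export
motif_zscores <- function(network, config = motif_config(), census = NULL) {
  stopifnot(inherits(config, "motif_config"))
  if (is.null(census)) census <- enumerate_triads(network)
  sigs <- names(census$counts)
  nclass <- length(sigs)
  nullmat <- matrix(0, nrow = nclass, ncol = config$n_random,
                    dimnames = list(sigs, NULL))
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, config$n_random)
  for (r in seq_len(config$n_random)) {
    rnet <- randomize_network(network, seeds[r], config$swaps_per_edge)
    rc <- triad_counts(rnet)
    common <- intersect(names(rc), sigs)
    if (length(common)) nullmat[common, r] <- rc[common]
  }
  null_mean <- rowMeans(nullmat)
  null_sd <- apply(nullmat, 1, stats::sd)
  count_real <- as.numeric(census$counts)
  sd_zero <- null_sd == 0
  z <- ifelse(sd_zero, NA_real_, (count_real - null_mean) / null_sd)
  p <- (rowSums(nullmat >= count_real) + 1) / (config$n_random + 1)
  is_comp <- vapply(sigs, function(s) is_composite_ffl(census$instances[[s]][[1]]),
                    logical(1))
  df <- data.frame(signature = sigs, count_real = count_real,
                   null_mean = null_mean, null_sd = null_sd,
                   z_score = z, p_value = p, n_random = config$n_random,
                   sd_zero = sd_zero, is_composite_ffl = unname(is_comp),
                   stringsAsFactors = FALSE)
  df$significant <- !df$sd_zero & !is.na(df$z_score) &
    df$z_score > config$z_min & df$p_value < config$p_max
  df <- df[order(-df$count_real, df$signature), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Select significant composite-FFL classes and merge their instances
#'
#' Keeps the classes that pass the Z-score and p-value thresholds and whose
#' instances are composite FFLs, merges all their instances into the
#' motif-specific sub-network (union of instance nodes and edges), and
#' lists the explicit (TF, miRNA, gene) triples. When no class passes, an
#' empty network is returned with a warning.
#'
#' @param stats result of [motif_zscores()].
#' @param census the matching [enumerate_triads()] result.
#' @param config a [motif_config()].
#' @return list with `classes` (selected rows of `stats`), `network` (the
#'   merged `typed_network`) and `triples` (data.frame tf / mirna / gene).
#' @export
select_and_merge <- function(stats, census, config = motif_config()) {
  sel <- stats$significant & stats$is_composite_ffl
  empty_triples <- data.frame(tf = character(), mirna = character(),
                              gene = character(), stringsAsFactors = FALSE)
  if (!any(sel)) {
    warning("no significant composite-FFL class; returning empty sub-network",
            call. = FALSE)
    return(list(classes = stats[sel, , drop = FALSE],
                network = typed_network(
                  data.frame(node = character(), role = character()), NULL),
                triples = empty_triples))
  }
  keep_nodes <- character()
  keep_edge_keys <- character()
  triples <- list()
  parent <- census$network
  for (sig in stats$signature[sel]) {
    for (inst in census$instances[[sig]]) {
      keep_nodes <- union(keep_nodes, inst$nodes)
      keep_edge_keys <- union(keep_edge_keys,
                              paste(inst$edges$source, inst$edges$target,
                                    inst$edges$category, sep = "\r"))
      triples[[length(triples) + 1L]] <- composite_ffl_assignments(inst)
    }
  }
  ekey <- paste(parent$edges$source, parent$edges$target,
                parent$edges$category, sep = "\r")
  merged <- typed_network(
    nodes = parent$nodes[parent$nodes$node %in% keep_nodes, , drop = FALSE],
    edges = parent$edges[ekey %in% keep_edge_keys, , drop = FALSE]
  )
  tri <- do.call(rbind, triples)
  tri <- tri[!duplicated(paste(tri$tf, tri$mirna, tri$gene, sep = "\r")), ,
             drop = FALSE]
  tri <- tri[order(tri$tf, tri$mirna, tri$gene), , drop = FALSE]
  rownames(tri) <- NULL
  list(classes = stats[sel, , drop = FALSE], network = merged, triples = tri)
}
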