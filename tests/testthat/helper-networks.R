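# Shared fixtures: random typed networks and independent naive oracles.
# The oracles deliberately use a different mechanism from the package code
# (explicit bijection testing, per-definition loops, exhaustive draw
# enumeration) so they can stand as independent checks.

# The single composite-FFL network used throughout.
composite_ffl_network <- function() {
  edges <- data.frame(
    source = c("TF1", "hsa-mir-1", "TF1", "hsa-mir-1"),
    target = c("hsa-mir-1", "TF1", "G1", "G1"),
    category = c("TF_MIRNA", "MIRNA_TF", "TF_GENE", "MIRNA_GENE"),
    stringsAsFactors = FALSE)
  build_network(edges, "TF1", "G1", "hsa-mir-1")
}

# Random typed network with role-compatible random edges (including some
# dual-role nodes), for property sweeps.
random_typed_network <- function(n_nodes = 10, edges_per_category = 6,
                                 p_dual = 0.15) {
  n_tf <- max(1, rbinom(1, n_nodes, 0.3))
  n_mirna <- max(1, rbinom(1, n_nodes - n_tf, 0.5))
  n_gene <- max(1, n_nodes - n_tf - n_mirna)
  tf <- sprintf("T%02d", seq_len(n_tf))
  mirna <- sprintf("hsa-mir-%02d", seq_len(n_mirna))
  gene <- sprintf("G%02d", seq_len(n_gene))
  n_dual <- rbinom(1, min(n_tf, 3), p_dual)
  if (n_dual > 0) {
    dual <- sprintf("D%02d", seq_len(n_dual))
    tf <- c(tf, dual)
    gene <- c(gene, dual)
  }
  ends <- list(TF_MIRNA = list(tf, mirna), TF_GENE = list(tf, gene),
               MIRNA_GENE = list(mirna, gene), MIRNA_TF = list(mirna, tf))
  rows <- list()
  for (cat in names(ends)) {
    s <- sample(ends[[cat]][[1]], edges_per_category, replace = TRUE)
    t <- sample(ends[[cat]][[2]], edges_per_category, replace = TRUE)
    keep <- s != t
    if (any(keep))
      rows[[cat]] <- data.frame(source = s[keep], target = t[keep],
                                category = cat, stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  pairs <- pairs[!duplicated(paste(pairs$source, pairs$target, pairs$category)), ]
  build_network(pairs, tf, gene, mirna)
}

# ---- naive triad oracle -------------------------------------------------

# Effective role of each node of a triad, computed per definition from the
# categories of its incident edges.
naive_effective_roles <- function(nodes, roles, edges) {
  out <- character(3)
  for (i in 1:3) {
    v <- nodes[i]
    outc <- edges$category[edges$source == v]
    inc <- edges$category[edges$target == v]
    tf_side <- any(outc %in% c("TF_MIRNA", "TF_GENE")) |
      any(inc == "MIRNA_TF")
    gene_side <- any(inc %in% c("TF_GENE", "MIRNA_GENE"))
    if (roles[v] != "TF_AND_GENE") out[i] <- roles[v]
    else if (tf_side && gene_side) out[i] <- "TF_AND_GENE"
    else if (gene_side) out[i] <- "GENE"
    else out[i] <- "TF"
  }
  out
}

# TRUE when two triads (effective roles r, edge endpoint vectors s/t on
# local ids 1..3, category vector cat) are isomorphic, by trying all 6
# bijections explicitly.
naive_triads_isomorphic <- function(r1, s1, t1, cat1, r2, s2, t2, cat2) {
  if (length(s1) != length(s2)) return(FALSE)
  key1 <- sort(paste(s1, t1, cat1))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  for (p in perms) {
    if (!all(r1 == r2[p])) next
    if (identical(key1, sort(paste(match(s2, p), match(t2, p), cat2))))
      return(TRUE)
  }
  FALSE
}

# Brute-force census: every node triple, connectivity by scan, classes by
# linear comparison against representatives. Returns the triple keys
# (sorted node ids pasted) and a class id per connected triple.
naive_triad_census <- function(net) {
  nodes <- net$nodes$node
  roles <- setNames(net$nodes$role, nodes)
  e <- net$edges
  n <- length(nodes)
  reps <- list()
  class_id <- integer()
  keys <- character()
  if (n < 3 || nrow(e) == 0) return(list(keys = keys, class_id = class_id))
  for (combo in utils::combn(n, 3, simplify = FALSE)) {
    trio <- sort(nodes[combo])
    sel <- e$source %in% trio & e$target %in% trio
    if (!any(sel)) next
    s <- match(e$source[sel], trio)
    t <- match(e$target[sel], trio)
    cat <- e$category[sel]
    und <- unique(paste(pmin(s, t), pmax(s, t)))
    if (length(und) < 2) next  # not connected
    eff <- naive_effective_roles(trio, roles, e[sel, , drop = FALSE])
    found <- 0L
    for (k in seq_along(reps)) {
      rp <- reps[[k]]
      if (naive_triads_isomorphic(rp$r, rp$s, rp$t, rp$cat, eff, s, t, cat)) {
        found <- k; break
      }
    }
    if (!found) {
      reps[[length(reps) + 1L]] <- list(r = eff, s = s, t = t, cat = cat)
      found <- length(reps)
    }
    keys <- c(keys, paste(trio, collapse = "|"))
    class_id <- c(class_id, found)
  }
  list(keys = keys, class_id = class_id)
}

# triple-key -> signature map from a package census (for partition
# comparison against the naive census)
census_triple_signatures <- function(census) {
  out <- character(); keys <- character()
  for (sig in names(census$instances)) {
    for (inst in census$instances[[sig]]) {
      keys <- c(keys, paste(sort(inst$nodes), collapse = "|"))
      out <- c(out, sig)
    }
  }
  setNames(out, keys)
}

# ---- naive topology oracle ----------------------------------------------

naive_topology <- function(net) {
  nodes <- net$nodes$node
  n <- length(nodes)
  A <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(net$edges))) {
    i <- match(net$edges$source[r], nodes)
    j <- match(net$edges$target[r], nodes)
    A[i, j] <- 1L; A[j, i] <- 1L
  }
  deg <- rowSums(A)
  cc <- tc <- nc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1L)
    k <- length(nb)
    nc[i] <- if (k > 0) mean(deg[nb]) else 0
    if (k < 2) { cc[i] <- 0 } else {
      links <- 0
      for (a in nb) for (b in nb) if (a < b && A[a, b] == 1L) links <- links + 1
      cc[i] <- 2 * links / (k * (k - 1))
    }
    if (k < 2) { tc[i] <- 0 } else {
      vals <- c()
      for (m in seq_len(n)) {
        if (m == i) next
        shared <- sum(A[i, ] == 1L & A[m, ] == 1L)
        if (shared > 0) vals <- c(vals, (shared + (A[i, m] == 1L)) / k)
      }
      tc[i] <- if (length(vals)) mean(vals) else 0
    }
  }
  data.frame(node = nodes, degree = as.integer(deg),
             clustering_coefficient = cc, topological_coefficient = tc,
             neighborhood_connectivity = nc, stringsAsFactors = FALSE)
}

# ---- exhaustive hypergeometric oracle -----------------------------------

# P(overlap <= x) by enumerating every size-N draw from universe 1..M with
# marked subset 1..K.
enum_hyper_cdf <- function(x, M, K, N) {
  if (N == 0) return(1)
  draws <- utils::combn(M, N, simplify = FALSE)
  overlaps <- vapply(draws, function(d) sum(d <= K), numeric(1))
  mean(overlaps <= x)
}

# per-node, per-category in/out degree table (for randomization invariants)
per_category_degrees <- function(net) {
  out <- list()
  for (cat in EDGE_CATEGORIES) {
    e <- net$edges[net$edges$category == cat, , drop = FALSE]
    out[[cat]] <- list(
      outdeg = table(factor(e$source, levels = net$nodes$node)),
      indeg = table(factor(e$target, levels = net$nodes$node)))
  }
  out
}
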