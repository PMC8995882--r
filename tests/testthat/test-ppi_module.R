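test_that("combined-score filtering is strict and drops isolated nodes", {
  edges <- data.frame(protein_a = c("A", "C", "E"),
                      protein_b = c("B", "D", "F"),
                      combined_score = c(0.95, 0.85, 0.9))
  g <- filter_ppi(edges, 0.9)
  expect_equal(igraph::ecount(g), 1)
  expect_setequal(igraph::V(g)$name, c("A", "B"))  # score == 0.9 excluded

  g0 <- filter_ppi(edges[0, ], 0.9)
  expect_equal(igraph::vcount(g0), 0)
})

test_that("hub calling uses a strict degree threshold with lexicographic ties", {
  star <- data.frame(protein_a = "HUB", protein_b = sprintf("L%02d", 1:31),
                     combined_score = 0.99)
  g <- filter_ppi(star, 0.9)
  expect_equal(hub_genes(g, 30), "HUB")
  g30 <- filter_ppi(star[1:30, ], 0.9)
  expect_equal(hub_genes(g30, 30), character())

  k5 <- t(utils::combn(c("N1", "N2", "N3", "N4", "N5"), 2))
  g5 <- filter_ppi(data.frame(protein_a = k5[, 1], protein_b = k5[, 2],
                              combined_score = 1), 0.9)
  expect_equal(hub_genes(g5, 3), c("N1", "N2", "N3", "N4", "N5"))
})

test_that("cluster score equals size times density (2E/(N-1))", {
  expect_equal(round(cluster_score(19, 112), 3), 12.444)
  expect_equal(round(cluster_score(20, 62), 3), 6.526)
  expect_equal(cluster_score(3, 3), 3.0)  # triangle: density 1 -> score = N
  expect_error(cluster_score(1, 0), "2 nodes")
  expect_error(cluster_score(4, 7), "choose")
  # algebraic identity n * density == 2E/(N-1), and relabeling invariance
  for (n in c(5, 9, 14)) for (e in c(n - 1, n, 2 * n)) {
    expect_equal(cluster_score(n, e), n * (2 * e / (n * (n - 1))))
  }
})

test_that("MCODE returns nothing without a 3-core and finds an isolated clique", {
  # a tree has no 2-core, let alone a 3-core
  tree <- data.frame(protein_a = c("A", "A", "B", "B"),
                     protein_b = c("B", "C", "D", "E"),
                     combined_score = 1)
  expect_equal(nrow(mcode_clusters(filter_ppi(tree, 0.9))), 0)

  k6 <- t(utils::combn(sprintf("K%d", 1:6), 2))
  sparse <- data.frame(
    protein_a = c(k6[, 1], "X1", "X2"),
    protein_b = c(k6[, 2], "X2", "X3"),
    combined_score = 1)
  cl <- mcode_clusters(filter_ppi(sparse, 0.9))
  expect_equal(nrow(cl), 1)
  expect_setequal(cl$members[[1]], sprintf("K%d", 1:6))
  expect_equal(cl$score, 6)  # clique score equals its size
})

test_that("MCODE recovers two separated cliques exactly and deterministically", {
  # two 7-cliques joined to a sparse background tree: recovery is
  # structural, so the expectation is exact
  cliq <- function(tag) t(utils::combn(sprintf("%s%d", tag, 1:7), 2))
  a <- cliq("A"); b <- cliq("B")
  bridge <- data.frame(
    protein_a = c("A1", "X1", "X2", "B1"),
    protein_b = c("X1", "X2", "X3", "X3"),
    combined_score = 0.95)
  edges <- rbind(
    data.frame(protein_a = a[, 1], protein_b = a[, 2], combined_score = 0.99),
    data.frame(protein_a = b[, 1], protein_b = b[, 2], combined_score = 0.99),
    bridge)
  g <- filter_ppi(edges, 0.9)
  cl <- mcode_clusters(g, mcode_config())
  expect_equal(nrow(cl), 2)
  expect_setequal(cl$members[[1]], sprintf("A%d", 1:7))
  expect_setequal(cl$members[[2]], sprintf("B%d", 1:7))
  expect_equal(cl$score, c(7, 7))
  expect_identical(cl, mcode_clusters(g, mcode_config()))
})

test_that("MCODE recovers planted clique modules from synthetic PPI data", {
  ppi <- generate_ppi(synth_ppi_config(p_within = 1.0, seed = 42))
  g <- filter_ppi(ppi$edges, 0.9)
  # precondition of the check: no surviving background edge bridges the
  # two planted modules directly (a legitimate bridge merges them)
  mods <- ppi$ground_truth$planted_module_members
  el <- igraph::as_edgelist(g)
  cross <- (el[, 1] %in% mods[[1]] & el[, 2] %in% mods[[2]]) |
    (el[, 1] %in% mods[[2]] & el[, 2] %in% mods[[1]])
  expect_false(any(cross))
  cl <- mcode_clusters(g, mcode_config())
  expect_gte(nrow(cl), 2)
  for (mod in mods) {
    jac <- vapply(cl$members, function(m)
      length(intersect(m, mod)) / length(union(m, mod)), numeric(1))
    expect_gte(max(jac), 0.9)
  }
})

test_that("every returned cluster has a 3-core and clears the score floor", {
  set.seed(8)
  for (rep in 1:3) {
    ppi <- generate_ppi(synth_ppi_config(n_proteins = 60, n_modules = 2,
                                         module_size = 7, p_within = 0.85,
                                         p_background = 0.05,
                                         seed = 100 + rep))
    g <- filter_ppi(ppi$edges, 0)
    cl <- mcode_clusters(g, mcode_config())
    for (i in seq_len(nrow(cl))) {
      sub <- igraph::induced_subgraph(g, cl$members[[i]])
      expect_gte(max(igraph::coreness(sub)), 3)
      expect_gte(cl$score[i], 5)
      expect_equal(cl$score[i], cluster_score(cl$n_nodes[i], cl$n_edges[i]))
    }
  }
})
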