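test_that("network assembly assigns roles, deduplicates and validates universes", {
  net <- composite_ffl_network()
  expect_equal(n_nodes(net), 3)
  expect_equal(n_edges(net), 4)

  # dual membership -> TF_AND_GENE
  pairs <- data.frame(source = c("P", "hsa-mir-1"),
                      target = c("hsa-mir-1", "P"),
                      category = c("TF_MIRNA", "MIRNA_TF"))
  net2 <- build_network(pairs, tf_universe = "P", gene_universe = "P",
                        mirna_universe = "hsa-mir-1")
  expect_equal(net2$nodes$role[net2$nodes$node == "P"], "TF_AND_GENE")

  # same pair twice leaves the edge count unchanged
  net3 <- build_network(rbind(pairs, pairs), "P", "P", "hsa-mir-1")
  expect_equal(n_edges(net3), 2)

  expect_error(build_network(pairs, "OTHER", "OTHER", "hsa-mir-1"),
               "no universe")
})

test_that("role census counts sum to the node total", {
  net <- composite_ffl_network()
  cen <- node_census(net)
  expect_equal(cen$TF, 1); expect_equal(cen$MIRNA, 1)
  expect_equal(cen$GENE, 1); expect_equal(cen$TF_AND_GENE, 0)
  expect_equal(cen$total, 3)

  empty <- typed_network(data.frame(node = character(), role = character()),
                         NULL)
  expect_equal(node_census(empty)$total, 0)

  set.seed(21)
  for (rep in 1:5) {
    net <- random_typed_network(n_nodes = 12)
    cen <- node_census(net)
    expect_equal(cen$TF + cen$MIRNA + cen$GENE + cen$TF_AND_GENE, cen$total)
    expect_equal(cen$total, n_nodes(net))
  }
})

test_that("topology statistics match hand values on canonical small graphs", {
  # triangle: everyone clusters perfectly
  tri <- build_network(
    data.frame(source = c("T1", "T1", "hsa-mir-1"),
               target = c("hsa-mir-1", "G1", "G1"),
               category = c("TF_MIRNA", "TF_GENE", "MIRNA_GENE")),
    "T1", "G1", "hsa-mir-1")
  prof <- topology_profile(tri)
  expect_true(all(prof$clustering_coefficient == 1))

  # path A-B-C: middle node has no triangles; leaves see degree-2 neighbour
  path <- build_network(
    data.frame(source = c("T1", "hsa-mir-1"),
               target = c("hsa-mir-1", "G1"),
               category = c("TF_MIRNA", "MIRNA_GENE")),
    "T1", "G1", "hsa-mir-1")
  prof2 <- topology_profile(path)
  expect_equal(prof2$clustering_coefficient[prof2$node == "hsa-mir-1"], 0)
  expect_equal(prof2$neighborhood_connectivity[prof2$node == "T1"], 2)
  expect_equal(prof2$degree[prof2$node == "hsa-mir-1"], 2)
})

test_that("topology statistics agree with a per-definition naive oracle", {
  set.seed(33)
  for (rep in 1:8) {
    net <- random_typed_network(n_nodes = sample(5:15, 1),
                                edges_per_category = sample(3:8, 1))
    got <- topology_profile(net)
    want <- naive_topology(net)
    got <- got[order(got$node), ]; rownames(got) <- NULL
    want <- want[order(want$node), ]; rownames(want) <- NULL
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("power-law fitting is exact on noiseless data and sane on edge cases", {
  # n(k) = 16 k^-1 over k in {1,2,4,8}
  fit <- fit_power_law(rep(c(1, 2, 4, 8), times = c(16, 8, 4, 2)))
  expect_equal(fit$a, 16, tolerance = 1e-10)
  expect_equal(fit$b, -1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)

  flat <- fit_power_law(rep(c(1, 2, 3), times = c(4, 4, 4)))
  expect_equal(flat$b, 0, tolerance = 1e-10)

  expect_error(fit_power_law(rep(3, 10)), "distinct")
})

test_that("ego sub-networks equal a brute-force neighbour scan", {
  net <- composite_ffl_network()
  star <- ego_subnetwork(net, "TF1")
  expect_equal(n_nodes(star), 3)

  leafy <- build_network(
    data.frame(source = c("T1", "T1", "T2"),
               target = c("hsa-mir-1", "G1", "G2"),
               category = c("TF_MIRNA", "TF_GENE", "TF_GENE")),
    c("T1", "T2"), c("G1", "G2"), "hsa-mir-1")
  sub <- ego_subnetwork(leafy, "G2")
  expect_setequal(sub$nodes$node, c("G2", "T2"))
  expect_equal(n_edges(sub), 1)
  expect_error(ego_subnetwork(leafy, "NOPE"), "not in network")

  set.seed(5)
  for (rep in 1:5) {
    net <- random_typed_network(n_nodes = 12)
    center <- sample(net$nodes$node, 1)
    sub <- ego_subnetwork(net, center)
    e <- net$edges
    want <- unique(c(center, e$target[e$source == center],
                     e$source[e$target == center]))
    expect_setequal(sub$nodes$node, want)
  }
})
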