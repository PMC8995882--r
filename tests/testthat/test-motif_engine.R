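test_that("a lone composite FFL yields one class with one instance", {
  census <- enumerate_triads(composite_ffl_network())
  expect_length(census$counts, 1)
  expect_equal(unname(census$counts), 1)
  inst <- census$instances[[1]][[1]]
  expect_true(is_composite_ffl(inst))
  expect_equal(nrow(inst$edges), 4)
})

test_that("a directed path induces exactly one connected triad", {
  net <- build_network(
    data.frame(source = c("T1", "hsa-mir-1"),
               target = c("hsa-mir-1", "G1"),
               category = c("TF_MIRNA", "MIRNA_GENE")),
    "T1", "G1", "hsa-mir-1")
  census <- enumerate_triads(net)
  expect_equal(sum(census$counts), 1)
  expect_false(is_composite_ffl(census$instances[[1]][[1]]))
})

test_that("canonical signatures are invariant to node relabeling and see edge differences", {
  roles <- c(A = "TF", B = "MIRNA", C = "GENE")
  edges4 <- data.frame(source = c("A", "B", "A", "B"),
                       target = c("B", "A", "C", "C"),
                       category = c("TF_MIRNA", "MIRNA_TF", "TF_GENE",
                                    "MIRNA_GENE"))
  sig <- canonical_class(roles, edges4)

  relabel <- c(A = "Z9", B = "Q1", C = "M5")
  edges_r <- data.frame(source = relabel[edges4$source],
                        target = relabel[edges4$target],
                        category = edges4$category)
  roles_r <- setNames(roles, relabel[names(roles)])
  expect_identical(canonical_class(roles_r, edges_r), sig)

  # dropping the miRNA->TF edge gives the classic (non-composite) FFL
  sig3 <- canonical_class(roles, edges4[-2, ])
  expect_false(identical(sig3, sig))

  expect_error(canonical_class(c(A = "TF", B = "MIRNA", C = "GENE"),
                               edges4[1, ]), "not connected")
})

test_that("composite-FFL recognition requires all four categories and the role triple", {
  census <- enumerate_triads(composite_ffl_network())
  inst <- census$instances[[1]][[1]]
  expect_true(is_composite_ffl(inst))

  # classic FFL without the miRNA->TF arm is not composite
  net3 <- build_network(
    data.frame(source = c("T1", "T1", "hsa-mir-1"),
               target = c("hsa-mir-1", "G1", "G1"),
               category = c("TF_MIRNA", "TF_GENE", "MIRNA_GENE")),
    "T1", "G1", "hsa-mir-1")
  c3 <- enumerate_triads(net3)
  expect_false(is_composite_ffl(c3$instances[[1]][[1]]))

  # two TFs and a gene can never be composite
  net2tf <- build_network(
    data.frame(source = c("T1", "T2"), target = c("G1", "G1"),
               category = c("TF_GENE", "TF_GENE")),
    c("T1", "T2"), "G1", character())
  c2 <- enumerate_triads(net2tf)
  expect_false(is_composite_ffl(c2$instances[[1]][[1]]))
})

test_that("census counts equal the brute-force colored-isomorphism oracle", {
  set.seed(14)
  for (rep in 1:20) {
    net <- random_typed_network(n_nodes = sample(6:12, 1),
                                edges_per_category = sample(3:7, 1))
    fast <- enumerate_triads(net)
    slow <- naive_triad_census(net)
    expect_equal(sum(fast$counts), length(slow$class_id))
    # identical partitions: the two censuses pair every triple to the same
    # classmates (signature <-> naive class id is a bijection)
    sig_by_key <- census_triple_signatures(fast)
    expect_setequal(names(sig_by_key), slow$keys)
    tab <- table(sig_by_key[slow$keys], slow$class_id)
    expect_true(all(rowSums(tab > 0) == 1))
    expect_true(all(colSums(tab > 0) == 1))
  }
})

test_that("randomization preserves per-category degree sequences, roles and determinism", {
  cfg <- synth_regnet_config(n_planted_ffl = 10,
                             background_edges_per_category = 25, seed = 19)
  reg <- generate_regulatory_pairs(cfg)
  net <- build_network(reg$pairs, reg$universes$tf, reg$universes$gene,
                       reg$universes$mirna)
  before <- per_category_degrees(net)
  r1 <- randomize_network(net, seed = 77)
  expect_identical(per_category_degrees(r1), before)
  expect_identical(r1$nodes, net$nodes)
  expect_identical(randomize_network(net, seed = 77), r1)
  expect_equal(n_edges(r1), n_edges(net))

  # a category with a single edge cannot move
  lone <- composite_ffl_network()
  expect_identical(randomize_network(lone, seed = 5)$edges, lone$edges)
})

test_that("planted composite FFLs are called significant and recovered by merging", {
  cfg <- synth_regnet_config(n_tf = 10, n_mirna = 15, n_gene = 25,
                             n_planted_ffl = 15,
                             background_edges_per_category = 20, seed = 23)
  reg <- generate_regulatory_pairs(cfg)
  net <- build_network(reg$pairs, reg$universes$tf, reg$universes$gene,
                       reg$universes$mirna)
  census <- enumerate_triads(net)
  stats <- motif_zscores(net, motif_config(n_random = 100, seed = 23),
                         census = census)
  comp <- stats[stats$is_composite_ffl, ]
  expect_gte(sum(comp$count_real), 15)
  expect_true(any(comp$significant))

  merged <- select_and_merge(stats, census, motif_config(n_random = 100,
                                                         seed = 23))
  got <- paste(merged$triples$tf, merged$triples$mirna, merged$triples$gene)
  want <- paste(reg$ground_truth$planted_ffl_triples$tf,
                reg$ground_truth$planted_ffl_triples$mirna,
                reg$ground_truth$planted_ffl_triples$gene)
  expect_true(all(want %in% got))
  # merged network is the union of the selected instances
  expect_true(all(merged$triples$mirna %in% merged$network$nodes$node))
})

test_that("empirical p-values use the add-one estimator and flag sd-zero classes", {
  net <- composite_ffl_network()
  stats <- motif_zscores(net, motif_config(n_random = 2, seed = 3))
  # single-edge categories cannot be rewired: null counts equal the real
  # count, so sd is 0 and p is the add-one maximum
  expect_true(all(stats$sd_zero))
  expect_true(all(is.na(stats$z_score)))
  expect_true(all(stats$p_value == 1))
  expect_false(any(stats$significant))

  expect_warning(res <- select_and_merge(stats, enumerate_triads(net),
                                         motif_config(n_random = 2, seed = 3)),
                 "no significant")
  expect_equal(n_nodes(res$network), 0)
  expect_equal(nrow(res$triples), 0)
})

test_that("two instances sharing a gene merge into five nodes", {
  pairs <- rbind(
    data.frame(source = c("T1", "hsa-mir-1", "T1", "hsa-mir-1"),
               target = c("hsa-mir-1", "T1", "G1", "G1"),
               category = c("TF_MIRNA", "MIRNA_TF", "TF_GENE", "MIRNA_GENE")),
    data.frame(source = c("T2", "hsa-mir-2", "T2", "hsa-mir-2"),
               target = c("hsa-mir-2", "T2", "G1", "G1"),
               category = c("TF_MIRNA", "MIRNA_TF", "TF_GENE", "MIRNA_GENE")))
  net <- build_network(pairs, c("T1", "T2"), "G1",
                       c("hsa-mir-1", "hsa-mir-2"))
  census <- enumerate_triads(net)
  comp_sigs <- names(Filter(
    function(insts) is_composite_ffl(insts[[1]]), census$instances))
  stats <- data.frame(signature = comp_sigs, count_real = NA, null_mean = NA,
                      null_sd = NA, z_score = 10, p_value = 0.001,
                      n_random = 10, sd_zero = FALSE, is_composite_ffl = TRUE,
                      significant = TRUE, stringsAsFactors = FALSE)
  merged <- select_and_merge(stats, census)
  expect_equal(n_nodes(merged$network), 5)
  expect_equal(nrow(merged$triples), 2)
})
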