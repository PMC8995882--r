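test_that("a single planted FFL with no background is exactly 3 nodes / 4 edges", {
  reg <- generate_regulatory_pairs(synth_regnet_config(
    n_tf = 5, n_mirna = 5, n_gene = 5, n_dual = 0, n_planted_ffl = 1,
    background_edges_per_category = 0, seed = 2))
  expect_equal(nrow(reg$pairs), 4)
  expect_setequal(reg$pairs$category, EDGE_CATEGORIES)
  net <- build_network(reg$pairs, reg$universes$tf, reg$universes$gene,
                       reg$universes$mirna)
  expect_equal(n_nodes(net), 3)
  expect_equal(n_edges(net), 4)
  expect_equal(nrow(reg$ground_truth$planted_ffl_triples), 1)
})

test_that("generators are pure functions of their config (seed included)", {
  cfg <- synth_regnet_config(n_planted_ffl = 8,
                             background_edges_per_category = 15, seed = 9)
  expect_identical(generate_regulatory_pairs(cfg),
                   generate_regulatory_pairs(cfg))
  pcfg <- synth_ppi_config(n_proteins = 40, n_modules = 2, module_size = 6,
                           seed = 9)
  expect_identical(generate_ppi(pcfg), generate_ppi(pcfg))
  dcfg <- synth_drug_config(n_drugs = 10, seed = 9)
  q <- sprintf("Q%02d", 1:10)
  expect_identical(generate_drug_targets(dcfg, q),
                   generate_drug_targets(dcfg, q))
})

test_that("ground truth is verifiable against the emitted tables by direct scan", {
  reg <- generate_regulatory_pairs(synth_regnet_config(
    n_planted_ffl = 6, background_edges_per_category = 12, seed = 4))
  has_pair <- function(s, t, cat)
    any(reg$pairs$source == s & reg$pairs$target == t &
          reg$pairs$category == cat)
  gt <- reg$ground_truth$planted_ffl_triples
  for (i in seq_len(nrow(gt))) {
    expect_true(has_pair(gt$tf[i], gt$mirna[i], "TF_MIRNA"))
    expect_true(has_pair(gt$mirna[i], gt$tf[i], "MIRNA_TF"))
    expect_true(has_pair(gt$tf[i], gt$gene[i], "TF_GENE"))
    expect_true(has_pair(gt$mirna[i], gt$gene[i], "MIRNA_GENE"))
  }
})

test_that("the motif census finds exactly the planted composite FFLs", {
  cfg <- synth_regnet_config(n_planted_ffl = 5,
                             background_edges_per_category = 20, seed = 7)
  reg <- generate_regulatory_pairs(cfg)
  net <- build_network(reg$pairs, reg$universes$tf, reg$universes$gene,
                       reg$universes$mirna)
  census <- enumerate_triads(net)
  comp <- Filter(function(s) is_composite_ffl(census$instances[[s]][[1]]),
                 names(census$counts))
  expect_gte(length(comp), 1)
  expect_equal(sum(census$counts[comp]), 5)
  triples <- do.call(rbind, lapply(unlist(census$instances[comp],
                                          recursive = FALSE),
                                   composite_ffl_assignments))
  key <- function(df) sort(paste(df$tf, df$mirna, df$gene))
  expect_equal(key(triples), key(reg$ground_truth$planted_ffl_triples))
})

test_that("planted PPI modules appear as dense blocks with signal scores", {
  cfg <- synth_ppi_config(n_proteins = 40, n_modules = 2, module_size = 6,
                          p_within = 1.0, p_background = 0,
                          seed = 3)
  ppi <- generate_ppi(cfg)
  # p_within = 1 -> each module is a full clique; p_background = 0 -> no
  # other edges
  expect_equal(nrow(ppi$edges), 2 * choose(6, 2))
  for (mod in ppi$ground_truth$planted_module_members) {
    inside <- ppi$edges$protein_a %in% mod & ppi$edges$protein_b %in% mod
    expect_equal(sum(inside), choose(6, 2))
    expect_true(all(ppi$edges$combined_score[inside] >= 0.905))
  }
})

test_that("the planted drug's targets fall inside the query set as configured", {
  q <- sprintf("QG%02d", 1:8)
  res <- generate_drug_targets(synth_drug_config(
    n_drugs = 5, targets_per_drug = 4, planted_drug_overlap = 4, seed = 6), q)
  planted <- res$pairs[res$pairs$drug_id == res$ground_truth$planted_drug_id, ]
  expect_equal(nrow(planted), 4)
  expect_true(all(planted$target_gene %in% q))

  res1 <- generate_drug_targets(synth_drug_config(
    n_drugs = 1, targets_per_drug = 7, planted_drug_overlap = 2, seed = 6), q)
  expect_equal(nrow(res1$pairs), 7)
})

test_that("write_synthetic_inputs materialises a readable, consistent input set", {
  dir <- withr::local_tempdir()
  paths <- write_synthetic_inputs(
    dir,
    regnet_config = synth_regnet_config(n_planted_ffl = 4,
                                        background_edges_per_category = 8,
                                        seed = 12),
    ppi_config = synth_ppi_config(n_proteins = 30, n_modules = 1,
                                  module_size = 6, seed = 12),
    drug_config = synth_drug_config(n_drugs = 8, targets_per_drug = 4,
                                    planted_drug_overlap = 3, seed = 12))
  expect_true(all(file.exists(unlist(paths))))
  pairs <- read_pair_table(paths$tf_mirna, "TF_MIRNA")
  expect_gt(nrow(pairs), 0)
  gt <- jsonlite::read_json(paths$ground_truth, simplifyVector = TRUE)
  expect_equal(nrow(gt$planted_ffl_triples), 4)
})
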