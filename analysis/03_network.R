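#!/usr/bin/env Rscript
# Stage 3: assemble the TF-miRNA-gene network from the four pair tables,
# profile its topology and fit the power-law degree distribution. Writes
# the network SIF, the per-node topology table and the fit under results/.

suppressPackageStartupMessages(library(fflregnet))

pairs <- rbind(
  read_pair_table("results/data/tf_mirna.tsv", "TF_MIRNA"),
  read_pair_table("results/data/tf_gene.tsv", "TF_GENE"),
  read_pair_table("results/data/mirna_gene.tsv", "MIRNA_GENE"),
  read_pair_table("results/data/mirna_tf.tsv", "MIRNA_TF"))
uni <- lapply(c(tf = "tf", gene = "gene", mirna = "mirna"), function(u)
  readLines(sprintf("results/data/%s_universe.txt", u)))
net <- build_network(pairs, uni$tf, uni$gene, uni$mirna)
cen <- node_census(net)
cat(sprintf("network: %d nodes (%d TF, %d TF&gene, %d miRNA, %d gene), %d edges\n",
            cen$total, cen$TF, cen$TF_AND_GENE, cen$MIRNA, cen$GENE,
            n_edges(net)))
write_sif(net, "results/tmign.sif")

topo <- topology_profile(net)
write.table(topo, "results/topology.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
fit <- fit_power_law(topo$degree)
cat(sprintf("degree distribution fit: n(k) = %.3f k^(%.3f), R^2 = %.3f\n",
            fit$a, fit$b, fit$r_squared))
jsonlite::write_json(fit, "results/power_law.json", auto_unbox = TRUE,
                     digits = NA)

# first-neighbour sub-network around the highest-degree regulator
top <- topo$node[which.max(topo$degree)]
sub <- ego_subnetwork(net, top)
cat(sprintf("highest-degree node %s: ego sub-network of %d nodes / %d edges\n",
            top, n_nodes(sub), n_edges(sub)))
write_sif(sub, "results/ego_top_degree.sif")
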