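#!/usr/bin/env Rscript
# Stage 5: drug screen. Maps the motif sub-network's gene-capable nodes to
# drug targets and tests every (miRNA, drug) combination with the
# cumulative hypergeometric distribution (both tails; upper tail drives
# the significance call; drugs with < 2 targets discarded).

suppressPackageStartupMessages(library(fflregnet))

drugs <- read_drug_target_table("results/data/drug_targets.tsv")
sub <- read_sif("results/iacfmsn.sif")
full <- read_sif("results/tmign.sif")

genes <- sub$nodes$node[sub$nodes$role %in% c("GENE", "TF_AND_GENE")]
mapped <- map_drugs_to_genes(genes, drugs, approved_only = TRUE)
cat(sprintf("%d approved drug-target pairs hit %d sub-network genes (%d drugs)\n",
            nrow(mapped), length(unique(mapped$target_gene)),
            length(unique(mapped$drug_id))))
write.table(mapped, "results/drug_gene_map.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

mirnas <- sub$nodes$node[sub$nodes$role == "MIRNA"]
e <- full$edges[full$edges$category %in% c("MIRNA_GENE", "MIRNA_TF") &
                  full$edges$source %in% mirnas, ]
mirna_targets <- split(e$target, e$source)
drug_targets <- split(drugs$target_gene[drugs$approved],
                      drugs$drug_id[drugs$approved])
assoc <- mirna_drug_association(mirna_targets, drug_targets, M = 20000,
                                min_drug_targets = 2, alpha = 0.05,
                                tail = "upper")
write.table(assoc, "results/drug_associations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("tested %d (miRNA, drug) pairs; %d significant at upper-tail p < 0.05\n",
            nrow(assoc), sum(assoc$significant)))
top <- assoc[1, ]
cat(sprintf("smallest upper-tail p: %s x %s (x = %d, K = %d, N = %d, p = %.4g)\n",
            top$mirna_id, top$drug_id, top$x, top$K, top$N, top$p_upper))
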