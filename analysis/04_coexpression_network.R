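#!/usr/bin/env Rscript
# Stage 4: key-lncRNA selection and bipartite co-expression network.
#
# The 9 reversal lncRNAs with the largest treatment-contrast fold change are
# the key lncRNAs; Pearson correlation across all 12 pooled samples against
# every differentially expressed mRNA, keeping pairs with |r| >= 0.98 and
# p < 0.05. Exports Cytoscape-ready SIF alongside the full edge table.

suppressPackageStartupMessages(library(reversalnet))

study <- read_expression_study("results/study/matrix.tsv",
                               "results/study/samples.tsv",
                               "results/study/annotation.tsv")
rev_tab <- utils::read.delim("results/reversal.tsv")
de_a <- utils::read.delim("results/de/retained_CIA_vs_Control.tsv")
de_b <- utils::read.delim("results/de/retained_BZXD_vs_CIA.tsv")

lnc_rec <- rev_tab[rev_tab$biotype == "lncRNA", ]
key <- select_key_lncrnas(lnc_rec, min(9, nrow(lnc_rec)), fc_column = "fc_b")
cat("key lncRNAs (descending treatment-contrast fc):\n")
print(lnc_rec[match(key, lnc_rec$transcript_id), c("transcript_id", "fc_b")],
      row.names = FALSE)

mrna_ids <- study$annotation$transcript_id[study$annotation$biotype == "mRNA"]
candidates <- intersect(union(de_a$transcript_id, de_b$transcript_id),
                        mrna_ids)
net <- build_network(study, key, candidates)
write_edge_list(net, "results/edges.tsv", "TSV")
write_edge_list(net, "results/edges.sif", "SIF")

cat(sprintf("network: %d lncRNA nodes x %d mRNA nodes, %d edges (%d positive, %d negative)\n",
            length(net$lncrna_nodes), length(net$mrna_nodes),
            nrow(net$edges), sum(net$edges$r > 0), sum(net$edges$r < 0)))

truth <- read_planted_truth("results/study/planted_truth.tsv")
planted <- paste(truth$planted_edges$lncrna_id, truth$planted_edges$mrna_id)
got <- paste(net$edges$lncrna_id, net$edges$mrna_id)
cat(sprintf("planted-edge recovery: %d / %d; non-planted edges: %d\n",
            sum(planted %in% got), length(planted), sum(!got %in% planted)))
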