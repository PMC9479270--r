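#!/usr/bin/env Rscript
# Stage 1: generate the synthetic three-group microarray study.
#
# Emulates the study design: 12 arrays (Control / CIA / BZXD x 4 replicates),
# ~1e4 lncRNA and 2e4 mRNA probes, 9 planted key lncRNAs each driving a
# 15-mRNA co-expression module with a treatment-reversal pattern (disease
# fold change 4, treated group pushed past baseline), plus 25 standalone
# reversal mRNAs. Writes the study and the planted ground truth under
# results/study/.

suppressPackageStartupMessages(library(reversalnet))

out <- "results/study"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 20260924L)
sim <- simulate_study(cfg)

write_expression_study(sim$study,
                       file.path(out, "matrix.tsv"),
                       file.path(out, "samples.tsv"),
                       file.path(out, "annotation.tsv"))
write_planted_truth(sim$truth, file.path(out, "planted_truth.tsv"))

cat(sprintf("simulated %d transcripts x %d samples (%d lncRNA, %d mRNA)\n",
            nrow(sim$study$matrix), ncol(sim$study$matrix),
            cfg$n_lncrna, cfg$n_mrna))
cat(sprintf("planted: %d key lncRNAs, %d reversal mRNAs, %d module edges\n",
            length(sim$truth$reversal_lncrna),
            length(sim$truth$reversal_mrna),
            nrow(sim$truth$planted_edges)))
cat("wrote", out, "\n")
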