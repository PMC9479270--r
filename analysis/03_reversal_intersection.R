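#!/usr/bin/env Rscript
# Stage 3: treatment-reversal intersection.
#
# Intersects the two retained, directed DE sets: transcripts up in disease
# and down after treatment (and the converse) are the treatment-responsive
# candidates. Also reproduces the bookkeeping of the bundled published
# 33-lncRNA reversal table through the same code path.

suppressPackageStartupMessages(library(reversalnet))

de_a <- utils::read.delim("results/de/retained_CIA_vs_Control.tsv")
de_b <- utils::read.delim("results/de/retained_BZXD_vs_CIA.tsv")
ann <- utils::read.delim("results/study/annotation.tsv")

rv <- reversal_sets(de_a, de_b)
rec <- rv$records
rec$biotype <- ann$biotype[match(rec$transcript_id, ann$transcript_id)]
dir.create("results", showWarnings = FALSE)
utils::write.table(rec, "results/reversal.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

cnt <- reversal_counts(rv, ann)
cat(sprintf("simulated study: %d up-then-down + %d down-then-up = %d reversal transcripts\n",
            cnt$up_then_down, cnt$down_then_up, cnt$total))
print(cnt$by_biotype)

# published-table bookkeeping through the same operation
pub <- reversal_sets_from_table()
cat(sprintf("published 33-lncRNA table: %d up-then-down, %d down-then-up\n",
            length(pub$up_then_down), length(pub$down_then_up)))

truth <- read_planted_truth("results/study/planted_truth.tsv")
planted <- c(truth$reversal_lncrna, truth$reversal_mrna)
got <- c(rv$up_then_down, rv$down_then_up)
cat(sprintf("recovered %d / %d planted reversal transcripts (%.1f%%)\n",
            length(intersect(got, planted)), length(planted),
            100 * length(intersect(got, planted)) / length(planted)))
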