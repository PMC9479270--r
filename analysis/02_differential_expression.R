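#!/usr/bin/env Rscript
# Stage 2: per-contrast differential expression.
#
# Fold changes on linear group means, two-sided Welch t on log2 intensities,
# then the four-part screen (fc >= 2, p < 0.05, raw intensity > 200 in at
# least one compared group, length < 3 kb) for the disease contrast
# (CIA vs Control) and the treatment contrast (BZXD vs CIA).

suppressPackageStartupMessages(library(reversalnet))

study <- read_expression_study("results/study/matrix.tsv",
                               "results/study/samples.tsv",
                               "results/study/annotation.tsv")
dir.create("results/de", showWarnings = FALSE, recursive = TRUE)
thr <- de_thresholds()

for (ct in list(contrast("CIA", "Control"), contrast("BZXD", "CIA"))) {
  stats <- contrast_statistics(study, ct)
  kept <- filter_de(stats, study, thr)
  stats$q_bh <- p.adjust(stats$p_value, "BH")
  stats$retained <- stats$transcript_id %in% kept$transcript_id
  slug <- gsub(" ", "_", ct$name)
  utils::write.table(stats, file.path("results/de",
                                      paste0("de_", slug, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(kept, file.path("results/de",
                                     paste0("retained_", slug, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d / %d transcripts pass the screen (%d up, %d down)\n",
              ct$name, nrow(kept), nrow(stats),
              sum(kept$direction == "Up"), sum(kept$direction == "Down")))
}
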