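#' Recovery of planted structure across simulation seeds
#'
#' For each seed, simulates a study, runs differential expression, the
#' reversal intersection, key-lncRNA selection and network construction, and
#' scores the result against the planted truth:
#'
#' * reversal sensitivity -- fraction of planted reversal transcripts
#'   (lncRNA and mRNA) recovered by the intersection;
#' * edge sensitivity -- fraction of planted lncRNA-mRNA pairs recovered as
#'   network edges;
#' * false-edge rate -- recovered edges that were not planted, divided by
#'   the number of candidate pairs that were not planted (selected lncRNAs x
#'   candidate mRNAs).
#'
#' The network candidates are the differentially expressed mRNAs of either
#' contrast, as in [run_pipeline()].
#'
#' @param cfg a [sim_config()]; its seed field is replaced per iteration.
#' @param seeds integer vector of seeds.
#' @param thresholds a [de_thresholds()].
#' @param min_abs_r,max_p network edge thresholds.
#' @return A list with `per_seed` (data frame of the three rates per seed)
#'   and `summary` (their means).
#' @export
planted_recovery <- function(cfg, seeds, thresholds = de_thresholds(),
                             min_abs_r = 0.98, max_p = 0.05) {
  stopifnot(inherits(cfg, "sim_config"))
  rows <- lapply(seeds, function(s) {
    cfg$seed <- as.integer(s)
    sim <- simulate_study(cfg)
    study <- sim$study
    truth <- sim$truth
    groups <- cfg$groups

    de_a <- filter_de(contrast_statistics(study, contrast(groups[2], groups[1])),
                      study, thresholds)
    de_b <- filter_de(contrast_statistics(study, contrast(groups[3], groups[2])),
                      study, thresholds)
    rev <- reversal_sets(de_a, de_b)
    recovered <- c(rev$up_then_down, rev$down_then_up)
    planted_rev <- c(truth$reversal_lncrna, truth$reversal_mrna)
    rev_sens <- if (length(planted_rev))
      length(intersect(recovered, planted_rev)) / length(planted_rev)
    else NA_real_

    ann <- study$annotation
    lnc_rec <- rev$records[
      ann$biotype[match(rev$records$transcript_id, ann$transcript_id)] ==
        "lncRNA", , drop = FALSE]
    k <- min(cfg$n_reversal_lncrna, nrow(lnc_rec))
    key <- if (k > 0L) select_key_lncrnas(lnc_rec, k, fc_column = "fc_b")
           else character()
    mrna_ids <- ann$transcript_id[ann$biotype == "mRNA"]
    candidates <- intersect(union(de_a$transcript_id, de_b$transcript_id),
                            mrna_ids)
    net <- build_network(study, key, candidates,
                         min_abs_r = min_abs_r, max_p = max_p)

    planted_pairs <- paste(truth$planted_edges$lncrna_id,
                           truth$planted_edges$mrna_id)
    got_pairs <- paste(net$edges$lncrna_id, net$edges$mrna_id)
    edge_sens <- if (length(planted_pairs))
      mean(planted_pairs %in% got_pairs) else NA_real_
    n_pairs <- length(key) * length(candidates)
    n_planted_cand <- sum(truth$planted_edges$lncrna_id %in% key &
                            truth$planted_edges$mrna_id %in% candidates)
    n_false <- sum(!got_pairs %in% planted_pairs)
    false_rate <- if (n_pairs - n_planted_cand > 0)
      n_false / (n_pairs - n_planted_cand) else NA_real_

    data.frame(seed = s, reversal_sensitivity = rev_sens,
               edge_sensitivity = edge_sens, false_edge_rate = false_rate,
               n_candidates = length(candidates))
  })
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed,
       summary = list(
         reversal_sensitivity = mean(per_seed$reversal_sensitivity),
         edge_sensitivity = mean(per_seed$edge_sensitivity),
         false_edge_rate = mean(per_seed$false_edge_rate)))
}
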