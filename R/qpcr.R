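#' Relative quantification by the 2^-ddCt (Livak) method
#'
#' For each sample and gene, technical replicates are averaged, then
#' dCt = Ct_gene - Ct_reference within the sample, ddCt = dCt minus the
#' arithmetic mean dCt of the calibrator group (equivalently, folds are
#' centred so their geometric mean over the calibrator group is 1), and
#' fold = 2^-ddCt. Amplification efficiency is fixed at 2.
#'
#' @param ct data frame with columns `sample_id`, `group`, `gene`, `ct`
#'   (threshold cycles, > 0); one row per technical replicate.
#' @param reference_gene name of the internal reference (e.g. `"U6"`);
#'   must be measured in every sample.
#' @param calibrator_group group whose mean dCt defines ddCt = 0.
#' @return Data frame with one row per sample x non-reference gene:
#'   `sample_id`, `group`, `gene`, `delta_ct`, `delta_delta_ct`, `fold`.
#' @export
ddct <- function(ct, reference_gene, calibrator_group) {
  need <- c("sample_id", "group", "gene", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss))
    stop("format error: Ct table missing column ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(ct$ct <= 0) || anyNA(ct$ct))
    stop("data error: Ct values must be positive", call. = FALSE)
  if (!calibrator_group %in% ct$group)
    stop("design error: calibrator group '", calibrator_group,
         "' has no samples", call. = FALSE)

  # average technical replicates
  agg <- stats::aggregate(ct ~ sample_id + group + gene, data = ct,
                          FUN = mean)
  ref <- agg[agg$gene == reference_gene, , drop = FALSE]
  missing_ref <- setdiff(unique(agg$sample_id), ref$sample_id)
  if (length(missing_ref))
    stop("data error: reference gene '", reference_gene,
         "' not measured in sample ", missing_ref[1], call. = FALSE)
  tgt <- agg[agg$gene != reference_gene, , drop = FALSE]
  tgt$delta_ct <- tgt$ct - ref$ct[match(tgt$sample_id, ref$sample_id)]

  cal_mean <- tapply(tgt$delta_ct[tgt$group == calibrator_group],
                     tgt$gene[tgt$group == calibrator_group], mean)
  no_cal <- setdiff(unique(tgt$gene), names(cal_mean))
  if (length(no_cal))
    stop("data error: gene '", no_cal[1],
         "' has no calibrator-group measurement", call. = FALSE)
  tgt$delta_delta_ct <- tgt$delta_ct - as.vector(cal_mean[tgt$gene])
  tgt$fold <- 2^(-tgt$delta_delta_ct)
  out <- tgt[order(tgt$gene, tgt$sample_id),
             c("sample_id", "group", "gene", "delta_ct", "delta_delta_ct",
               "fold")]
  rownames(out) <- NULL
  out
}

#' Compare relative expression between two groups
#'
#' Independent two-sample Student t-test (two-sided) on the per-sample fold
#' values of one gene, or on ddCt values with `on = "delta_delta_ct"`.
#'
#' @param rel output of [ddct()].
#' @param group_a,group_b group labels to compare.
#' @param gene gene to test; may be omitted when `rel` holds a single gene.
#' @param on test on `"fold"` (default) or `"delta_delta_ct"` values.
#' @param var_equal pooled-variance Student test (default, matching the
#'   usual qPCR convention) or Welch when FALSE.
#' @return List: `gene`, `mean_a`, `mean_b`, `difference` (a - b), `p_value`.
#' @export
group_compare <- function(rel, group_a, group_b, gene = NULL,
                          on = c("fold", "delta_delta_ct"),
                          var_equal = TRUE) {
  on <- match.arg(on)
  if (is.null(gene)) {
    genes <- unique(rel$gene)
    if (length(genes) != 1L)
      stop("parameter error: multiple genes present; pass `gene`",
           call. = FALSE)
    gene <- genes
  }
  rel <- rel[rel$gene == gene, , drop = FALSE]
  xa <- rel[[on]][rel$group == group_a]
  xb <- rel[[on]][rel$group == group_b]
  if (length(xa) < 2L || length(xb) < 2L)
    stop("design error: both groups need >= 2 samples", call. = FALSE)
  if (stats::var(xa) == 0 && stats::var(xb) == 0 && mean(xa) == mean(xb)) {
    p <- 1  # identical groups: no evidence of difference
  } else {
    p <- stats::t.test(xa, xb, var.equal = var_equal)$p.value
  }
  list(gene = gene, mean_a = mean(xa), mean_b = mean(xb),
       difference = mean(xa) - mean(xb), p_value = p)
}
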