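#' Define a two-group contrast
#'
#' @param numerator_group,denominator_group group labels; the fold change is
#'   numerator over denominator.
#' @param name contrast label; defaults to "numerator vs denominator".
#' @return A list of class `contrast`.
#' @export
contrast <- function(numerator_group, denominator_group,
                     name = paste(numerator_group, "vs", denominator_group)) {
  if (identical(numerator_group, denominator_group))
    stop("design error: contrast groups must differ", call. = FALSE)
  structure(list(name = name, numerator_group = numerator_group,
                 denominator_group = denominator_group),
            class = "contrast")
}

#' Per-transcript fold change and Welch-t p-value for one contrast
#'
#' Fold change is computed on linear-scale group means and reported as a
#' magnitude >= 1 with a separate direction (Up when the numerator-group mean
#' exceeds the denominator's, None when they are equal). The p-value is a
#' two-sided Welch (unequal-variance) two-sample t-test on log2 intensities;
#' set `pooled_var = TRUE` for the pooled-variance Student test.
#'
#' @param study an `expression_study`.
#' @param ct a [contrast()].
#' @param pooled_var use the pooled-variance t-test instead of Welch.
#' @return Data frame ordered by `transcript_id` with columns
#'   `transcript_id`, `fc_magnitude`, `direction`, `p_value`,
#'   `mean_numerator`, `mean_denominator` (linear-scale means).
#' @export
contrast_statistics <- function(study, ct, pooled_var = FALSE) {
  stopifnot(inherits(study, "expression_study"), inherits(ct, "contrast"))
  s_num <- group_samples(study, ct$numerator_group)
  s_den <- group_samples(study, ct$denominator_group)
  if (length(s_num) < 2L || length(s_den) < 2L)
    stop("design error: both contrast groups need >= 2 replicates",
         call. = FALSE)
  if (any(study$matrix <= 0))
    stop("data error: intensities must be strictly positive", call. = FALSE)

  x_num <- study$matrix[, s_num, drop = FALSE]
  x_den <- study$matrix[, s_den, drop = FALSE]
  mean_num <- rowMeans(x_num)
  mean_den <- rowMeans(x_den)
  ratio <- mean_num / mean_den
  fc <- pmax(ratio, 1 / ratio)
  direction <- ifelse(ratio > 1, "Up", ifelse(ratio < 1, "Down", "None"))

  l_num <- log2(x_num)
  l_den <- log2(x_den)
  n1 <- ncol(l_num)
  n2 <- ncol(l_den)
  m1 <- rowMeans(l_num)
  m2 <- rowMeans(l_den)
  v1 <- rowSums((l_num - m1)^2) / (n1 - 1)
  v2 <- rowSums((l_den - m2)^2) / (n2 - 1)
  if (pooled_var) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(se2))
  } else {
    a1 <- v1 / n1
    a2 <- v2 / n2
    se2 <- a1 + a2
    df <- se2^2 / (a1^2 / (n1 - 1) + a2^2 / (n2 - 1))
  }
  diff <- m1 - m2
  tstat <- diff / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), df)
  # degenerate rows: zero variance in both groups
  zero_se <- se2 == 0
  p[zero_se & diff == 0] <- 1
  p[zero_se & diff != 0] <- 0

  out <- data.frame(
    transcript_id = rownames(study$matrix),
    fc_magnitude = unname(fc),
    direction = unname(direction),
    p_value = unname(p),
    mean_numerator = unname(mean_num),
    mean_denominator = unname(mean_den),
    stringsAsFactors = FALSE
  )
  out[order(out$transcript_id), , drop = FALSE]
}

#' Differential-expression filtering thresholds
#'
#' Defaults follow the microarray screening convention: fold change >= 2,
#' raw p < 0.05, mean raw intensity above 200 in at least one of the two
#' compared groups, and RNA length below 3 kb.
#'
#' @param min_fc minimum fold-change magnitude (>= 1).
#' @param max_p p-value cutoff (exclusive).
#' @param min_raw_intensity raw-intensity floor (exclusive).
#' @param max_length_nt RNA-length ceiling in nucleotides (exclusive).
#' @param strict_fc require fold change strictly greater than `min_fc`
#'   instead of >=.
#' @return A list of class `de_thresholds`.
#' @export
de_thresholds <- function(min_fc = 2, max_p = 0.05, min_raw_intensity = 200,
                          max_length_nt = 3000, strict_fc = FALSE) {
  if (min_fc < 1) stop("invalid threshold: min_fc must be >= 1", call. = FALSE)
  if (max_p <= 0 || max_p > 1)
    stop("invalid threshold: max_p must be in (0, 1]", call. = FALSE)
  structure(list(min_fc = min_fc, max_p = max_p,
                 min_raw_intensity = min_raw_intensity,
                 max_length_nt = max_length_nt, strict_fc = strict_fc),
            class = "de_thresholds")
}

#' Apply the differential-expression filter
#'
#' Retains transcripts with fold-change magnitude >= `min_fc` (strictly
#' greater when `strict_fc`), p-value below `max_p`, mean raw intensity above
#' `min_raw_intensity` in at least one of the two compared groups, and
#' annotated RNA length below `max_length_nt`. A Benjamini-Hochberg adjusted
#' q-value is reported alongside but, following common microarray screening
#' practice, is not part of the filter.
#'
#' @param results output of [contrast_statistics()].
#' @param study the `expression_study` the results were computed on (supplies
#'   the length annotation).
#' @param thresholds a [de_thresholds()].
#' @return Data frame of retained transcripts with their direction, ordered
#'   by `transcript_id`: columns `transcript_id`, `direction`,
#'   `fc_magnitude`, `p_value`, `q_bh`.
#' @export
filter_de <- function(results, study, thresholds = de_thresholds()) {
  stopifnot(inherits(thresholds, "de_thresholds"))
  if (nrow(results) == 0L)
    return(data.frame(transcript_id = character(), direction = character(),
                      fc_magnitude = numeric(), p_value = numeric(),
                      q_bh = numeric(), stringsAsFactors = FALSE))
  idx <- match(results$transcript_id, study$annotation$transcript_id)
  if (anyNA(idx))
    stop("data error: transcript missing annotation: ",
         results$transcript_id[which(is.na(idx))[1]], call. = FALSE)
  len <- study$annotation$length_nt[idx]
  q <- stats::p.adjust(results$p_value, method = "BH")
  fc_ok <- if (isTRUE(thresholds$strict_fc))
    results$fc_magnitude > thresholds$min_fc
  else results$fc_magnitude >= thresholds$min_fc
  keep <- fc_ok &
    results$p_value < thresholds$max_p &
    pmax(results$mean_numerator, results$mean_denominator) >
      thresholds$min_raw_intensity &
    len < thresholds$max_length_nt
  out <- data.frame(
    transcript_id = results$transcript_id[keep],
    direction = results$direction[keep],
    fc_magnitude = results$fc_magnitude[keep],
    p_value = results$p_value[keep],
    q_bh = q[keep],
    stringsAsFactors = FALSE
  )
  out[order(out$transcript_id), , drop = FALSE]
}
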