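#' Select key lncRNAs by treatment-contrast fold change
#'
#' Ranks reversal records by the magnitude of the treatment-contrast fold
#' change and returns the top `k` transcript ids, the standard way a handful
#' of "key" lncRNAs is chosen from a reversal table before network
#' construction. Ties are broken by transcript id, ascending.
#'
#' @param records data frame with `transcript_id` and the fold-change column.
#' @param k how many to select.
#' @param fc_column name of the fold-change column (default the treatment
#'   contrast of the bundled table, `fc_bzxd_vs_cia`; use `fc_b` for
#'   [reversal_sets()] records).
#' @return Character vector of `k` ids, descending by fold change.
#' @export
select_key_lncrnas <- function(records, k, fc_column = "fc_bzxd_vs_cia") {
  if (!fc_column %in% names(records))
    stop("parameter error: no column '", fc_column, "' in records",
         call. = FALSE)
  if (k > nrow(records))
    stop("parameter error: k (", k, ") exceeds number of records (",
         nrow(records), ")", call. = FALSE)
  fc <- records[[fc_column]]
  if (anyNA(fc))
    stop("parameter error: missing fold-change values", call. = FALSE)
  ord <- order(-fc, records$transcript_id)
  records$transcript_id[ord][seq_len(k)]
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return The correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y))
    stop("parameter error: vectors must have equal length", call. = FALSE)
  if (length(x) < 3L)
    stop("parameter error: need at least 3 observations", call. = FALSE)
  dx <- x - mean(x)
  dy <- y - mean(y)
  sx <- sqrt(sum(dx^2))
  sy <- sqrt(sum(dy^2))
  if (sx == 0 || sy == 0)
    stop("undefined correlation: constant vector", call. = FALSE)
  r <- sum(dx * dy) / (sx * sy)
  max(-1, min(1, r))
}

#' Two-sided p-value of a Pearson correlation
#'
#' Uses the exact null distribution of r under bivariate normality:
#' t = r * sqrt((n - 2) / (1 - r^2)) referred to the t distribution with
#' n - 2 degrees of freedom. |r| = 1 maps to p = 0.
#'
#' @param r correlation coefficient(s) in [-1, 1].
#' @param n sample size(s), >= 3.
#' @return Two-sided p-value(s).
#' @export
correlation_pvalue <- function(r, n) {
  if (any(n < 3))
    stop("parameter error: n must be >= 3", call. = FALSE)
  if (any(abs(r) > 1 + 1e-12))
    stop("parameter error: |r| must be <= 1", call. = FALSE)
  r <- pmax(-1, pmin(1, r))
  p <- ifelse(abs(r) == 1, 0, {
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.xmin))
    2 * stats::pt(-abs(tstat), n - 2)
  })
  unname(p)
}

#' Build the bipartite lncRNA-mRNA co-expression network
#'
#' Computes Pearson correlations between every lncRNA / mRNA pair across all
#' samples of the study (the three groups pooled) and keeps the pairs with
#' |r| >= `min_abs_r` and correlation p-value < `max_p`. Correlations are
#' computed on log2 intensities by default. Constant-expression transcripts
#' are skipped with a warning. Candidate nodes left without any edge are not
#' part of the network (no orphan nodes).
#'
#' @param study an `expression_study`.
#' @param lncrna_ids,mrna_ids candidate node ids; must be rows of the study.
#' @param min_abs_r,max_p edge thresholds.
#' @param log2_scale correlate log2 intensities (default) or linear.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A list of class `coexpression_network`: `edges` (data frame
#'   lncrna_id, mrna_id, r, p_value, n, sorted), `lncrna_nodes`,
#'   `mrna_nodes`, `thresholds`.
#' @export
build_network <- function(study, lncrna_ids, mrna_ids,
                          min_abs_r = 0.98, max_p = 0.05,
                          log2_scale = TRUE,
                          method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(study, "expression_study"))
  missing_ids <- setdiff(c(lncrna_ids, mrna_ids), rownames(study$matrix))
  if (length(missing_ids))
    stop("data error: id not in study: ", missing_ids[1], call. = FALSE)
  n <- ncol(study$matrix)
  empty <- function() structure(
    list(edges = data.frame(lncrna_id = character(), mrna_id = character(),
                            r = numeric(), p_value = numeric(),
                            n = integer(), stringsAsFactors = FALSE),
         lncrna_nodes = character(), mrna_nodes = character(),
         thresholds = list(min_abs_r = min_abs_r, max_p = max_p)),
    class = "coexpression_network")
  if (length(lncrna_ids) == 0L || length(mrna_ids) == 0L) return(empty())

  m <- study$matrix[unique(c(lncrna_ids, mrna_ids)), , drop = FALSE]
  if (log2_scale) m <- log2(m)
  if (method == "spearman") m <- t(apply(m, 1L, rank))

  standardize <- function(ids) {
    x <- m[ids, , drop = FALSE]
    x <- x - rowMeans(x)
    ss <- sqrt(rowSums(x^2))
    const <- ss == 0
    if (any(const)) {
      warning("skipping constant-expression transcript(s): ",
              paste(utils::head(ids[const], 3), collapse = ", "),
              if (sum(const) > 3) " ..." else "", call. = FALSE)
      x <- x[!const, , drop = FALSE]
      ss <- ss[!const]
    }
    x / ss
  }
  zl <- standardize(unique(lncrna_ids))
  zm <- standardize(unique(mrna_ids))
  if (nrow(zl) == 0L || nrow(zm) == 0L) return(empty())

  rmat <- pmin(pmax(tcrossprod(zl, zm), -1), 1)
  pmat <- matrix(correlation_pvalue(as.vector(rmat), n), nrow = nrow(rmat),
                 dimnames = dimnames(rmat))
  hit <- which(abs(rmat) >= min_abs_r & pmat < max_p, arr.ind = TRUE)
  edges <- data.frame(
    lncrna_id = rownames(rmat)[hit[, 1]],
    mrna_id = colnames(rmat)[hit[, 2]],
    r = rmat[hit],
    p_value = pmat[hit],
    n = rep.int(n, nrow(hit)),
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$lncrna_id, edges$mrna_id), , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(edges = edges,
         lncrna_nodes = sort(unique(edges$lncrna_id)),
         mrna_nodes = sort(unique(edges$mrna_id)),
         thresholds = list(min_abs_r = min_abs_r, max_p = max_p)),
    class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(class(x)[1], ":", length(x$lncrna_nodes), "lncRNA nodes,",
      length(x$mrna_nodes), "mRNA nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}
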