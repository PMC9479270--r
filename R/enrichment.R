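#' Hypergeometric gene-set over-representation test
#'
#' One-sided (over-representation) test per gene set: with a universe of N
#' ids of which K belong to the set, and a query of n ids, the p-value is the
#' upper hypergeometric tail P(X >= k) for the observed overlap k. Query ids
#' outside the universe are dropped with a warning; sets with no member in
#' the universe are skipped. Benjamini-Hochberg q-values are computed across
#' all tested sets.
#'
#' @param query character vector of ids of interest.
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param universe character vector; the background (typically all annotated
#'   transcripts detected on the array).
#' @return Data frame sorted by p-value (ties by set name): `set_name`,
#'   `overlap` (k), `query_size` (n), `set_size` (K), `universe_size` (N),
#'   `p_value`, `q_value`, `overlap_ids` (comma-separated).
#' @export
hypergeom_enrich <- function(query, sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L)
    stop("parameter error: empty universe", call. = FALSE)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning("dropping ", length(outside), " query id(s) outside the universe",
            call. = FALSE)
    query <- intersect(query, universe)
  }
  if (length(query) == 0L)
    stop("parameter error: empty query after universe restriction",
         call. = FALSE)
  n <- length(query)
  N <- length(universe)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(sets[[nm]]), universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    hits <- intersect(query, members)
    k <- length(hits)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, overlap = k, query_size = n, set_size = K,
               universe_size = N, p_value = p,
               overlap_ids = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(set_name = character(), overlap = integer(),
                      query_size = integer(), set_size = integer(),
                      universe_size = integer(), p_value = numeric(),
                      q_value = numeric(), overlap_ids = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set_name),
             c("set_name", "overlap", "query_size", "set_size",
               "universe_size", "p_value", "q_value", "overlap_ids")]
  rownames(out) <- NULL
  out
}
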