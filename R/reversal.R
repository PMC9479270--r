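#' Transcripts whose regulation direction flips between two contrasts
#'
#' Intersects two filtered, directed transcript sets: `up_then_down` collects
#' transcripts Up in the disease contrast and Down in the treatment contrast,
#' `down_then_up` the converse. Transcripts present in only one input, or
#' with direction `None`, are excluded.
#'
#' @param de_disease,de_treated data frames with columns `transcript_id` and
#'   `direction` (typically from [filter_de()]); extra columns
#'   `fc_magnitude` / `p_value` are carried into the per-id records.
#' @return A list of class `reversal_sets`: `up_then_down` and `down_then_up`
#'   (sorted id vectors) and `records`, a data frame with both contrasts'
#'   statistics per reversal transcript (`fc_a`/`p_a` disease contrast,
#'   `fc_b`/`p_b` treatment contrast).
#' @export
reversal_sets <- function(de_disease, de_treated) {
  for (df in list(de_disease, de_treated))
    if (!all(c("transcript_id", "direction") %in% names(df)))
      stop("format error: inputs need transcript_id and direction columns",
           call. = FALSE)
  a <- de_disease[de_disease$direction %in% c("Up", "Down"), , drop = FALSE]
  b <- de_treated[de_treated$direction %in% c("Up", "Down"), , drop = FALSE]
  common <- intersect(a$transcript_id, b$transcript_id)
  dir_a <- a$direction[match(common, a$transcript_id)]
  dir_b <- b$direction[match(common, b$transcript_id)]
  utd <- sort(common[dir_a == "Up" & dir_b == "Down"])
  dtu <- sort(common[dir_a == "Down" & dir_b == "Up"])
  members <- c(utd, dtu)
  grab <- function(df, ids, col) {
    if (col %in% names(df)) df[[col]][match(ids, df$transcript_id)]
    else rep(NA_real_, length(ids))
  }
  records <- data.frame(
    transcript_id = members,
    pattern = rep(c("up_then_down", "down_then_up"),
                  c(length(utd), length(dtu))),
    fc_a = grab(a, members, "fc_magnitude"),
    p_a = grab(a, members, "p_value"),
    fc_b = grab(b, members, "fc_magnitude"),
    p_b = grab(b, members, "p_value"),
    stringsAsFactors = FALSE
  )
  structure(list(up_then_down = utd, down_then_up = dtu, records = records),
            class = "reversal_sets")
}

#' @export
print.reversal_sets <- function(x, ...) {
  cat("reversal_sets:", length(x$up_then_down), "up-then-down,",
      length(x$down_then_up), "down-then-up\n")
  invisible(x)
}

#' Reversal counts per pattern and biotype
#'
#' @param reversal a [reversal_sets()] object.
#' @param annotation per-transcript annotation with `transcript_id` and
#'   `biotype`, or NULL to count without biotype stratification.
#' @param biotype optionally restrict totals to one biotype.
#' @return A list: `up_then_down`, `down_then_up`, `total`, and (if
#'   annotation is given) `by_biotype`, a table of pattern x biotype counts.
#' @export
reversal_counts <- function(reversal, annotation = NULL, biotype = NULL) {
  stopifnot(inherits(reversal, "reversal_sets"))
  rec <- reversal$records
  if (!is.null(annotation)) {
    bt <- annotation$biotype[match(rec$transcript_id,
                                   annotation$transcript_id)]
    if (anyNA(bt))
      stop("data error: reversal transcript missing annotation", call. = FALSE)
    if (!is.null(biotype)) rec <- rec[bt == biotype, , drop = FALSE]
  }
  utd <- sum(rec$pattern == "up_then_down")
  dtu <- sum(rec$pattern == "down_then_up")
  out <- list(up_then_down = utd, down_then_up = dtu, total = utd + dtu)
  if (!is.null(annotation) && is.null(biotype)) {
    bt <- annotation$biotype[match(reversal$records$transcript_id,
                                   annotation$transcript_id)]
    out$by_biotype <- table(pattern = reversal$records$pattern, biotype = bt)
  }
  out
}

#' Reversal sets from the bundled 33-lncRNA table
#'
#' Reinterprets the packaged reversal table's regulation columns as two
#' directed sets and runs [reversal_sets()] on them, so the printed table's
#' bookkeeping (27 up-then-down, 6 down-then-up) is reproduced by the same
#' code path used for new data.
#'
#' @param tbl a `reversal_table`; loaded from the package when omitted.
#' @return A `reversal_sets` object.
#' @export
reversal_sets_from_table <- function(tbl = load_reversal_table()) {
  de_a <- data.frame(transcript_id = tbl$transcript_id,
                     direction = tbl$reg_cia_vs_control,
                     fc_magnitude = tbl$fc_cia_vs_control,
                     p_value = tbl$p_cia_vs_control,
                     stringsAsFactors = FALSE)
  de_b <- data.frame(transcript_id = tbl$transcript_id,
                     direction = tbl$reg_bzxd_vs_cia,
                     fc_magnitude = tbl$fc_bzxd_vs_cia,
                     p_value = tbl$p_bzxd_vs_cia,
                     stringsAsFactors = FALSE)
  reversal_sets(de_a, de_b)
}
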