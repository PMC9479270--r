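#' The bundled 33-lncRNA treatment-reversal table
#'
#' Loads the packaged table of 33 lncRNAs whose regulation direction was
#' reversed by treatment in a rat collagen-induced arthritis (CIA) microarray
#' study of the herbal decoction BZXD: significantly up in CIA vs Control and
#' down in BZXD vs CIA (27 transcripts) or the converse (6 transcripts). Each
#' record carries both contrasts' p-values and fold-change magnitudes, the
#' regulation directions, chromosome, strand and genomic-relationship class,
#' transcribed verbatim from the published table (including Unicode minus
#' signs in ids such as `uc.361−`; see [canonical_id()]).
#'
#' @param check_integrity verify the file checksum before parsing.
#' @return Data frame of class `reversal_table` with 33 rows and columns
#'   `transcript_id`, `p_cia_vs_control`, `p_bzxd_vs_cia`,
#'   `fc_cia_vs_control`, `fc_bzxd_vs_cia`, `reg_cia_vs_control`,
#'   `reg_bzxd_vs_cia`, `chromosome`, `strand`, `relationship`, in the
#'   printed order.
#' @export
load_reversal_table <- function(check_integrity = TRUE) {
  path <- reversal_table_path()
  if (check_integrity) {
    sum <- unname(tools::md5sum(path))
    if (!identical(sum, .reversal_table_md5))
      stop("integrity error: reversal table fixture checksum mismatch (",
           sum, ")", call. = FALSE)
  }
  tbl <- read_tsv(path)
  stopifnot(
    nrow(tbl) == 33L,
    all(tbl$fc_cia_vs_control >= 2), all(tbl$fc_bzxd_vs_cia >= 2),
    all(tbl$p_cia_vs_control >= 0 & tbl$p_cia_vs_control <= 1),
    all(tbl$p_bzxd_vs_cia >= 0 & tbl$p_bzxd_vs_cia <= 1),
    all(tbl$reg_cia_vs_control != tbl$reg_bzxd_vs_cia)
  )
  class(tbl) <- c("reversal_table", "data.frame")
  tbl
}

.reversal_table_md5 <- "75ae19b043d3d5137e6c02b40efa852b"

#' Path of the packaged reversal table
#' @return File path of the TSV fixture.
#' @export
reversal_table_path <- function() {
  system.file("extdata", "reversal_lncrnas_33.tsv", package = "reversalnet",
              mustWork = TRUE)
}

#' Canonical transcript id
#'
#' The published table prints trailing Unicode minus signs in some ids
#' (`uc.361−`). For copy-paste robustness an ASCII hyphen alias is accepted
#' anywhere ids are matched; this helper maps the ASCII form to the printed
#' form.
#'
#' @param id character vector of transcript ids.
#' @return ids with a trailing ASCII `-` replaced by Unicode minus.
#' @export
canonical_id <- function(id) {
  sub("-$", "\u2212", id)
}

#' Look up one record of the reversal table
#' @param tbl a `reversal_table` from [load_reversal_table()].
#' @param id transcript id (ASCII hyphen alias accepted).
#' @return One-row data frame.
#' @export
reversal_record <- function(tbl, id) {
  hit <- tbl[tbl$transcript_id == canonical_id(id), , drop = FALSE]
  if (nrow(hit) != 1L)
    stop("no such transcript in the reversal table: ", id, call. = FALSE)
  hit
}
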