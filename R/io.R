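#' Write an expression study to three TSV files
#'
#' The matrix TSV has `transcript_id` as its first column and one column per
#' sample; the metadata TSV has `sample_id`, `group`, `replicate`; the
#' annotation TSV carries the per-transcript annotation. Plain tab-separated
#' text, decimal point, no quoting.
#'
#' @param study an `expression_study`.
#' @param matrix_path,metadata_path,annotation_path output file paths.
#' @return Invisibly, the three paths.
#' @export
write_expression_study <- function(study, matrix_path, metadata_path,
                                   annotation_path) {
  mat <- data.frame(transcript_id = rownames(study$matrix), study$matrix,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(mat, matrix_path)
  write_tsv(study$samples, metadata_path)
  write_tsv(study$annotation, annotation_path)
  invisible(c(matrix_path, metadata_path, annotation_path))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", check.names = FALSE,
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8", ...)
}

#' Read an expression study from TSV files
#'
#' Inverse of [write_expression_study()]; validates all study invariants
#' (unique ids, strictly positive intensities, three groups with >= 2
#' replicates, matrix/metadata agreement). Samples are ordered as in the
#' metadata file.
#'
#' @param matrix_path,metadata_path,annotation_path input file paths.
#' @return An `expression_study`.
#' @export
read_expression_study <- function(matrix_path, metadata_path,
                                  annotation_path) {
  mat_df <- read_tsv(matrix_path)
  if (names(mat_df)[1] != "transcript_id")
    stop("format error: matrix file must start with a transcript_id column",
         call. = FALSE)
  meta <- read_tsv(metadata_path)
  ann <- read_tsv(annotation_path)
  if (!"sample_id" %in% names(meta))
    stop("format error: metadata missing column sample_id", call. = FALSE)
  sample_cols <- setdiff(names(mat_df), "transcript_id")
  extra <- setdiff(sample_cols, meta$sample_id)
  if (length(extra))
    stop("format error: matrix sample '", extra[1],
         "' absent from metadata", call. = FALSE)
  m <- as.matrix(mat_df[, meta$sample_id, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(mat_df[meta$sample_id], is.numeric, logical(1)))[1]
    stop("format error: non-numeric intensity in column ",
         meta$sample_id[bad], call. = FALSE)
  }
  rownames(m) <- mat_df$transcript_id
  expression_study(m, meta, ann)
}

#' Write a co-expression network edge list
#'
#' @param network a `coexpression_network` (or sub-network).
#' @param path output file path.
#' @param dialect `"TSV"` writes columns lncrna_id, mrna_id, r, p_value, n
#'   (r and p with 6 significant digits); `"SIF"` writes Cytoscape simple
#'   interaction lines `lncrna_id coexp_pos|coexp_neg mrna_id`.
#' @return Invisibly, the path.
#' @export
write_edge_list <- function(network, path, dialect = c("TSV", "SIF")) {
  dialect <- match.arg(dialect)
  e <- network$edges
  if (dialect == "SIF") {
    lines <- if (nrow(e)) paste(e$lncrna_id,
                                ifelse(e$r >= 0, "coexp_pos", "coexp_neg"),
                                e$mrna_id, sep = "\t") else character()
    writeLines(lines, path, useBytes = FALSE)
  } else {
    out <- data.frame(lncrna_id = e$lncrna_id, mrna_id = e$mrna_id,
                      r = signif(e$r, 6), p_value = signif(e$p_value, 6),
                      n = e$n, stringsAsFactors = FALSE)
    write_tsv(out, path)
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields `name`, `description`,
#' then member ids. Duplicate members within a line are dropped.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (set name -> member ids).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop("format error: GMT line ", i, " has fewer than 3 fields",
           call. = FALSE)
    sets[[fields[1]]] <- unique(fields[-(1:2)])
  }
  sets
}

#' Write / read planted ground truth
#'
#' Serialized as a TSV of (role, id, partner_id, sign): roles
#' `reversal_lncrna`, `reversal_mrna`, `edge`, `de_disease_<dir>`,
#' `de_treated_<dir>`.
#'
#' @param truth a `planted_truth` list from [simulate_study()].
#' @param path file path.
#' @return Invisibly, the path (writer) or the `planted_truth` (reader).
#' @export
write_planted_truth <- function(truth, path) {
  role_rows <- function(role, id, partner = NA_character_, sign = NA_real_) {
    if (!length(id)) return(NULL)
    data.frame(role = role, id = id, partner_id = partner, sign = sign,
               stringsAsFactors = FALSE)
  }
  rows <- rbind(
    role_rows("reversal_lncrna", truth$reversal_lncrna),
    role_rows("reversal_mrna", truth$reversal_mrna),
    role_rows("edge", truth$planted_edges$lncrna_id,
              truth$planted_edges$mrna_id, truth$planted_edges$sign),
    role_rows(paste0("de_disease_", truth$de_disease$direction),
              truth$de_disease$transcript_id),
    role_rows(paste0("de_treated_", truth$de_treated$direction),
              truth$de_treated$transcript_id)
  )
  if (is.null(rows))
    rows <- data.frame(role = character(), id = character(),
                       partner_id = character(), sign = numeric(),
                       stringsAsFactors = FALSE)
  write_tsv(rows, path)
  invisible(path)
}

#' @rdname write_planted_truth
#' @export
read_planted_truth <- function(path) {
  rows <- read_tsv(path)
  pick <- function(role) rows$id[rows$role == role]
  dir_df <- function(prefix) {
    sel <- startsWith(rows$role, prefix)
    data.frame(transcript_id = rows$id[sel],
               direction = sub(prefix, "", rows$role[sel], fixed = TRUE),
               stringsAsFactors = FALSE)
  }
  ed <- rows[rows$role == "edge", , drop = FALSE]
  truth <- list(
    de_disease = dir_df("de_disease_"),
    de_treated = dir_df("de_treated_"),
    reversal_lncrna = pick("reversal_lncrna"),
    reversal_mrna = pick("reversal_mrna"),
    planted_edges = data.frame(lncrna_id = ed$id, mrna_id = ed$partner_id,
                               sign = ed$sign, stringsAsFactors = FALSE)
  )
  class(truth) <- "planted_truth"
  truth
}
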