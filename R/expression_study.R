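#' Construct and validate an expression study
#'
#' The substrate of every pipeline stage: a transcript-by-sample matrix of
#' strictly positive linear-scale intensities, a sample table assigning each
#' array to one of three groups, and a per-transcript annotation.
#'
#' @param matrix numeric matrix, transcripts x samples, with row names
#'   (transcript ids) and column names (sample ids); linear scale, > 0.
#' @param samples data frame with columns `sample_id`, `group`, `replicate`;
#'   sample order defines the column order of the matrix.
#' @param annotation data frame with columns `transcript_id`, `biotype`
#'   (`lncRNA` or `mRNA`), `chromosome`, `strand` (`+`/`-`), `length_nt`,
#'   `relationship`.
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(matrix, samples, annotation) {
  obj <- structure(list(matrix = matrix, samples = samples,
                        annotation = annotation),
                   class = "expression_study")
  validate_study(obj)
}

validate_study <- function(study) {
  m <- study$matrix
  s <- study$samples
  a <- study$annotation
  if (!is.matrix(m) || !is.numeric(m))
    stop("format error: expression matrix must be a numeric matrix",
         call. = FALSE)
  need_s <- c("sample_id", "group", "replicate")
  miss <- setdiff(need_s, names(s))
  if (length(miss))
    stop("format error: sample table missing column ",
         paste(miss, collapse = ", "), call. = FALSE)
  need_a <- c("transcript_id", "biotype", "chromosome", "strand",
              "length_nt", "relationship")
  miss <- setdiff(need_a, names(a))
  if (length(miss))
    stop("format error: annotation missing column ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(s$sample_id))
    stop("format error: duplicate sample_id ",
         s$sample_id[duplicated(s$sample_id)][1], call. = FALSE)
  if (anyDuplicated(a$transcript_id))
    stop("format error: duplicate transcript_id ",
         a$transcript_id[duplicated(a$transcript_id)][1], call. = FALSE)
  if (!identical(colnames(m), s$sample_id))
    stop("format error: matrix columns do not match sample table",
         call. = FALSE)
  if (!all(rownames(m) %in% a$transcript_id))
    stop("data error: matrix row without annotation record: ",
         setdiff(rownames(m), a$transcript_id)[1], call. = FALSE)
  if (anyNA(m) || any(m <= 0))
    stop("data error: intensities must be strictly positive", call. = FALSE)
  if (length(unique(s$group)) != 3L)
    stop("format error: unknown group -- a three-group design is required, ",
         "got groups: ", paste(unique(s$group), collapse = ", "),
         call. = FALSE)
  if (any(table(s$group) < 2L))
    stop("design error: each group needs >= 2 replicates", call. = FALSE)
  invisible(study)
}

#' @export
print.expression_study <- function(x, ...) {
  bt <- table(x$annotation$biotype[match(rownames(x$matrix),
                                         x$annotation$transcript_id)])
  cat("expression_study:", nrow(x$matrix), "transcripts x",
      ncol(x$matrix), "samples\n")
  cat("  groups:", paste(unique(x$samples$group), collapse = ", "), "\n")
  cat("  biotypes:", paste(names(bt), bt, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Log2-transformed expression matrix of a study
#' @param study an `expression_study`.
#' @return numeric matrix of log2 intensities.
#' @export
log2_matrix <- function(study) {
  log2(study$matrix)
}

#' Sample ids belonging to one group
#' @param study an `expression_study`.
#' @param group group label.
#' @return character vector of sample ids.
#' @export
group_samples <- function(study, group) {
  if (!group %in% study$samples$group)
    stop("design error: group '", group, "' not present in the study",
         call. = FALSE)
  study$samples$sample_id[study$samples$group == group]
}
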