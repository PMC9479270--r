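#' Configuration for the end-to-end pipeline
#'
#' One object drives the full chain simulate (or load) -> differential
#' expression -> reversal intersection -> key-lncRNA selection -> bipartite
#' co-expression network -> core-mRNA sub-network -> optional enrichment.
#' A single `seed` governs every stochastic stage.
#'
#' @param out_dir directory for all stage outputs (created if absent).
#' @param sim a [sim_config()] used when no study paths are given.
#' @param study_paths optional named list (`matrix`, `metadata`,
#'   `annotation`) of TSV paths to load a study instead of simulating.
#' @param thresholds a [de_thresholds()].
#' @param min_abs_r,max_p co-expression edge thresholds.
#' @param k_key_lncrna how many key lncRNAs to select by treatment-contrast
#'   fold change (capped at the number of reversal lncRNAs found).
#' @param key_lncrna_ids explicit key lncRNA ids, overriding the fold-change
#'   ranking.
#' @param gmt_path optional GMT file; when given, the core mRNAs are tested
#'   for over-representation against all annotated mRNAs.
#' @param seed integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            sim = sim_config(),
                            study_paths = NULL,
                            thresholds = de_thresholds(),
                            min_abs_r = 0.98, max_p = 0.05,
                            k_key_lncrna = 9L,
                            key_lncrna_ids = NULL,
                            gmt_path = NULL,
                            seed = 1L) {
  if (min_abs_r < 0 || min_abs_r > 1)
    stop("invalid configuration: `min_abs_r` must be in [0, 1]", call. = FALSE)
  if (max_p <= 0 || max_p > 1)
    stop("invalid configuration: `max_p` must be in (0, 1]", call. = FALSE)
  if (k_key_lncrna < 0)
    stop("invalid configuration: `k_key_lncrna` must be >= 0", call. = FALSE)
  structure(list(out_dir = out_dir, sim = sim, study_paths = study_paths,
                 thresholds = thresholds, min_abs_r = min_abs_r,
                 max_p = max_p, k_key_lncrna = as.integer(k_key_lncrna),
                 key_lncrna_ids = key_lncrna_ids, gmt_path = gmt_path,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' Recognised keys mirror the arguments of [pipeline_config()]; `sim` and
#' `thresholds` may be nested objects with the corresponding constructor
#' arguments.
#'
#' @param path JSON file.
#' @param out_dir output directory (overrides the file's `out_dir` if given).
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_json <- function(path, out_dir = NULL) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("out_dir", "sim", "thresholds", "min_abs_r", "max_p",
             "k_key_lncrna", "key_lncrna_ids", "gmt_path", "seed",
             "study_paths")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("invalid configuration: unknown key(s) ",
         paste(unknown, collapse = ", "), call. = FALSE)
  args <- raw
  if (!is.null(raw$sim)) args$sim <- do.call(sim_config, as.list(raw$sim))
  if (!is.null(raw$thresholds))
    args$thresholds <- do.call(de_thresholds, as.list(raw$thresholds))
  if (!is.null(out_dir)) args$out_dir <- out_dir
  do.call(pipeline_config, args)
}

#' Run the full pipeline
#'
#' Executes every stage in order, writes all stage TSV/SIF outputs plus a
#' machine-readable JSON summary under `cfg$out_dir`, and returns the stage
#' objects. Identical configuration and seed reproduce identical outputs.
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return Invisibly, a list of class `pipeline_report`: `summary` (named
#'   counts), `files` (paths written), and the stage objects (`study`,
#'   `truth`, `de`, `reversal`, `key_lncrnas`, `network`, `subnetwork`,
#'   `enrichment`).
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  say <- function(...) if (!quiet) message("[reversalnet] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline aborted at stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  out <- function(name) file.path(cfg$out_dir, name)

  # --- input -----------------------------------------------------------
  truth <- NULL
  if (is.null(cfg$study_paths)) {
    sim_cfg <- cfg$sim
    sim_cfg$seed <- cfg$seed
    res <- stage("simulate", simulate_study(sim_cfg))
    study <- res$study
    truth <- res$truth
    stage("simulate", {
      write_expression_study(study, out("matrix.tsv"), out("samples.tsv"),
                             out("annotation.tsv"))
      write_planted_truth(truth, out("planted_truth.tsv"))
    })
    files <- c(files, out("matrix.tsv"), out("samples.tsv"),
               out("annotation.tsv"), out("planted_truth.tsv"))
    say("simulated study: ", nrow(study$matrix), " transcripts x ",
        ncol(study$matrix), " samples")
  } else {
    study <- stage("load", read_expression_study(cfg$study_paths$matrix,
                                                 cfg$study_paths$metadata,
                                                 cfg$study_paths$annotation))
    say("loaded study: ", nrow(study$matrix), " transcripts")
  }
  groups <- unique(study$samples$group)

  # --- differential expression ----------------------------------------
  ct_a <- contrast(groups[2], groups[1])  # disease vs control
  ct_b <- contrast(groups[3], groups[2])  # treated vs disease
  de <- stage("differential_expression", {
    lapply(list(a = ct_a, b = ct_b), function(ct) {
      stats <- contrast_statistics(study, ct)
      retained <- filter_de(stats, study, cfg$thresholds)
      stats$q_bh <- stats::p.adjust(stats$p_value, method = "BH")
      stats$retained <- stats$transcript_id %in% retained$transcript_id
      list(contrast = ct, statistics = stats, retained = retained)
    })
  })
  for (nm in names(de)) {
    path <- out(sprintf("de_%s.tsv", gsub(" ", "_", de[[nm]]$contrast$name)))
    write_tsv(de[[nm]]$statistics, path)
    files <- c(files, path)
  }
  say(ct_a$name, ": ", nrow(de$a$retained), " DE transcripts; ",
      ct_b$name, ": ", nrow(de$b$retained))

  # --- reversal intersection ------------------------------------------
  rev <- stage("reversal", reversal_sets(de$a$retained, de$b$retained))
  biotype <- study$annotation$biotype[match(rev$records$transcript_id,
                                            study$annotation$transcript_id)]
  rev_tab <- cbind(rev$records, biotype = biotype)
  write_tsv(rev_tab, out("reversal.tsv"))
  files <- c(files, out("reversal.tsv"))
  say("reversal: ", length(rev$up_then_down), " up-then-down, ",
      length(rev$down_then_up), " down-then-up")

  # --- key lncRNA selection -------------------------------------------
  lnc_records <- rev_tab[rev_tab$biotype == "lncRNA", , drop = FALSE]
  key <- stage("key_lncrna_selection", {
    if (!is.null(cfg$key_lncrna_ids)) cfg$key_lncrna_ids
    else if (nrow(lnc_records) == 0L) character()
    else {
      k <- min(cfg$k_key_lncrna, nrow(lnc_records))
      if (k < cfg$k_key_lncrna)
        say("only ", nrow(lnc_records), " reversal lncRNAs available; ",
            "selecting all of them")
      select_key_lncrnas(lnc_records, k, fc_column = "fc_b")
    }
  })
  say("key lncRNAs: ", length(key))

  # --- co-expression network ------------------------------------------
  mrna_ids <- study$annotation$transcript_id[study$annotation$biotype == "mRNA"]
  de_mrna <- intersect(union(de$a$retained$transcript_id,
                             de$b$retained$transcript_id), mrna_ids)
  network <- stage("network",
                   build_network(study, key, de_mrna,
                                 min_abs_r = cfg$min_abs_r,
                                 max_p = cfg$max_p))
  write_edge_list(network, out("edges.tsv"), "TSV")
  write_edge_list(network, out("edges.sif"), "SIF")
  files <- c(files, out("edges.tsv"), out("edges.sif"))
  say("network: ", length(network$lncrna_nodes), " lncRNA x ",
      length(network$mrna_nodes), " mRNA nodes, ", nrow(network$edges),
      " edges")

  # --- core mRNAs and sub-network -------------------------------------
  rev_mrna <- rev_tab$transcript_id[rev_tab$biotype == "mRNA"]
  core <- stage("subnetwork", core_mrnas(rev_mrna, network))
  sub <- stage("subnetwork", induced_subnetwork(network, core))
  write_edge_list(sub, out("sub_edges.tsv"), "TSV")
  write_edge_list(sub, out("sub_edges.sif"), "SIF")
  files <- c(files, out("sub_edges.tsv"), out("sub_edges.sif"))
  say("sub-network: ", length(core), " core mRNAs, ", nrow(sub$edges),
      " edges")

  # --- enrichment (optional) ------------------------------------------
  enrichment <- NULL
  if (!is.null(cfg$gmt_path) && length(core)) {
    enrichment <- stage("enrichment", {
      sets <- read_gmt(cfg$gmt_path)
      hypergeom_enrich(core, sets, universe = mrna_ids)
    })
    write_tsv(enrichment, out("enrichment.tsv"))
    files <- c(files, out("enrichment.tsv"))
    say("enrichment: ", nrow(enrichment), " sets tested")
  }

  summary <- list(
    n_transcripts = nrow(study$matrix),
    n_samples = ncol(study$matrix),
    de_disease = nrow(de$a$retained),
    de_treated = nrow(de$b$retained),
    reversal_up_then_down = length(rev$up_then_down),
    reversal_down_then_up = length(rev$down_then_up),
    reversal_total = length(rev$up_then_down) + length(rev$down_then_up),
    n_key_lncrna = length(key),
    network_lncrna_nodes = length(network$lncrna_nodes),
    network_mrna_nodes = length(network$mrna_nodes),
    network_edges = nrow(network$edges),
    core_mrnas = length(core),
    subnetwork_edges = nrow(sub$edges),
    seed = cfg$seed
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, out("summary.json"))

  report <- list(summary = summary, files = files, study = study,
                 truth = truth, de = de, reversal = rev, key_lncrnas = key,
                 network = network, subnetwork = sub,
                 enrichment = enrichment)
  class(report) <- "pipeline_report"
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  for (nm in names(x$summary))
    cat(sprintf("  %-24s %s\n", nm, x$summary[[nm]]))
  invisible(x)
}
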