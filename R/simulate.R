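#' Simulation settings for a three-group microarray study
#'
#' Builds the configuration for [simulate_study()]. The defaults emulate a
#' 3-group x 4-replicate one-colour microarray design (12 arrays) carrying
#' roughly 1e4 lncRNA and 2e4 mRNA probes, with planted treatment-reversal
#' effects (fold change 4 in the disease contrast, pushed back past baseline
#' by the treatment) and planted high-correlation lncRNA-mRNA modules.
#'
#' Each planted key lncRNA drives a co-expression module: the lncRNA and its
#' `targets_per_lncrna` mRNA targets share one latent per-sample profile
#' (group effect + per-sample biological variation of sd `latent_log2_sd`)
#' plus independent residual noise of sd `coupling_sd`, so module members are
#' near-perfectly correlated across all samples while transcripts in
#' different modules are not. `n_reversal_mrna` additional standalone mRNAs
#' carry a reversal pattern of their own without belonging to any module.
#'
#' @param n_lncrna,n_mrna number of lncRNA / mRNA probes.
#' @param n_replicates replicates per group.
#' @param groups ordered labels: control, disease, treated.
#' @param baseline_log2_mean,baseline_log2_sd log2 baseline intensity
#'   distribution across transcripts. The default baseline (2^10 = 1024)
#'   keeps ordinary transcripts well above a raw-intensity filter of 200.
#' @param noise_log2_sd replicate (measurement) noise, log2 scale.
#' @param n_reversal_lncrna number of planted key lncRNAs (each gets a
#'   reversal pattern and a co-expression module).
#' @param n_reversal_mrna number of standalone planted reversal mRNAs.
#' @param planted_fc_range magnitude range (>= 1) of the planted disease
#'   fold change; the treated group overshoots baseline in the opposite
#'   direction by half the disease effect (log2 scale).
#' @param targets_per_lncrna mRNA targets co-driven with each key lncRNA.
#' @param coupling_sd residual log2 noise of a module member around the
#'   shared latent profile.
#' @param latent_log2_sd per-sample biological variability of a module
#'   latent profile (and of standalone reversal mRNAs). This is what makes
#'   co-driven pairs separable from merely co-differential transcripts by
#'   pooled-sample correlation.
#' @param low_intensity_fraction fraction of unplanted transcripts simulated
#'   at low intensity (raw mean ~ 64), to exercise the raw-intensity filter.
#' @param long_fraction fraction of unplanted transcripts with length >= 3 kb,
#'   to exercise the RNA-length filter.
#' @param seed integer seed; identical config (same seed) reproduces the
#'   study bit-for-bit.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_lncrna = 10000L,
                       n_mrna = 20000L,
                       n_replicates = 4L,
                       groups = c("Control", "CIA", "BZXD"),
                       baseline_log2_mean = 10,
                       baseline_log2_sd = 1.5,
                       noise_log2_sd = 0.1,
                       n_reversal_lncrna = 9L,
                       n_reversal_mrna = 25L,
                       planted_fc_range = c(4, 4),
                       targets_per_lncrna = 15L,
                       coupling_sd = 0.05,
                       latent_log2_sd = 0.5,
                       low_intensity_fraction = 0.05,
                       long_fraction = 0.05,
                       seed = 1L) {
  cfg <- list(
    n_lncrna = as.integer(n_lncrna), n_mrna = as.integer(n_mrna),
    n_replicates = as.integer(n_replicates), groups = as.character(groups),
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd, noise_log2_sd = noise_log2_sd,
    n_reversal_lncrna = as.integer(n_reversal_lncrna),
    n_reversal_mrna = as.integer(n_reversal_mrna),
    planted_fc_range = as.numeric(planted_fc_range),
    targets_per_lncrna = as.integer(targets_per_lncrna),
    coupling_sd = coupling_sd, latent_log2_sd = latent_log2_sd,
    low_intensity_fraction = low_intensity_fraction,
    long_fraction = long_fraction, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk_count <- function(field) {
    v <- cfg[[field]]
    if (length(v) != 1L || is.na(v) || v < 0L)
      stop("invalid configuration: `", field, "` must be a single count >= 0",
           call. = FALSE)
  }
  for (f in c("n_lncrna", "n_mrna", "n_replicates", "n_reversal_lncrna",
              "n_reversal_mrna", "targets_per_lncrna"))
    chk_count(f)
  chk_sd <- function(field) {
    v <- cfg[[field]]
    if (length(v) != 1L || is.na(v) || v < 0)
      stop("invalid configuration: `", field, "` must be >= 0", call. = FALSE)
  }
  for (f in c("baseline_log2_sd", "noise_log2_sd", "coupling_sd",
              "latent_log2_sd"))
    chk_sd(f)
  if (length(cfg$groups) != 3L || anyDuplicated(cfg$groups))
    stop("invalid configuration: `groups` must be three distinct labels",
         call. = FALSE)
  fr <- cfg$planted_fc_range
  if (length(fr) != 2L || any(is.na(fr)) || fr[1] < 1 || fr[2] < fr[1])
    stop("invalid configuration: `planted_fc_range` must be an increasing ",
         "pair with lower bound >= 1", call. = FALSE)
  if (cfg$n_reversal_lncrna > cfg$n_lncrna)
    stop("invalid configuration: `n_reversal_lncrna` exceeds `n_lncrna`",
         call. = FALSE)
  n_module_mrna <- cfg$n_reversal_lncrna * cfg$targets_per_lncrna
  if (n_module_mrna + cfg$n_reversal_mrna > cfg$n_mrna)
    stop("invalid configuration: `n_reversal_mrna` plus module targets ",
         "exceeds `n_mrna`", call. = FALSE)
  for (f in c("low_intensity_fraction", "long_fraction")) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("invalid configuration: `", f, "` must be in [0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

#' Simulate a three-group expression study with planted ground truth
#'
#' Generates linear-scale intensities for a control / disease / treated
#' design. Intensities are drawn on the log2 scale (Normal baseline + planted
#' group effects + noise) and exponentiated, the standard log-normal
#' microarray intensity model. Planted reversal transcripts are shifted by a
#' factor from `planted_fc_range` in the disease group and past baseline in
#' the opposite direction in the treated group. Unplanted transcripts share
#' one global null distribution with independent replicate noise.
#'
#' @param cfg a [sim_config()] object.
#' @return A list with components `study` (an `expression_study`, see
#'   [expression_study()]) and `truth` (a `planted_truth` list with elements
#'   `de_disease`, `de_treated` (data frames of transcript_id, direction),
#'   `reversal_lncrna`, `reversal_mrna` (id vectors) and `planted_edges`
#'   (data frame of lncrna_id, mrna_id, sign)).
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(cfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  n_rep <- cfg$n_replicates
  n_samp <- 3L * n_rep
  groups <- cfg$groups
  samples <- data.frame(
    sample_id = paste(rep(groups, each = n_rep), seq_len(n_rep), sep = "_"),
    group = rep(groups, each = n_rep),
    replicate = rep(seq_len(n_rep), times = 3L),
    stringsAsFactors = FALSE
  )
  group_of <- samples$group

  lnc_ids <- sprintf("LNC%05d", seq_len(cfg$n_lncrna))
  mrna_ids <- sprintf("MRNA%05d", seq_len(cfg$n_mrna))
  ids <- c(lnc_ids, mrna_ids)
  n_tx <- length(ids)

  # planted layout: key lncRNAs first among lncRNAs; their module targets,
  # then standalone reversal mRNAs, first among mRNAs
  key_lnc <- lnc_ids[seq_len(cfg$n_reversal_lncrna)]
  n_targets <- cfg$n_reversal_lncrna * cfg$targets_per_lncrna
  target_ids <- mrna_ids[seq_len(n_targets)]
  standalone_ids <- mrna_ids[seq_len(cfg$n_reversal_mrna) + n_targets]
  planted_ids <- c(key_lnc, target_ids, standalone_ids)

  baseline <- stats::rnorm(n_tx, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  names(baseline) <- ids
  # planted transcripts come from the expressed bulk of the intensity
  # distribution: a reversal transcript sitting at background would be an
  # artifact of the simulation, not a property of the design
  if (length(planted_ids))
    baseline[planted_ids] <- stats::rnorm(length(planted_ids),
                                          cfg$baseline_log2_mean + 0.5, 1)

  unplanted <- setdiff(ids, planted_ids)
  n_low <- round(cfg$low_intensity_fraction * length(unplanted))
  low_ids <- unplanted[seq_len(n_low)]
  baseline[low_ids] <- stats::rnorm(n_low, 6, 0.5)

  log2m <- matrix(
    baseline + stats::rnorm(n_tx * n_samp, 0, cfg$noise_log2_sd),
    nrow = n_tx, ncol = n_samp, dimnames = list(ids, samples$sample_id)
  )

  draw_log2fc <- function(n) log2(stats::runif(n, cfg$planted_fc_range[1],
                                               cfg$planted_fc_range[2]))
  # the treated group is shifted back past baseline by half the disease
  # effect: regulation reverses (and the treated-vs-disease fold change,
  # 2^(1.5 * effect), clears the filter) without mirroring the disease shift
  pattern_profile <- function(direction, eff_disease, eff_return) {
    # per-sample group offsets: 0 (control), +d*a (disease), -d*c (treated)
    offs <- c(0, direction * eff_disease, -direction * eff_return)
    offs[match(group_of, groups)]
  }

  truth_dir <- function(d) if (d > 0) "Up" else "Down"

  de_disease <- de_treated <- list()
  edges <- list()

  # key lncRNA modules
  if (cfg$n_reversal_lncrna > 0L) {
    dirs <- rep_len(c(1, -1), cfg$n_reversal_lncrna)
    eff_a <- draw_log2fc(cfg$n_reversal_lncrna)
    eff_c <- eff_a / 2
    for (i in seq_len(cfg$n_reversal_lncrna)) {
      latent <- pattern_profile(dirs[i], eff_a[i], eff_c[i]) +
        stats::rnorm(n_samp, 0, cfg$latent_log2_sd)
      lid <- key_lnc[i]
      log2m[lid, ] <- baseline[lid] + latent +
        stats::rnorm(n_samp, 0, cfg$coupling_sd)
      de_disease[[lid]] <- truth_dir(dirs[i])
      de_treated[[lid]] <- truth_dir(-dirs[i])
      if (cfg$targets_per_lncrna > 0L) {
        tix <- (i - 1L) * cfg$targets_per_lncrna + seq_len(cfg$targets_per_lncrna)
        signs <- rep_len(c(1, 1, -1), cfg$targets_per_lncrna)
        for (j in seq_along(tix)) {
          mid <- target_ids[tix[j]]
          log2m[mid, ] <- baseline[mid] + signs[j] * latent +
            stats::rnorm(n_samp, 0, cfg$coupling_sd)
          de_disease[[mid]] <- truth_dir(signs[j] * dirs[i])
          de_treated[[mid]] <- truth_dir(-signs[j] * dirs[i])
          edges[[length(edges) + 1L]] <-
            data.frame(lncrna_id = lid, mrna_id = mid, sign = signs[j],
                       stringsAsFactors = FALSE)
        }
      }
    }
  }

  # standalone reversal mRNAs: own pattern, own biological variation
  if (cfg$n_reversal_mrna > 0L) {
    dirs <- rep_len(c(-1, 1), cfg$n_reversal_mrna)
    eff_a <- draw_log2fc(cfg$n_reversal_mrna)
    eff_c <- eff_a / 2
    for (i in seq_len(cfg$n_reversal_mrna)) {
      mid <- standalone_ids[i]
      log2m[mid, ] <- log2m[mid, ] + pattern_profile(dirs[i], eff_a[i], eff_c[i]) +
        stats::rnorm(n_samp, 0, cfg$latent_log2_sd)
      de_disease[[mid]] <- truth_dir(dirs[i])
      de_treated[[mid]] <- truth_dir(-dirs[i])
    }
  }

  lengths_nt <- round(stats::runif(n_tx, 200, 2800))
  n_long <- round(cfg$long_fraction * length(unplanted))
  long_ids <- unplanted[length(unplanted) - seq_len(n_long) + 1L]
  lengths_nt[match(long_ids, ids)] <- round(stats::runif(n_long, 3000, 9000))

  annotation <- data.frame(
    transcript_id = ids,
    biotype = rep(c("lncRNA", "mRNA"), c(cfg$n_lncrna, cfg$n_mrna)),
    chromosome = sample(paste0("chr", c(1:20, "X")), n_tx, replace = TRUE),
    strand = sample(c("+", "-"), n_tx, replace = TRUE),
    length_nt = lengths_nt,
    relationship = sample(c("Intergenic", "Intronic antisense",
                            "Exon sense-overlapping",
                            "Intron sense-overlapping"),
                          n_tx, replace = TRUE,
                          prob = c(0.7, 0.1, 0.1, 0.1)),
    stringsAsFactors = FALSE
  )

  study <- expression_study(2^log2m, samples, annotation)

  as_directed_df <- function(x) data.frame(
    transcript_id = if (length(x)) names(x) else character(),
    direction = if (length(x)) unlist(x, use.names = FALSE) else character(),
    stringsAsFactors = FALSE
  )
  truth <- list(
    de_disease = as_directed_df(de_disease),
    de_treated = as_directed_df(de_treated),
    reversal_lncrna = key_lnc,
    reversal_mrna = c(target_ids, standalone_ids),
    planted_edges = if (length(edges)) do.call(rbind, edges) else
      data.frame(lncrna_id = character(), mrna_id = character(),
                 sign = numeric(), stringsAsFactors = FALSE)
  )
  class(truth) <- "planted_truth"

  list(study = study, truth = truth)
}
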