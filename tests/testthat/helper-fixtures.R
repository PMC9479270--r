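# small simulated studies used across test files

small_cfg <- function(...) {
  args <- list(n_lncrna = 60L, n_mrna = 200L,
               n_reversal_lncrna = 3L, n_reversal_mrna = 6L,
               targets_per_lncrna = 4L, seed = 11L)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

# a minimal hand-built 3-group study: 4 transcripts x 6 samples
toy_study <- function() {
  m <- rbind(
    T1 = c(8, 8, 2, 2, 4, 4),
    T2 = c(2, 2, 8, 8, 4, 4),
    T3 = c(5, 5, 5, 5, 5, 5),
    T4 = c(100, 110, 400, 410, 90, 95)
  )
  samples <- data.frame(
    sample_id = c("c1", "c2", "d1", "d2", "t1", "t2"),
    group = rep(c("Control", "CIA", "BZXD"), each = 2),
    replicate = rep(1:2, 3), stringsAsFactors = FALSE
  )
  colnames(m) <- samples$sample_id
  ann <- data.frame(
    transcript_id = rownames(m),
    biotype = c("lncRNA", "lncRNA", "mRNA", "mRNA"),
    chromosome = "chr1", strand = "+", length_nt = 500L,
    relationship = "Intergenic", stringsAsFactors = FALSE
  )
  expression_study(m, samples, ann)
}

# independently coded Welch t p-value (plain transcription of the formula)
oracle_welch_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x); v2 <- var(y)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * pt(-abs(t), df)
}

# independently coded Pearson r via the covariance formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  (sum(x * y) / n - mean(x) * mean(y)) /
    sqrt((sum(x^2) / n - mean(x)^2) * (sum(y^2) / n - mean(y)^2))
}

# exhaustive hypergeometric upper tail P(X >= k)
oracle_hyper_tail <- function(k, N, K, n) {
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
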