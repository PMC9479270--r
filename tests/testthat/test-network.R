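test_that("key lncRNAs are the top-k by treatment-contrast fold change", {
  tbl <- load_reversal_table()
  key <- select_key_lncrnas(tbl, 9)
  expect_length(key, 9L)
  expect_equal(key[1], canonical_id("uc.361-"))  # fc 111.56
  fc <- tbl$fc_bzxd_vs_cia[match(key, tbl$transcript_id)]
  expect_true(all(diff(fc) <= 0))                # descending
  # k = all records returns everything, sorted
  all_ids <- select_key_lncrnas(tbl, nrow(tbl))
  expect_setequal(all_ids, tbl$transcript_id)

  toy <- data.frame(transcript_id = c("x", "y", "z"),
                    fc_bzxd_vs_cia = c(5, 2, 9))
  expect_equal(select_key_lncrnas(toy, 2), c("z", "x"))
  expect_error(select_key_lncrnas(toy, 4), "parameter error")
  # ties broken by id ascending
  tie <- data.frame(transcript_id = c("b", "a"), fc_bzxd_vs_cia = c(3, 3))
  expect_equal(select_key_lncrnas(tie, 2), c("a", "b"))
})

test_that("pearson_r matches its defining formula and stats::cor", {
  expect_equal(pearson_r(1:5, 2 * (1:5) + 1), 1)
  expect_equal(pearson_r(1:5, -(1:5)), -1)
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 5)
  expect_equal(pearson_r(x, y), oracle_pearson(x, y), tolerance = 1e-12)
  expect_equal(pearson_r(x, y), cor(x, y), tolerance = 1e-12)
  set.seed(42)
  for (i in 1:20) {
    a <- rnorm(12); b <- rnorm(12)
    expect_equal(pearson_r(a, b), cor(a, b), tolerance = 1e-12)
    # symmetry and affine invariance
    expect_equal(pearson_r(a, b), pearson_r(b, a))
    expect_equal(pearson_r(2 * a + 3, b), pearson_r(a, b), tolerance = 1e-12)
    expect_equal(pearson_r(-2 * a, b), -pearson_r(a, b), tolerance = 1e-12)
  }
  expect_error(pearson_r(1:4, 1:5), "equal length")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  expect_error(pearson_r(rep(1, 5), 1:5), "constant")
})

test_that("correlation p-values follow the t distribution with n-2 df", {
  expect_equal(correlation_pvalue(0, 10), 1)
  expect_equal(correlation_pvalue(1, 12), 0)
  expect_equal(correlation_pvalue(-1, 12), 0)
  # against the t-CDF oracle and stats::cor.test
  for (r in c(0.98, -0.98, 0.5, -0.2, 0.9999)) {
    for (n in c(4, 12, 30)) {
      t_or <- r * sqrt((n - 2) / (1 - r^2))
      expect_equal(correlation_pvalue(r, n), 2 * pt(-abs(t_or), n - 2),
                   tolerance = 1e-10)
    }
  }
  set.seed(7)
  x <- rnorm(12); y <- x + rnorm(12, 0, 0.5)
  ct <- cor.test(x, y)
  expect_equal(correlation_pvalue(cor(x, y), 12), unname(ct$p.value),
               tolerance = 1e-10)
  expect_error(correlation_pvalue(0.5, 2), "n must be >= 3")
})

test_that("at n = 12 the p filter is implied by the r filter", {
  # analytic: |r| = 0.98 at n = 12 already gives p far below 0.05
  expect_lt(correlation_pvalue(0.98, 12), 0.05)
  expect_lt(correlation_pvalue(0.98, 12), 1e-7)
})

test_that("the network is bipartite, orphan-free and threshold-faithful", {
  cfg <- small_cfg(seed = 21L)
  sim <- simulate_study(cfg)
  lnc <- sim$truth$reversal_lncrna
  mr <- sim$study$annotation$transcript_id[
    sim$study$annotation$biotype == "mRNA"][1:80]
  net <- build_network(sim$study, lnc, mr)
  expect_true(all(net$edges$lncrna_id %in% lnc))
  expect_true(all(net$edges$mrna_id %in% mr))
  expect_setequal(net$lncrna_nodes, unique(net$edges$lncrna_id))
  expect_setequal(net$mrna_nodes, unique(net$edges$mrna_id))
  expect_true(all(abs(net$edges$r) >= 0.98))
  expect_true(all(net$edges$p_value < 0.05))
  expect_true(all(net$edges$n == 12L))

  # empty candidate side -> empty network
  empty <- build_network(sim$study, lnc, character())
  expect_equal(nrow(empty$edges), 0L)
  # maximal stringency -> empty or near-empty
  strict <- build_network(sim$study, lnc, mr, min_abs_r = 1)
  expect_lte(nrow(strict$edges), nrow(sim$truth$planted_edges))
})

test_that("planted edges are recovered and decoys rejected", {
  cfg <- small_cfg(n_lncrna = 20L, n_mrna = 260L, n_reversal_lncrna = 3L,
                   targets_per_lncrna = 5L, n_reversal_mrna = 0L)
  sens <- numeric(0); false_rate <- numeric(0)
  for (s in 1:25) {
    cfg$seed <- s
    sim <- simulate_study(cfg)
    decoys <- setdiff(sim$study$annotation$transcript_id[
      sim$study$annotation$biotype == "mRNA"],
      sim$truth$planted_edges$mrna_id)[1:200]
    cand <- c(unique(sim$truth$planted_edges$mrna_id), decoys)
    net <- build_network(sim$study, sim$truth$reversal_lncrna, cand)
    planted <- paste(sim$truth$planted_edges$lncrna_id,
                     sim$truth$planted_edges$mrna_id)
    got <- paste(net$edges$lncrna_id, net$edges$mrna_id)
    sens <- c(sens, mean(planted %in% got))
    n_decoy_pairs <- length(sim$truth$reversal_lncrna) * length(decoys)
    false_rate <- c(false_rate,
                    sum(net$edges$mrna_id %in% decoys) / n_decoy_pairs)
  }
  expect_gte(mean(sens), 0.95)
  expect_lte(mean(false_rate), 0.01)
})

test_that("constant transcripts are skipped with a warning, never an edge", {
  sim <- simulate_study(small_cfg(seed = 2L))
  study <- sim$study
  study$matrix["MRNA00050", ] <- 512
  lnc <- sim$truth$reversal_lncrna
  expect_warning(
    net <- build_network(study, lnc, c("MRNA00050", "MRNA00051")),
    "constant")
  expect_false("MRNA00050" %in% net$mrna_nodes)
})
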