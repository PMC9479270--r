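test_that("identical config and seed reproduce the study bit-for-bit", {
  cfg <- small_cfg()
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$study$matrix, b$study$matrix)
  expect_identical(a$study$annotation, b$study$annotation)
  expect_identical(a$truth, b$truth)
  c <- simulate_study(small_cfg(seed = 12L))
  expect_false(identical(a$study$matrix, c$study$matrix))
})

test_that("study dimensions and invariants follow the config", {
  cfg <- small_cfg()
  sim <- simulate_study(cfg)
  expect_equal(dim(sim$study$matrix), c(260L, 12L))
  expect_true(all(sim$study$matrix > 0))
  expect_equal(as.vector(table(sim$study$samples$group)[cfg$groups]),
               rep(4L, 3))
  expect_equal(nrow(sim$study$annotation), 260L)
})

test_that("nothing planted means empty truth", {
  sim <- simulate_study(small_cfg(n_reversal_lncrna = 0L,
                                  n_reversal_mrna = 0L))
  expect_equal(nrow(sim$truth$de_disease), 0L)
  expect_equal(length(sim$truth$reversal_lncrna), 0L)
  expect_equal(length(sim$truth$reversal_mrna), 0L)
  expect_equal(nrow(sim$truth$planted_edges), 0L)
})

test_that("planted edge count is forced by the pairing construction", {
  # 9 key lncRNAs x 15 targets each = 135 planted pairs, each lncRNA
  # paired with its own block of consecutive target mRNAs
  cfg <- small_cfg(n_lncrna = 20L, n_mrna = 200L, n_reversal_lncrna = 9L,
                   targets_per_lncrna = 15L, n_reversal_mrna = 0L)
  sim <- simulate_study(cfg)
  expect_equal(nrow(sim$truth$planted_edges), 135L)
  expect_equal(length(unique(sim$truth$planted_edges$lncrna_id)), 9L)
  expect_true(all(table(sim$truth$planted_edges$lncrna_id) == 15L))
  # edges reference ids present in the study
  expect_true(all(c(sim$truth$planted_edges$lncrna_id,
                    sim$truth$planted_edges$mrna_id) %in%
                    rownames(sim$study$matrix)))
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(sim_config(n_lncrna = -1), "n_lncrna")
  expect_error(sim_config(planted_fc_range = c(0.5, 4)), "planted_fc_range")
  expect_error(sim_config(n_reversal_lncrna = 5, n_lncrna = 3),
               "n_reversal_lncrna")
  expect_error(sim_config(noise_log2_sd = -0.1), "noise_log2_sd")
  expect_error(sim_config(groups = c("A", "B")), "groups")
})

test_that("planted disease fold changes land in [2, 8] almost surely", {
  # planted fc 4, noise sd 0.1: empirical two-group fc of planted
  # transcripts should fall within a factor 2 of the planted value
  cfg <- small_cfg(n_lncrna = 30L, n_mrna = 120L, n_reversal_lncrna = 5L,
                   targets_per_lncrna = 3L, n_reversal_mrna = 10L,
                   noise_log2_sd = 0.1)
  inside <- total <- 0
  for (s in 1:60) {
    cfg$seed <- s
    sim <- simulate_study(cfg)
    st <- contrast_statistics(sim$study, contrast("CIA", "Control"))
    planted <- st[st$transcript_id %in% sim$truth$de_disease$transcript_id, ]
    inside <- inside + sum(planted$fc_magnitude >= 2 &
                             planted$fc_magnitude <= 8)
    total <- total + nrow(planted)
  }
  expect_gte(inside / total, 0.99)
})

test_that("planted lncRNA-mRNA pairs correlate above 0.98 almost surely", {
  cfg <- small_cfg(n_lncrna = 10L, n_mrna = 40L, n_reversal_lncrna = 2L,
                   targets_per_lncrna = 5L, n_reversal_mrna = 0L,
                   coupling_sd = 0.05)
  hits <- total <- 0
  for (s in 1:40) {
    cfg$seed <- s
    sim <- simulate_study(cfg)
    lm <- log2(sim$study$matrix)
    ed <- sim$truth$planted_edges
    r <- vapply(seq_len(nrow(ed)), function(i)
      pearson_r(lm[ed$lncrna_id[i], ], lm[ed$mrna_id[i], ]), numeric(1))
    hits <- hits + sum(abs(r) >= 0.98)
    total <- total + nrow(ed)
  }
  expect_gte(hits / total, 0.95)
})
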