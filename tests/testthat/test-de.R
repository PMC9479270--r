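test_that("fold change is the ratio of linear group means with a direction", {
  study <- toy_study()
  res <- contrast_statistics(study, contrast("CIA", "Control"))
  t1 <- res[res$transcript_id == "T1", ]
  expect_equal(t1$fc_magnitude, 4)        # means 2 vs 8
  expect_equal(t1$direction, "Down")
  t2 <- res[res$transcript_id == "T2", ]
  expect_equal(t2$fc_magnitude, 4)
  expect_equal(t2$direction, "Up")
  # identical replicate vectors in both groups: null case
  t3 <- res[res$transcript_id == "T3", ]
  expect_equal(t3$fc_magnitude, 1)
  expect_equal(t3$direction, "None")
  expect_equal(t3$p_value, 1)
})

test_that("Welch p-values agree with independent oracles", {
  a <- c(10.1, 9.9, 10.0, 10.2)
  b <- c(8.0, 8.2, 7.9, 8.1)
  m <- rbind(TX = 2^c(a, b))
  samples <- data.frame(sample_id = paste0("s", 1:8),
                        group = rep(c("A", "B"), each = 4),
                        replicate = c(1:4, 1:4))
  # embed in a minimal 3-group study (third group unused by the contrast)
  m <- cbind(m, `s9` = 2^9, `s10` = 2^9.1)
  samples <- rbind(samples, data.frame(sample_id = c("s9", "s10"),
                                       group = "C", replicate = 1:2))
  colnames(m) <- samples$sample_id
  ann <- data.frame(transcript_id = "TX", biotype = "mRNA",
                    chromosome = "chr1", strand = "+", length_nt = 500L,
                    relationship = "Intergenic")
  study <- expression_study(m, samples, ann)
  res <- contrast_statistics(study, contrast("A", "B"))
  expect_equal(res$p_value, oracle_welch_p(a, b), tolerance = 1e-12)
  expect_equal(res$p_value, t.test(a, b)$p.value, tolerance = 1e-12)
  # pooled-variance option against the Student oracle
  res_p <- contrast_statistics(study, contrast("A", "B"), pooled_var = TRUE)
  expect_equal(res_p$p_value, t.test(a, b, var.equal = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("contrast statistics are antisymmetric and scale equivariant", {
  sim <- simulate_study(small_cfg())
  fwd <- contrast_statistics(sim$study, contrast("CIA", "Control"))
  rev <- contrast_statistics(sim$study, contrast("Control", "CIA"))
  expect_equal(fwd$fc_magnitude, rev$fc_magnitude, tolerance = 1e-12)
  expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-12)
  flip <- c(Up = "Down", Down = "Up", None = "None")
  expect_equal(unname(flip[fwd$direction]), rev$direction)

  # multiplying one transcript by c > 0 changes neither its p nor its fc
  study2 <- sim$study
  study2$matrix[5, ] <- study2$matrix[5, ] * 7.3
  res2 <- contrast_statistics(study2, contrast("CIA", "Control"))
  expect_equal(res2$fc_magnitude[5], fwd$fc_magnitude[5], tolerance = 1e-12)
  expect_equal(res2$p_value[5], fwd$p_value[5], tolerance = 1e-12)
})

test_that("the DE filter applies all four criteria and recovers plantings", {
  # near-noiseless planting: retained set equals the planted set
  cfg <- small_cfg(n_lncrna = 40L, n_mrna = 160L, n_reversal_lncrna = 4L,
                   targets_per_lncrna = 2L, n_reversal_mrna = 0L,
                   noise_log2_sd = 0.05, latent_log2_sd = 0.05,
                   coupling_sd = 0.02, seed = 5L)
  sim <- simulate_study(cfg)
  res <- contrast_statistics(sim$study, contrast("CIA", "Control"))
  kept <- filter_de(res, sim$study, de_thresholds())
  expect_setequal(kept$transcript_id, sim$truth$de_disease$transcript_id)
  expect_equal(kept$direction,
               sim$truth$de_disease$direction[
                 match(kept$transcript_id,
                       sim$truth$de_disease$transcript_id)])

  # empty input
  expect_equal(nrow(filter_de(res[0, ], sim$study, de_thresholds())), 0L)

  # monotone thresholds: raising min_fc or lowering max_p never enlarges
  loose <- filter_de(res, sim$study, de_thresholds(min_fc = 2, max_p = 0.05))
  tight_fc <- filter_de(res, sim$study, de_thresholds(min_fc = 3))
  tight_p <- filter_de(res, sim$study, de_thresholds(max_p = 0.01))
  expect_true(all(tight_fc$transcript_id %in% loose$transcript_id))
  expect_true(all(tight_p$transcript_id %in% loose$transcript_id))
})

test_that("intensity and length filters drop what they should", {
  study <- toy_study()
  res <- contrast_statistics(study, contrast("CIA", "Control"))
  # T4: means 105 vs 405 -> fc ~3.86; max group mean 405 passes 200 floor
  kept <- filter_de(res, study, de_thresholds(max_p = 1))
  expect_true("T4" %in% kept$transcript_id)
  kept2 <- filter_de(res, study, de_thresholds(max_p = 1,
                                               min_raw_intensity = 500))
  expect_false("T4" %in% kept2$transcript_id)
  # length ceiling
  study$annotation$length_nt[study$annotation$transcript_id == "T4"] <- 3500L
  kept3 <- filter_de(res, study, de_thresholds(max_p = 1))
  expect_false("T4" %in% kept3$transcript_id)
})

test_that("the printed table, read as precomputed results, passes the filter", {
  tbl <- load_reversal_table()
  fake_ann <- list(annotation = data.frame(
    transcript_id = tbl$transcript_id, biotype = "lncRNA",
    chromosome = tbl$chromosome, strand = tbl$strand, length_nt = 1000L,
    relationship = tbl$relationship, stringsAsFactors = FALSE))
  as_results <- function(p, fc, reg) data.frame(
    transcript_id = tbl$transcript_id, fc_magnitude = fc, direction = reg,
    p_value = p, mean_numerator = 1000, mean_denominator = 1000,
    stringsAsFactors = FALSE)
  kept_a <- filter_de(as_results(tbl$p_cia_vs_control, tbl$fc_cia_vs_control,
                                 tbl$reg_cia_vs_control), fake_ann)
  kept_b <- filter_de(as_results(tbl$p_bzxd_vs_cia, tbl$fc_bzxd_vs_cia,
                                 tbl$reg_bzxd_vs_cia), fake_ann)
  expect_equal(nrow(kept_a), 33L)
  expect_equal(nrow(kept_b), 33L)
})

test_that("degenerate designs and inputs are rejected", {
  study <- toy_study()
  expect_error(contrast(" CIA", " CIA"))
  expect_error(contrast_statistics(study, contrast("CIA", "Nowhere")),
               "not present")
})
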