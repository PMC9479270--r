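ct_table <- function() {
  # 3 groups x 3 samples, one target gene + U6 reference
  grid <- expand.grid(rep = 1:3, group = c("Control", "CIA", "BZXD"),
                      stringsAsFactors = FALSE)
  data.frame(
    sample_id = paste(grid$group, grid$rep, sep = "_"),
    group = grid$group,
    gene = rep(c("GeneA", "U6"), each = nrow(grid)),
    ct = c(c(24, 24.2, 23.8, 22, 22.1, 21.9, 23, 23.1, 22.9),
           rep(18, nrow(grid)))
  )
}

test_that("the Livak identities hold", {
  # all Ct equal across genes and samples -> every fold = 1
  flat <- ct_table()
  flat$ct <- 20
  rel <- ddct(flat, "U6", "Control")
  expect_true(all(rel$fold == 1))

  # target one cycle above the calibrator mean, reference constant -> 0.5
  one_up <- ct_table()
  one_up$ct[one_up$gene == "GeneA"] <- 24
  one_up$ct[one_up$gene == "GeneA" & one_up$group == "CIA"] <- 25
  rel <- ddct(one_up, "U6", "Control")
  expect_equal(rel$fold[rel$group == "CIA"], rep(0.5, 3))

  # hand-derived case: Ct_gene 24, Ct_ref 18, calibrator dCt mean 7
  tab <- data.frame(
    sample_id = c("c1", "c2", "x1", "c1", "c2", "x1"),
    group = c("Cal", "Cal", "Other", "Cal", "Cal", "Other"),
    gene = rep(c("G", "REF"), each = 3),
    ct = c(25, 25, 24, 18, 18, 18))
  rel <- ddct(tab, "REF", "Cal")
  x1 <- rel[rel$sample_id == "x1", ]
  expect_equal(x1$delta_ct, 6)
  expect_equal(x1$delta_delta_ct, -1)
  expect_equal(x1$fold, 2)
})

test_that("calibrator folds have geometric mean 1 and reference shifts cancel", {
  tab <- ct_table()
  rel <- ddct(tab, "U6", "Control")
  cal <- rel$fold[rel$group == "Control"]
  expect_equal(exp(mean(log(cal))), 1, tolerance = 1e-12)

  # adding a constant to every Ct of one sample leaves all folds unchanged
  shifted <- tab
  pick <- shifted$sample_id == "CIA_2"
  shifted$ct[pick] <- shifted$ct[pick] + 1.7
  rel2 <- ddct(shifted, "U6", "Control")
  expect_equal(rel2$fold, rel$fold, tolerance = 1e-12)
})

test_that("technical replicates are averaged before dCt", {
  tab <- data.frame(
    sample_id = c("c1", "c1", "c2", "x1", "c1", "c2", "x1"),
    group = c("Cal", "Cal", "Cal", "Oth", "Cal", "Cal", "Oth"),
    gene = c("G", "G", "G", "G", "REF", "REF", "REF"),
    ct = c(24, 26, 25, 24, 18, 18, 18))  # c1 technical reps average to 25
  rel <- ddct(tab, "REF", "Cal")
  expect_equal(rel$delta_ct[rel$sample_id == "c1"], 7)
})

test_that("missing reference measurements are reported by sample", {
  tab <- ct_table()
  tab <- tab[!(tab$gene == "U6" & tab$sample_id == "CIA_1"), ]
  expect_error(ddct(tab, "U6", "Control"), "CIA_1")
  expect_error(ddct(ct_table(), "U6", "Nowhere"), "calibrator")
})

test_that("group comparison matches the Student t oracle", {
  rel <- data.frame(
    sample_id = paste0("s", 1:6),
    group = rep(c("A", "B"), each = 3),
    gene = "G",
    delta_ct = 0, delta_delta_ct = 0,
    fold = c(2.0, 2.1, 1.9, 1.0, 1.1, 0.9))
  cmp <- group_compare(rel, "A", "B")
  a <- c(2.0, 2.1, 1.9); b <- c(1.0, 1.1, 0.9)
  # independently coded pooled-variance t
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_or <- (mean(a) - mean(b)) / sqrt(sp2 * (2 / 3))
  expect_equal(cmp$p_value, 2 * pt(-abs(t_or), 4), tolerance = 1e-10)
  expect_equal(cmp$difference, 1, tolerance = 1e-12)

  # identical groups -> no difference, p = 1
  rel$fold <- rep(c(1.5, 1.6, 1.4), 2)
  same <- group_compare(rel, "A", "B")
  expect_equal(same$p_value, 1)
  expect_equal(same$difference, 0)

  # far-separated groups -> tiny p
  rel$fold <- c(10, 10.01, 9.99, 1, 1.01, 0.99)
  far <- group_compare(rel, "A", "B")
  expect_lt(far$p_value, 1e-4)

  expect_error(group_compare(rel[1:4, ], "A", "B"), "design error")
})
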