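clearance_fixture <- function(medians) {
  # three samples per stage so the middle value is the exact median
  meta <- toy_meta(n_per_stage = 3L,
                   stages = c("oocyte_GV", "oocyte_MII", "8cell"))
  expr <- matrix(0, nrow = nrow(medians), ncol = nrow(meta),
                 dimnames = list(rownames(medians), meta$sample_id))
  for (st in colnames(medians)) {
    ids <- meta$sample_id[meta$stage == st]
    for (g in rownames(medians)) {
      m <- medians[g, st]
      expr[g, ids] <- c(m * 0.5, m, m * 2)
    }
  }
  list(expr = expr, meta = meta)
}

test_that("maternal genes need a strict oocyte median above the cut", {
  medians <- matrix(c(3.0, 0.5, 1.0,
                      2.0, 2.0, 1.0,
                      1.0, 2.5, 1.0),
                    nrow = 3, byrow = TRUE,
                    dimnames = list(c("gGV", "gBoundary", "gMII"),
                                    c("oocyte_GV", "oocyte_MII", "8cell")))
  fx <- clearance_fixture(medians)
  mat <- annotate_maternal(fx$expr, fx$meta)
  expect_equal(mat$maternal[match(c("gGV", "gBoundary", "gMII"),
                                  mat$gene_id)],
               c(TRUE, FALSE, TRUE))
  no8 <- fx$meta[fx$meta$stage != "8cell", ]
  expect_error(annotate_maternal(fx$expr, sample_meta(no8)), "8cell")
})

test_that("clearance targets need a strict two-fold oocyte-to-8-cell drop", {
  medians <- matrix(c(4.0, 5.0, 1.5,    # 4.0 > 3.0 -> decay
                      4.0, 5.0, 2.0,    # 4.0 = 4.0 -> others (strict)
                      4.0, 5.0, 0.0,    # zero baseline -> decay
                      1.0, 1.0, 0.1),   # not maternal
                    nrow = 4, byrow = TRUE,
                    dimnames = list(c("gDecay", "gBoundary", "gZero", "gLow"),
                                    c("oocyte_GV", "oocyte_MII", "8cell")))
  fx <- clearance_fixture(medians)
  ann <- annotate_clearance(annotate_maternal(fx$expr, fx$meta))
  got <- ann$clearance_group[match(c("gDecay", "gBoundary", "gZero", "gLow"),
                                   ann$gene_id)]
  expect_equal(got, c("decay_at_8cell", "others", "decay_at_8cell",
                      "not_maternal"))
})

test_that("maternal and clearance annotation are threshold-monotone", {
  set.seed(31)
  medians <- matrix(runif(30, 0, 6), nrow = 10,
                    dimnames = list(sprintf("g%02d", 1:10),
                                    c("oocyte_GV", "oocyte_MII", "8cell")))
  fx <- clearance_fixture(medians)
  m2 <- annotate_maternal(fx$expr, fx$meta, fpkm_cut = 2)
  m4 <- annotate_maternal(fx$expr, fx$meta, fpkm_cut = 4)
  expect_true(all(m2$maternal | !m4$maternal))
  # shrinking every 8-cell value only grows the decay set
  c1 <- annotate_clearance(m2)
  fx_small <- fx
  ids8 <- fx$meta$sample_id[fx$meta$stage == "8cell"]
  fx_small$expr[, ids8] <- fx_small$expr[, ids8] * 0.5
  c2 <- annotate_clearance(annotate_maternal(fx_small$expr, fx$meta))
  expect_true(all(c2$clearance_group[c1$clearance_group == "decay_at_8cell"]
                  == "decay_at_8cell"))
})

test_that("the 2x2 chi-square statistic matches the textbook formula", {
  edits <- data.frame(
    stage = "zygote",
    is_ree = rep(c(TRUE, FALSE), each = 40),
    is_gain = c(rep(TRUE, 30), rep(FALSE, 10), rep(TRUE, 10), rep(FALSE, 30)))
  res <- chi_square_mbs_gain(edits)
  expect_equal(res$statistic, 20)
  flat <- data.frame(stage = "zygote",
                     is_ree = rep(c(TRUE, FALSE), each = 20),
                     is_gain = rep(c(TRUE, FALSE), 20))
  expect_equal(chi_square_mbs_gain(flat)$statistic, 0)
  expect_equal(chi_square_mbs_gain(flat)$p_value, 1)
  degenerate <- data.frame(stage = "zygote", is_ree = TRUE,
                           is_gain = c(TRUE, FALSE))
  expect_equal(chi_square_mbs_gain(degenerate)$note,
               "zero_margin_test_skipped")
})

test_that("chi-square p values are BH-adjusted across the stage family", {
  set.seed(17)
  edits <- do.call(rbind, lapply(c("zygote", "2cell", "4cell"), function(s) {
    data.frame(stage = s, is_ree = rep(c(TRUE, FALSE), each = 50),
               is_gain = sample(c(TRUE, FALSE), 100, replace = TRUE))
  }))
  res <- chi_square_mbs_gain(edits)
  expect_equal(res$p_adjusted, bh_adjust(res$p_value))
  expect_true(all(res$p_adjusted >= res$p_value))
})

test_that("the paired one-tailed test matches exact sign enumeration", {
  res <- wilcoxon_paired_one_tailed(c(2, 3, 4, 5, 6, 7), rep(1, 6))
  expect_equal(res$p_value, 1 / 64)
  # independent enumeration oracle on a mixed-sign fixture
  set.seed(23)
  x <- round(rnorm(12, 0.4), 2)
  y <- round(rnorm(12, 0), 2)
  res2 <- wilcoxon_paired_one_tailed(x, y)
  expect_equal(res2$p_value, oracle_signed_rank_p(x - y), tolerance = 1e-9)
  # degenerate all-zero differences
  res3 <- wilcoxon_paired_one_tailed(1:5, 1:5)
  expect_equal(res3$p_value, 1)
  expect_equal(res3$note, "degenerate_all_differences_zero")
  # invariance under consistent pair reordering
  perm <- sample(12)
  expect_equal(wilcoxon_paired_one_tailed(x[perm], y[perm])$p_value,
               res2$p_value)
})

test_that("the unpaired one-tailed test matches exact rank enumeration", {
  x <- c(11, 12, 13, 14); y <- c(1, 2, 3, 4)
  res <- wilcoxon_unpaired_one_tailed(x, y)
  expect_equal(res$p_value, 1 / 70)   # 1 / choose(8, 4)
  expect_equal(res$p_value, oracle_rank_sum_p(x, y))
  # identical tied groups: no evidence of a shift in either direction
  # (tie handling makes the approximate p sit a little above one half)
  res_flat <- wilcoxon_unpaired_one_tailed(c(2, 3, 4), c(2, 3, 4))
  expect_gte(res_flat$p_value, 0.5)
  expect_lte(res_flat$p_value, 0.75)
  expect_error(wilcoxon_unpaired_one_tailed(numeric(0), y), "empty x")
  expect_error(wilcoxon_unpaired_one_tailed(x, numeric(0)), "empty y")
  # degenerate against-zero baseline mode
  res0 <- wilcoxon_unpaired_one_tailed(c(1, 2, 3, 4), 0)
  expect_equal(res0$test, "wilcoxon_one_sample_vs_zero")
  expect_equal(res0$p_value, 1 / 16)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(41)
  p <- runif(20)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p & adj <= 1))
  expect_equal(order(adj), order(adj[order(p)][rank(p)]))
  # re-adjusting never decreases any value
  expect_true(all(bh_adjust(adj) >= adj))
})

test_that("clearance enrichment compares dense per-pair gain counts", {
  clearance <- data.frame(gene_id = c("gT1", "gT2", "gO1", "gO2"),
                          clearance_group = c("decay_at_8cell",
                                              "decay_at_8cell",
                                              "others", "others"))
  pair_table <- data.frame(gene_id = c("gT1", "gT1", "gT2", "gO1"),
                           sample_id = c("s1", "s2", "s1", "s1"),
                           gains = c(2L, 1L, 1L, 0L))
  res <- clearance_enrichment(pair_table, clearance, c("s1", "s2"))
  expect_equal(res$test, c("wilcoxon_unpaired", "wilcoxon_one_sample_vs_zero"))
  expect_equal(res$n_x[1], 4L)   # dense: 2 target genes x 2 samples
  expect_equal(res$n_y[1], 4L)
  expect_true(res$p_value[1] < 0.5)
})
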