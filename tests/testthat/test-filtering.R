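test_that("substitution classes rotate onto the transcript strand", {
  expect_equal(classify_change("A", "G", "+"),
               data.frame(change = "A-to-G", definiteness = "strand_definite"))
  expect_equal(classify_change("T", "C", "unknown"),
               data.frame(change = "A-to-G/T-to-C",
                          definiteness = "strand_ambiguous"))
  # genomic A-to-G on a minus-strand gene is T-to-C on the transcript
  expect_equal(classify_change("A", "G", "-")$change, "T-to-C")
  expect_equal(classify_change("T", "C", "-")$change, "A-to-G")
  expect_error(classify_change("A", "A", "+"), "differ")
  expect_error(classify_change("A", "N", "+"), "A, C, G or T")
})

test_that("known-variant exclusion is an exact set difference", {
  set.seed(7)
  calls <- edit_calls(data.frame(
    sample_id = "s1", chrom = "chr1", pos = sample(10000L, 100L),
    ref = "A", alt = "G", AC = 2L, AN = 4L))
  planted <- calls[sample(100L, 30L), c("chrom", "pos")]
  kept <- exclude_known_variants(calls, planted)
  expect_equal(nrow(kept), 70L)
  expect_length(intersect(site_key(kept), site_key(planted)), 0L)
  # empty known set: identity
  expect_equal(exclude_known_variants(calls, data.frame(chrom = character(),
                                                        pos = integer())),
               calls)
  # GRanges sets work too
  gr <- GenomicRanges::GRanges(planted$chrom,
                               IRanges::IRanges(planted$pos, planted$pos))
  expect_equal(nrow(exclude_known_variants(calls, gr)), 70L)
})

test_that("per-call filters apply the Alu and non-Alu thresholds", {
  calls <- edit_calls(data.frame(
    sample_id = "s", chrom = "chr1", pos = 1:4, ref = "A", alt = "G",
    AC = c(1L, 0L, 1L, 1L), AN = c(2L, 10L, 10L, 1L)))
  res <- apply_site_filters(calls, is_alu = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res$accept, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$reason,
               c(NA, "low_level", "few_mismatch_reads", "low_coverage"))
})

test_that("per-call acceptance is monotone in the thresholds", {
  set.seed(13)
  calls <- edit_calls(data.frame(
    sample_id = "s", chrom = "chr1", pos = 1:200, ref = "A", alt = "G",
    AN = an <- sample(1:12, 200, replace = TRUE),
    AC = vapply(an, function(x) sample(0:x, 1L), integer(1))))
  alu <- sample(c(TRUE, FALSE), 200, replace = TRUE)
  base <- apply_site_filters(calls, alu)$accept
  for (cfg in list(filter_config(min_coverage = 4L),
                   filter_config(min_editing_level = 0.3),
                   filter_config(min_mismatch_reads_non_alu = 4L))) {
    stricter <- apply_site_filters(calls, alu, cfg)$accept
    expect_true(all(base | !stricter))
  }
})

test_that("support filter needs one Alu sample or two same-stage same-class", {
  meta <- sample_meta(data.frame(
    sample_id = c("n1", "n2", "n3", "a1", "a2"),
    stage = c("zygote", "zygote", "2cell", "zygote", "zygote"),
    condition = c("normal", "normal", "normal", "AG", "PG")))
  alu <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 1999))
  obs <- data.frame(
    chrom = "chr1",
    pos = c(1500L,            # Alu, single sample -> kept
            10L, 10L,          # non-Alu, 2 normal zygotes -> kept
            20L, 20L,          # non-Alu, normal zygote + normal 2cell -> out
            30L, 30L,          # non-Alu, normal + abnormal never pooled -> out
            40L, 40L),         # non-Alu, 2 abnormal same stage -> kept
    sample_id = c("n1", "n1", "n2", "n1", "n3", "n1", "a1", "a1", "a2"))
  sites <- apply_support_filter(obs, meta, alu)
  expect_setequal(sites$pos, c(1500L, 10L, 40L))
  expect_error(apply_support_filter(
    data.frame(chrom = "chr1", pos = 1L, sample_id = "ghost"), meta, alu),
    "unknown sample")
})

test_that("QC metrics count the A-to-G-compatible classes", {
  classes <- rbind(
    classify_change(rep("A", 6), rep("G", 6), "+"),
    classify_change(rep("T", 2), rep("C", 2), "unknown"),
    classify_change(rep("C", 2), rep("T", 2), "+"))
  expect_equal(qc_a2g_proportion(classes), 0.8)
  expect_equal(qc_a2g_proportion(classify_change("A", "G", "+")), 1)
  expect_warning(expect_true(is.nan(qc_a2g_proportion(classes[0, ]))),
                 "empty")
  # permutation invariance
  expect_equal(qc_a2g_proportion(classes[sample(nrow(classes)), ]), 0.8)
})

test_that("Alu ratio and DNA-RNA concordance are plain site fractions", {
  alu <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
  sites <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 500L))
  expect_equal(qc_alu_ratio(sites, alu), 0.75)
  expect_warning(expect_true(is.nan(qc_alu_ratio(sites[0, ], alu))))
  expect_equal(qc_alu_ratio(sites, GenomicRanges::GRanges()), 0)

  rna <- data.frame(chrom = "chr1", pos = c(1L, 2L))
  dna <- data.frame(chrom = "chr1", pos = c(3L, 4L))
  expect_equal(dna_rna_concordance(rna, dna), 0)
  expect_equal(dna_rna_concordance(rna, rna), 1)
  rna$sample_id <- c("s1", "s2")
  per <- dna_rna_concordance(rna, dna)
  expect_equal(unname(per), c(0, 0))
  expect_equal(names(per), c("s1", "s2"))
})

test_that("context profiles are oriented to the edited strand", {
  genome <- toy_genome(c(chr1 = "CATAGGC"))
  sites <- data.frame(chrom = "chr1", pos = 4L, strand = "+")
  prof <- context_profile(sites, genome, flank = 3L)
  expect_equal(prof["T", "-1"], 1)
  expect_equal(prof["G", "1"], 1)
  expect_equal(prof["A", "0"], 1)
  expect_equal(colSums(prof), rep(1, 7), ignore_attr = TRUE)

  # minus-strand: the recorded strand flips the window
  genome2 <- toy_genome(c(chr1 = "GCCTATG"))  # revcomp of CATAGGC
  sites2 <- data.frame(chrom = "chr1", pos = 4L, strand = "-")
  prof2 <- context_profile(sites2, genome2, flank = 3L)
  expect_equal(prof2, prof)

  edge <- data.frame(chrom = "chr1", pos = 1L, strand = "+")
  expect_warning(p <- context_profile(edge, genome, flank = 3L), "skipped")
  expect_equal(attr(p, "n_skipped"), 1L)
})
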