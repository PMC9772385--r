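test_that("family tables enforce the seed definition", {
  fam <- toy_family()
  expect_equal(substr(fam$mature_seq, 2, 8), fam$seed)
  bad <- transform(fam, mature_seq = paste0("TT", fam$seed, "AAAA"))
  expect_error(mirna_families(bad), "positions 2-8")
  expect_error(mirna_families(transform(fam, seed = "GAGGTA")), "7 nucleotides")
  fam_rna <- transform(fam, seed = "GAGGUAG")
  expect_equal(mirna_families(fam_rna)$seed, "GAGGTAG")
})

test_that("seed sites find the canonical site types", {
  seed <- "GAGGTAG"                       # let-7 style; core = TACCTC
  # CTACCTCA: m8 match (C) + core + A1 adenosine -> 8mer
  s <- seed_sites("GGCTACCTCAGG", seed)
  expect_equal(s$site_type, "8mer")
  expect_equal(c(s$start, s$end), c(3L, 10L))
  # drop the A1 adenosine -> 7mer-m8
  s <- seed_sites("GGCTACCTCGGG", seed)
  expect_equal(s$site_type, "7mer-m8")
  expect_equal(c(s$start, s$end), c(3L, 9L))
  # drop the m8 match, keep A1 -> 7mer-A1
  s <- seed_sites("GGTTACCTCAGG", seed)
  expect_equal(s$site_type, "7mer-A1")
  expect_equal(c(s$start, s$end), c(4L, 10L))
  # neither -> 6mer
  s <- seed_sites("GGTTACCTCGGG", seed)
  expect_equal(s$site_type, "6mer")
  expect_equal(c(s$start, s$end), c(4L, 9L))
  # RNA alphabet input works
  expect_equal(seed_sites("GGCUACCUCAGG", "GAGGUAG")$site_type, "8mer")
  expect_equal(nrow(seed_sites("", seed)), 0L)
  expect_equal(nrow(seed_sites(strrep("A", 50), seed)), 0L)
})

test_that("seed sites equal the brute-force window oracle", {
  set.seed(101)
  for (i in 1:50) {
    utr <- random_dna_str(sample(10:200, 1))
    seed <- random_dna_str(7)
    got <- seed_sites(utr, seed)
    want <- oracle_sites(utr, seed)
    expect_equal(nrow(got), length(want))
    if (length(want) > 0) {
      want_df <- do.call(rbind, lapply(want, function(w) {
        data.frame(start = as.integer(w[["start"]]),
                   end = as.integer(w[["end"]]), site_type = w[["type"]])
      }))
      expect_equal(got[, c("start", "end", "site_type")], want_df)
    }
  }
})

test_that("the mature-sequence aligner anchors on exact seed complements", {
  fam <- toy_family()
  mature <- fam$mature_seq[1]
  utr <- paste0("GGG", revcomp_chr_test(mature), "TTT")
  aln <- align_mature(utr, mature, "m1")
  expect_gte(nrow(aln), 1L)
  ss <- seed_sites(utr, fam$seed[1])
  expect_true(all(paste(aln$start, aln$end) %in% paste(ss$start, ss$end)))
  # no seed complement -> no predictions
  expect_equal(nrow(align_mature(strrep("A", 60), mature)), 0L)
  # unreachable minimum score -> no predictions
  sc <- align_scoring(); sc$min_score <- 1e6
  expect_equal(nrow(align_mature(utr, mature, scoring = sc)), 0L)
})

test_that("collapsing unifies predictions by the four-property key", {
  fam <- toy_family(n_matures = 2L)
  preds <- data.frame(
    mature_id = c("let7-m1", "let7-m2", "let7-m1", "let7-m1"),
    utr_id = "u1",
    start = c(3L, 3L, 3L, 10L), end = c(10L, 10L, 9L, 17L),
    site_type = c("8mer", "8mer", "7mer-m8", "8mer"))
  col <- collapse_predictions(preds, fam)
  # two matures, same family/UTR/type/coords -> one prediction;
  # different type and different coords stay distinct
  expect_equal(nrow(col), 3L)
  expect_error(collapse_predictions(transform(preds, mature_id = "ghost"),
                                    fam), "not in any family")
})

test_that("prediction intersection is commutative, idempotent and a subset", {
  a <- data.frame(family_id = "f", utr_id = "u", start = c(1L, 5L, 9L),
                  end = c(6L, 10L, 14L), site_type = "6mer")
  b <- a[2, ]
  ab <- intersect_predictions(a, b)
  expect_equal(nrow(ab), 1L)
  expect_equal(ab$start, 5L)
  expect_equal(intersect_predictions(b, a), ab)
  expect_equal(intersect_predictions(a, a), a)
  expect_equal(nrow(intersect_predictions(a, transform(a, start = start + 1L))),
               0L)
  # intersection route agrees with the seed route on clean sequences
  fam <- toy_family()
  utr <- c(u = paste0("GG", "CTACCTCA", revcomp_chr_test(fam$mature_seq[1])))
  both <- mbs_predictions(utr, fam, predictor = "intersection")
  seed_only <- mbs_predictions(utr, fam, predictor = "seed")
  expect_true(all(paste(both$start, both$end) %in%
                    paste(seed_only$start, seed_only$end)))
})

test_that("apply_edit substitutes exactly one adenosine", {
  expect_equal(apply_edit("CCACC", 3L), "CCGCC")
  expect_error(apply_edit("CCACC", 6L), "out of range")
  expect_error(apply_edit("CCGCC", 3L), "not adenosine")
  expect_equal(apply_edit("ccacc", 3L), "CCGCC")
})

test_that("the five-way cascade follows its clause order", {
  expect_equal(classify_mbs_delta(c(0L, 0L), c(0L, 0L)), "no_overlaps")
  expect_equal(classify_mbs_delta(c(1L, 0L), c(1L, 0L)), "site_unchanged")
  expect_equal(classify_mbs_delta(c(1L, 0L), c(0L, 0L)), "gain")
  expect_equal(classify_mbs_delta(c(0L, 0L), c(1L, 0L)), "lost")
  expect_equal(classify_mbs_delta(c(1L, 0L), c(0L, 1L)), "mixed")
  # overlap without a count change is not "no overlaps"
  expect_equal(classify_mbs_delta(0L, 0L, overlap = TRUE), "site_unchanged")
  expect_error(classify_mbs_delta(c(1L, 0L), 0L), "transcript sets differ")
})

test_that("an edit far from any adenosine window never changes site counts", {
  fam <- toy_family()
  utr <- paste0(strrep("C", 30), "A", strrep("C", 30))
  d <- mbs_transcript_delta(utr, 31L, fam)
  expect_equal(d$introduced, 0L)
  expect_equal(d$removed, 0L)
})

test_that("per-pair tables aggregate observed gains and losses", {
  deltas <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L),
                       gene_id = c("g1", "g1", "g2"),
                       family_id = "f1",
                       classification = c("gain", "lost", "gain"))
  calls <- rbind(obs_calls("chr1", 10L, c("s1", "s2")),
                 obs_calls("chr1", 20L, "s1"),
                 obs_calls("chr1", 30L, "s2"))
  pp <- per_pair_mbs_table(deltas, calls)
  g1s1 <- pp[pp$gene_id == "g1" & pp$sample_id == "s1", ]
  expect_equal(c(g1s1$gains, g1s1$losses, g1s1$net), c(1L, 1L, 0L))
  g1s2 <- pp[pp$gene_id == "g1" & pp$sample_id == "s2", ]
  expect_equal(c(g1s2$gains, g1s2$losses, g1s2$net), c(1L, 0L, 1L))
  expect_equal(nrow(pp[pp$gene_id == "g2" & pp$sample_id == "s1", ]), 0L)
})

test_that("gene-level classification spans transcripts of the locus", {
  # a seed with a C among mature positions 2-7, so its site pattern has a G
  fam <- toy_family(seed = "GACCTAG", family_id = "famC")
  # the 8mer pattern with one G replaced by A: editing completes the site
  pattern <- paste0(revcomp_chr_test(fam$seed), "A")
  chars <- strsplit(pattern, "")[[1]]
  q <- which(chars[1:7] == "G")[1]
  expect_false(is.na(q))
  chars[q] <- "A"
  utr1 <- paste0(strrep("T", 10), paste(chars, collapse = ""),
                 strrep("T", 10))
  edit_pos <- 10L + q
  cls <- classify_edit_mbs(c(t1 = utr1), c(t1 = edit_pos), fam)
  expect_equal(cls$classification, "gain")
  # a second transcript without the edit in its UTR contributes zeros
  cls2 <- classify_edit_mbs(c(t1 = utr1, t2 = strrep("T", 30)),
                            c(t1 = edit_pos, t2 = NA_integer_), fam)
  expect_equal(cls2$classification, "gain")
})
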