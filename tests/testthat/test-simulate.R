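small_design <- function(seed = 5L, ...) {
  cohort_design(seed = seed, stages = c("zygote", "2cell"), n_normal = 4L,
                n_abnormal = 2L, n_genes = 15L, n_rees = 20L, n_noise = 25L,
                n_snps = 5L, dropout = c(AG = 2L, PG = 2L, elder_mother = 0L),
                n_families = 4L, ...)
}

test_that("generation is a pure function of the design", {
  d <- small_design()
  s1 <- simulate_cohort(d)
  s2 <- simulate_cohort(d)
  expect_identical(as.character(s1$reference$genome),
                   as.character(s2$reference$genome))
  expect_identical(as.data.frame(s1$calls), as.data.frame(s2$calls))
  expect_identical(s1$fpkm, s2$fpkm)
  expect_identical(s1$families, s2$families)
  s3 <- simulate_cohort(small_design(seed = 6L))
  expect_false(identical(as.character(s1$reference$genome),
                         as.character(s3$reference$genome)))
})

test_that("designs are validated", {
  expect_error(cohort_design(ree_detect_prob = 1.2))
  d <- small_design()
  d$utr3_len <- c(5L, 8L)
  expect_error(generate_reference(d, generate_families(d)), "infeasible")
})

test_that("families carry unique seeds shared by their matures", {
  d <- small_design()
  fam <- generate_families(d)
  expect_equal(length(unique(fam$seed[!duplicated(fam$family_id)])),
               d$n_families)
  expect_equal(substr(fam$mature_seq, 2, 8), fam$seed)
  expect_identical(fam, generate_families(d))
})

test_that("the reference is internally consistent", {
  d <- small_design()
  sim <- simulate_cohort(d)
  ref <- sim$reference
  expect_equal(nrow(ref$model$genes), d$n_genes)
  # extracted 3'-UTRs equal independent genome slices under the strand rule
  tx <- ref$model$transcripts
  for (i in sample(nrow(tx), 5L)) {
    b <- ref$model$features[ref$model$features$transcript_id ==
                              tx$transcript_id[i] &
                              ref$model$features$type == "UTR3", ]
    slice <- as.character(Biostrings::subseq(ref$genome[[b$chrom[1]]],
                                             min(b$start), max(b$end)))
    if (b$strand[1] == "-") slice <- revcomp_chr_test(slice)
    expect_equal(as.character(ref$utrs[[tx$transcript_id[i]]]), slice)
  }
  # planted A-to-G placements sit on adenosines of the transcript strand
  pl <- ref$placements
  ag <- pl[pl$kind %in% c("ree", "noise"), ]
  expect_true(all(ifelse(ag$strand == "+", ag$ref == "A", ag$ref == "T")))
  expect_true(all(ifelse(ag$strand == "+", ag$alt == "G", ag$alt == "C")))
})

test_that("generated files pass the package's own readers", {
  sim <- simulate_cohort(small_design())
  dir <- withr::local_tempdir()
  write_cohort(sim, dir)
  calls <- read_edit_calls(file.path(dir, "calls.tsv"), "tsv")
  expect_equal(nrow(calls), nrow(sim$calls))
  mask <- read_interval_mask(file.path(dir, "alu.bed"))
  expect_equal(length(mask), length(sim$reference$alu))
  gm <- read_gene_model(file.path(dir, "model.gtf"))
  expect_equal(nrow(gm$genes), nrow(sim$reference$model$genes))
  fam <- read_mirna_families(file.path(dir, "families.tsv"))
  expect_equal(fam$seed, sim$families$seed)
  meta <- read_sample_meta(file.path(dir, "meta.tsv"),
                           stages = sim$design$stages)
  expect_equal(nrow(meta), nrow(sim$meta))
})

test_that("planted calls pass the per-call filters by construction", {
  sim <- simulate_cohort(small_design())
  is_alu <- pos_in_mask(sim$calls$chrom, sim$calls$pos, sim$reference$alu)
  res <- apply_site_filters(sim$calls, is_alu)
  snp_keys <- site_key(sim$snp_positions)
  non_snp <- !(site_key(sim$calls) %in% snp_keys)
  expect_true(all(res$accept[non_snp]))
})

test_that("planted detection frequencies track the design probability", {
  d <- cohort_design(seed = 9L, stages = "zygote", n_normal = 50L,
                     n_abnormal = 2L, n_genes = 20L, n_rees = 40L,
                     n_noise = 10L, n_snps = 0L,
                     dropout = c(AG = 0L, PG = 0L, elder_mother = 0L),
                     n_families = 3L)
  sim <- simulate_cohort(d)
  normal <- sim$meta$sample_id[sim$meta$condition == "normal"]
  calls <- sim$calls[sim$calls$sample_id %in% normal, ]
  active <- sim$truth$rees
  freq <- vapply(seq_len(nrow(active)), function(i) {
    sum(calls$chrom == active$chrom[i] & calls$pos == active$pos[i]) /
      length(normal)
  }, numeric(1))
  # binomial sampling at n = 50: the mean tracks the design probability
  # closely and no site strays far (threshold truncation bounds the left
  # tail at the recurrence fraction)
  expect_lt(abs(mean(freq) - d$ree_detect_prob), 0.1)
  expect_true(all(abs(freq - d$ree_detect_prob) <= 0.2))
})

test_that("dropout edits are absent from their group and present elsewhere", {
  sim <- simulate_cohort(small_design())
  drop <- sim$truth$dropout
  expect_equal(nrow(drop), 4L)
  meta <- sim$meta
  for (i in seq_len(nrow(drop))) {
    grp <- meta$sample_id[meta$stage == drop$stage[i] &
                            meta$condition == drop$condition[i]]
    hits <- sim$calls$sample_id[sim$calls$chrom == drop$chrom[i] &
                                  sim$calls$pos == drop$pos[i]]
    expect_length(intersect(hits, grp), 0L)
    expect_gt(length(hits), 0L)
  }
})

test_that("expression recovers the planted clearance groups exactly", {
  d <- cohort_design(seed = 11L,
                     stages = c("oocyte_GV", "oocyte_MII", "8cell"),
                     n_normal = 6L, n_abnormal = 2L, n_genes = 24L,
                     n_rees = 40L, n_noise = 30L, n_snps = 0L,
                     dropout = c(AG = 0L, PG = 0L, elder_mother = 0L),
                     n_families = 5L)
  sim <- simulate_cohort(d)
  ann <- annotate_clearance(annotate_maternal(sim$fpkm, sim$meta))
  planted <- sim$reference$gene_groups
  expect_equal(ann$clearance_group[match(planted$gene_id, ann$gene_id)],
               planted$group)
})

test_that("editing level couples negatively to target expression", {
  d <- cohort_design(seed = 13L, stages = "zygote", n_normal = 16L,
                     n_abnormal = 2L, n_genes = 20L, n_rees = 30L,
                     n_noise = 10L, n_snps = 0L,
                     dropout = c(AG = 0L, PG = 0L, elder_mother = 0L),
                     n_families = 3L)
  sim <- simulate_cohort(d)
  rees <- sim$truth$rees[!duplicated(sim$truth$rees$gene_id), ]
  gene_map <- rees[, c("chrom", "pos", "gene_id")]
  af <- sim$calls[, c("chrom", "pos", "sample_id", "AF")]
  normal <- sim$meta$sample_id[sim$meta$condition == "normal"]
  res <- ree_expression_correlation(af, sim$fpkm, gene_map, normal)
  expect_lt(median(res$rho, na.rm = TRUE), 0)
})

test_that("the context bias is visible in the planted flanks", {
  d <- cohort_design(seed = 15L, stages = "zygote", n_normal = 4L,
                     n_abnormal = 2L, n_genes = 40L, n_rees = 150L,
                     n_noise = 50L, n_snps = 0L,
                     dropout = c(AG = 0L, PG = 0L, elder_mother = 0L),
                     n_families = 3L)
  fam <- generate_families(d)
  ref <- generate_reference(d, fam)
  pl <- ref$placements
  sites <- pl[pl$kind == "ree" & !pl$is_gain_slot,
              c("chrom", "pos", "strand")]
  prof <- context_profile(sites, ref$genome, flank = 1L)
  expect_lt(prof["G", "-1"], 0.15)   # depleted 5' of the edit
  expect_gt(prof["G", "1"], 0.35)    # enriched 3' of the edit
  expect_equal(prof["A", "0"], 1)
})
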