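#' Annotate maternal genes from expression medians
#'
#' A gene is maternal when its median FPKM over normal samples exceeds 2
#' (strictly) in at least one of the two oocyte stages (germinal vesicle or
#' metaphase II).
#'
#' @param expr numeric matrix, genes x samples (FPKM).
#' @param meta a [sample_meta] table.
#' @param fpkm_cut maternal threshold (default 2).
#' @return data.frame per gene: `gene_id`, `median_GV`, `median_MII`,
#'   `median_8cell`, `maternal`.
#' @export
annotate_maternal <- function(expr, meta, fpkm_cut = 2) {
  needed <- c("oocyte_GV", "oocyte_MII", "8cell")
  stage_samples <- lapply(needed, function(s) {
    ids <- meta$sample_id[meta$stage == s & meta$condition == "normal"]
    ids <- intersect(ids, colnames(expr))
    if (length(ids) == 0L) {
      stop("annotate_maternal: no normal samples with expression for stage ", s)
    }
    ids
  })
  names(stage_samples) <- needed
  med <- vapply(stage_samples, function(ids) {
    apply(expr[, ids, drop = FALSE], 1L, stats::median)
  }, numeric(nrow(expr)))
  out <- data.frame(gene_id = rownames(expr),
                    median_GV = med[, "oocyte_GV"],
                    median_MII = med[, "oocyte_MII"],
                    median_8cell = med[, "8cell"],
                    stringsAsFactors = FALSE)
  out$maternal <- out$median_GV > fpkm_cut | out$median_MII > fpkm_cut
  rownames(out) <- NULL
  out
}

#' Annotate targets of maternal mRNA clearance
#'
#' Among maternal genes, a clearance target ("decay at 8-cell") is one whose
#' smaller oocyte median FPKM (GV vs MII) is strictly more than `fold` times
#' the 8-cell median. Other maternal genes are `others`; non-maternal genes
#' are `not_maternal`.
#'
#' @param maternal output of [annotate_maternal].
#' @param fold decay fold threshold (default 2).
#' @return `maternal` with an added `clearance_group` column.
#' @export
annotate_clearance <- function(maternal, fold = 2) {
  lo <- pmin(maternal$median_GV, maternal$median_MII)
  maternal$clearance_group <- ifelse(
    !maternal$maternal, "not_maternal",
    ifelse(lo > fold * maternal$median_8cell, "decay_at_8cell", "others"))
  maternal
}

test_result <- function(test, group = NA_character_, n_x = NA_integer_,
                        n_y = NA_integer_, statistic = NA_real_,
                        p_value = NA_real_, estimate = NA_real_,
                        conf_low = NA_real_, note = NA_character_) {
  data.frame(test = test, group = group, n_x = as.integer(n_x),
             n_y = as.integer(n_y), statistic = statistic,
             p_value = p_value, p_adjusted = NA_real_, estimate = estimate,
             conf_low = conf_low, note = note, stringsAsFactors = FALSE)
}

#' Per-stage chi-square test for MBS gain vs REE status
#'
#' For each stage, forms the 2x2 table of MBS-overlapping edits partitioned
#' by REE status (REE vs non-REE, disjoint) and MBS-gain status, and tests
#' independence with the plain chi-square statistic (no continuity
#' correction by default). P values are Benjamini-Hochberg-adjusted across
#' the stage family. Stages with a zero margin are reported with a note and
#' no statistic.
#'
#' @param edits data.frame of MBS-overlapping edits with columns `stage`,
#'   `is_ree` (logical), `is_gain` (logical).
#' @param correct continuity correction (default `FALSE`).
#' @return data.frame, one row per stage, in the statistics schema plus a
#'   `note` column.
#' @export
chi_square_mbs_gain <- function(edits, correct = FALSE) {
  stages <- unique(edits$stage)
  rows <- lapply(stages, function(s) {
    e <- edits[edits$stage == s, , drop = FALSE]
    tab <- table(factor(e$is_ree, levels = c(TRUE, FALSE)),
                 factor(e$is_gain, levels = c(TRUE, FALSE)))
    if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
      return(test_result("chi_square_mbs_gain", group = s,
                         n_x = sum(e$is_ree), n_y = sum(!e$is_ree),
                         note = "zero_margin_test_skipped"))
    }
    # the plain statistic is reported regardless of expected-count size;
    # chisq.test's small-count warning is informational here
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    test_result("chi_square_mbs_gain", group = s, n_x = sum(e$is_ree),
                n_y = sum(!e$is_ree), statistic = unname(ct$statistic),
                p_value = ct$p.value,
                estimate = mean(e$is_gain[e$is_ree]) -
                  mean(e$is_gain[!e$is_ree]))
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$p_value)
  out$p_adjusted[ok] <- bh_adjust(out$p_value[ok])
  out
}

#' One-tailed paired Wilcoxon test (signed-rank on differences)
#'
#' The paired comparison of per-(gene, sample) MBS gains against losses:
#' a one-sample Wilcoxon signed-rank test on `x - y` with zero differences
#' dropped, alternative "greater". Exact p values are used for small
#' tie-free samples and the tie-corrected normal approximation otherwise
#' (the standard behaviour of [stats::wilcox.test]). The Hodges-Lehmann
#' pseudomedian and the one-sided lower confidence bound are reported.
#'
#' @param x,y paired numeric vectors (same (gene, sample) pairs).
#' @param alternative alternative hypothesis (default `"greater"`).
#' @return one-row data.frame in the statistics schema.
#' @export
wilcoxon_paired_one_tailed <- function(x, y, alternative = "greater") {
  stopifnot(length(x) == length(y))
  d <- x - y
  if (all(d == 0)) {
    return(test_result("wilcoxon_paired", n_x = length(x), n_y = length(y),
                       statistic = 0, p_value = 1, estimate = 0,
                       note = "degenerate_all_differences_zero"))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                            alternative = alternative,
                                            conf.int = TRUE))
  test_result("wilcoxon_paired", n_x = length(x), n_y = length(y),
              statistic = unname(wt$statistic), p_value = wt$p.value,
              estimate = unname(wt$estimate), conf_low = wt$conf.int[1L])
}

#' One-tailed unpaired Wilcoxon rank-sum test
#'
#' The clearance-enrichment comparison: rank-sum (Mann-Whitney) test of the
#' `x` group against the `y` group with alternative "greater", exact for
#' small tie-free samples and tie-corrected normal approximation otherwise.
#' Reports the Hodges-Lehmann shift estimate and the one-sided lower
#' confidence bound. Passing `y = 0` (scalar) runs the degenerate
#' against-zero-baseline comparison as a one-sample signed-rank test.
#'
#' @param x,y numeric vectors (both nonempty), or scalar `y = 0` for the
#'   baseline mode.
#' @param alternative alternative hypothesis (default `"greater"`).
#' @return one-row data.frame in the statistics schema.
#' @export
wilcoxon_unpaired_one_tailed <- function(x, y, alternative = "greater") {
  if (length(x) == 0L) stop("wilcoxon_unpaired_one_tailed: empty x group")
  if (length(y) == 1L && y == 0) {
    wt <- suppressWarnings(stats::wilcox.test(x, mu = 0,
                                              alternative = alternative,
                                              conf.int = TRUE))
    return(test_result("wilcoxon_one_sample_vs_zero", n_x = length(x),
                       n_y = 0L, statistic = unname(wt$statistic),
                       p_value = wt$p.value, estimate = unname(wt$estimate),
                       conf_low = wt$conf.int[1L]))
  }
  if (length(y) == 0L) stop("wilcoxon_unpaired_one_tailed: empty y group")
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                            conf.int = TRUE))
  test_result("wilcoxon_unpaired", n_x = length(x), n_y = length(y),
              statistic = unname(wt$statistic), p_value = wt$p.value,
              estimate = unname(wt$estimate), conf_low = wt$conf.int[1L])
}

#' Benjamini-Hochberg adjustment of a p-value family
#'
#' Step-up false-discovery-rate adjustment: sorted p values are scaled by
#' m/i, monotonised from the largest rank downwards and capped at 1;
#' returned in the input order.
#'
#' @param pvals numeric vector of raw p values in `[0, 1]`.
#' @return adjusted p values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("bh_adjust: p values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Clearance-enrichment comparison of MBS-gain counts
#'
#' The headline maternal-clearance statistic: per-(gene, sample) counts of
#' MBS-gaining REEs for clearance targets (`decay_at_8cell`) are compared
#' against other maternal genes with the one-tailed unpaired rank-sum test
#' (alternative: targets greater), and against the zero baseline.
#'
#' @param pair_table output of [per_pair_mbs_table] restricted to the
#'   statistic of interest, with a `gene_id` column; the `gains` column is
#'   the per-pair statistic. Genes x samples absent from the table are not
#'   imputed: supply a dense table (see `dense`) to include zero pairs.
#' @param clearance output of [annotate_clearance].
#' @param samples sample ids forming the pair universe; with `dense = TRUE`
#'   every (maternal gene, sample) combination missing from `pair_table`
#'   contributes a zero.
#' @param dense include zero rows for unobserved (gene, sample) pairs
#'   (default `TRUE`, matching the per-pair universe of the enrichment
#'   analysis).
#' @return two-row data.frame: targets-vs-others and targets-vs-zero tests.
#' @export
clearance_enrichment <- function(pair_table, clearance, samples,
                                 dense = TRUE) {
  groups <- c("decay_at_8cell", "others")
  values <- lapply(groups, function(g) {
    genes <- clearance$gene_id[clearance$clearance_group == g]
    if (dense) {
      full <- expand.grid(gene_id = genes, sample_id = samples,
                          stringsAsFactors = FALSE)
      m <- merge(full, pair_table[, c("gene_id", "sample_id", "gains")],
                 by = c("gene_id", "sample_id"), all.x = TRUE)
      v <- m$gains
      v[is.na(v)] <- 0
      v
    } else {
      pair_table$gains[pair_table$gene_id %in% genes]
    }
  })
  rbind(
    wilcoxon_unpaired_one_tailed(values[[1L]], values[[2L]]),
    wilcoxon_unpaired_one_tailed(values[[1L]], 0)
  )
}
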