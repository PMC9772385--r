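#' Per-site filter thresholds
#'
#' Defaults follow the low-depth single-cell validation setting: an edit
#' needs coverage of at least 2 reads and an editing level of at least 0.1;
#' non-Alu edits additionally need at least 2 mismatch-supporting reads.
#' Cohort-level support asks Alu sites to be seen in at least 1 sample and
#' non-Alu sites in at least 2 same-stage samples of the same normal/abnormal
#' class. Read-level criteria (mean base quality >= 25, mapping quality
#' >= 20, PCR duplicates removed) are applied upstream of the candidate
#' tables and recorded here as metadata only.
#'
#' @param min_coverage minimum read coverage (AN).
#' @param min_editing_level minimum editing level (AF).
#' @param min_mismatch_reads_non_alu minimum AC for non-Alu sites.
#' @param min_samples_alu minimum observing samples for Alu sites.
#' @param min_samples_non_alu_same_stage minimum same-stage, same-class
#'   observing samples for non-Alu sites.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(min_coverage = 2L,
                          min_editing_level = 0.1,
                          min_mismatch_reads_non_alu = 2L,
                          min_samples_alu = 1L,
                          min_samples_non_alu_same_stage = 2L) {
  stopifnot(min_coverage >= 0, min_mismatch_reads_non_alu >= 0,
            min_samples_alu >= 0, min_samples_non_alu_same_stage >= 0,
            min_editing_level >= 0, min_editing_level <= 1)
  structure(list(min_coverage = as.integer(min_coverage),
                 min_editing_level = min_editing_level,
                 min_mismatch_reads_non_alu = as.integer(min_mismatch_reads_non_alu),
                 min_samples_alu = as.integer(min_samples_alu),
                 min_samples_non_alu_same_stage =
                   as.integer(min_samples_non_alu_same_stage),
                 upstream = list(min_mean_base_quality = 25,
                                 min_mapping_quality = 20,
                                 pcr_duplicates_removed = TRUE)),
            class = "filter_config")
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_base <- function(x) unname(DNA_COMPLEMENT[x])

#' Classify a nucleotide change on the transcript strand
#'
#' When the gene strand at a site is known, ref/alt are rotated onto the
#' transcript strand before labelling (a genomic T-to-C change on a
#' minus-strand gene is an A-to-G change on the transcript). When the strand
#' is unknown, the change and its reverse complement are collapsed into one
#' strand-ambiguous class such as `"A-to-G/T-to-C"`.
#'
#' @param ref,alt reference and alternative bases (A/C/G/T), vectorised.
#' @param gene_strand `"+"`, `"-"` or `"unknown"`, recycled.
#' @return data.frame with columns `change` (label) and `definiteness`
#'   (`strand_definite` or `strand_ambiguous`).
#' @export
classify_change <- function(ref, alt, gene_strand = "unknown") {
  ref <- toupper(ref); alt <- toupper(alt)
  n <- max(length(ref), length(alt), length(gene_strand))
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  gene_strand <- rep_len(gene_strand, n)
  if (!all(ref %in% names(DNA_COMPLEMENT)) || !all(alt %in% names(DNA_COMPLEMENT))) {
    stop("classify_change: ref and alt must be A, C, G or T")
  }
  if (any(ref == alt)) stop("classify_change: ref must differ from alt")
  if (!all(gene_strand %in% c("+", "-", "unknown"))) {
    stop("classify_change: gene_strand must be '+', '-' or 'unknown'")
  }
  minus <- gene_strand == "-"
  ref2 <- ifelse(minus, complement_base(ref), ref)
  alt2 <- ifelse(minus, complement_base(alt), alt)
  ambiguous <- gene_strand == "unknown"
  label <- paste0(ref2, "-to-", alt2)
  if (any(ambiguous)) {
    rc_label <- paste0(complement_base(ref2), "-to-", complement_base(alt2))
    # canonical member first: the one whose reference base is A or C
    first <- ifelse(ref2 %in% c("A", "C"), label, rc_label)
    second <- ifelse(ref2 %in% c("A", "C"), rc_label, label)
    label[ambiguous] <- paste0(first, "/", second)[ambiguous]
  }
  data.frame(change = label,
             definiteness = ifelse(ambiguous, "strand_ambiguous",
                                   "strand_definite"),
             stringsAsFactors = FALSE)
}

#' Remove calls at known genomic variant positions
#'
#' Genomic contamination control: any call whose (chrom, pos) appears in any
#' supplied known-variant set is dropped; all other calls are kept in their
#' input order.
#'
#' @param calls an [edit_calls] table.
#' @param snp_sets a single set or list of sets; each either a
#'   [GenomicRanges::GRanges] or a data.frame with `chrom` and `pos`.
#' @return the retained [edit_calls].
#' @export
exclude_known_variants <- function(calls, snp_sets) {
  if (nrow(calls) == 0L) return(calls)
  if (!is.list(snp_sets) || is.data.frame(snp_sets) ||
      methods::is(snp_sets, "GRanges")) {
    snp_sets <- list(snp_sets)
  }
  drop <- rep(FALSE, nrow(calls))
  for (s in snp_sets) {
    if (methods::is(s, "GRanges")) {
      drop <- drop | pos_in_mask(calls$chrom, calls$pos, s)
    } else if (nrow(s) > 0L) {
      drop <- drop | (site_key(calls) %in% site_key(s))
    }
  }
  calls[!drop, , drop = FALSE]
}

#' Apply per-call coverage, level and mismatch filters
#'
#' Alu calls pass with coverage >= `min_coverage` and level >=
#' `min_editing_level`; non-Alu calls additionally need at least
#' `min_mismatch_reads_non_alu` mismatch-supporting reads. The first failing
#' criterion (coverage, then level, then mismatch support) is reported as
#' the rejection reason.
#'
#' @param calls an [edit_calls] table.
#' @param is_alu logical vector (recycled): does each call sit in an Alu
#'   element?
#' @param cfg a [filter_config].
#' @return `calls` with added logical `accept` and character `reason`
#'   (`NA` for accepted calls; otherwise `low_coverage`, `low_level` or
#'   `few_mismatch_reads`).
#' @export
apply_site_filters <- function(calls, is_alu, cfg = filter_config()) {
  is_alu <- rep_len(is_alu, nrow(calls))
  reason <- rep(NA_character_, nrow(calls))
  low_cov <- calls$AN < cfg$min_coverage
  low_lvl <- !low_cov & calls$AF < cfg$min_editing_level
  few_mm <- !low_cov & !low_lvl & !is_alu &
    calls$AC < cfg$min_mismatch_reads_non_alu
  reason[few_mm] <- "few_mismatch_reads"
  reason[low_lvl] <- "low_level"
  reason[low_cov] <- "low_coverage"
  calls$accept <- is.na(reason)
  calls$reason <- reason
  calls
}

#' Cohort-level support filter for sites
#'
#' Summarises per-sample accepted calls to the site level: an Alu site is
#' kept if observed in at least `min_samples_alu` samples anywhere; a
#' non-Alu site is kept only if observed in at least
#' `min_samples_non_alu_same_stage` samples belonging to one (stage, normal)
#' group or to one (stage, abnormal) group. Normal and abnormal observations
#' are never pooled.
#'
#' @param observations data.frame of per-sample accepted calls with `chrom`,
#'   `pos`, `sample_id` (an [edit_calls] table works).
#' @param meta a [sample_meta] table covering every observing sample.
#' @param alu_mask [GenomicRanges::GRanges] of Alu elements.
#' @param cfg a [filter_config].
#' @return data.frame of accepted sites: `chrom`, `pos`, `is_alu`,
#'   `n_samples` (total observing samples).
#' @export
apply_support_filter <- function(observations, meta, alu_mask,
                                 cfg = filter_config()) {
  unknown <- setdiff(unique(observations$sample_id), meta$sample_id)
  if (length(unknown) > 0L) {
    stop("apply_support_filter: unknown sample id: ", unknown[1L])
  }
  if (nrow(observations) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      is_alu = logical(), n_samples = integer()))
  }
  obs <- unique(observations[, c("chrom", "pos", "sample_id")])
  idx <- match(obs$sample_id, meta$sample_id)
  obs$stage <- meta$stage[idx]
  obs$class <- ifelse(meta$condition[idx] == "normal", "normal", "abnormal")
  key <- site_key(obs)
  sites <- unique(obs[, c("chrom", "pos")])
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  skey <- site_key(sites)
  sites$is_alu <- pos_in_mask(sites$chrom, sites$pos, alu_mask)
  total <- table(key)
  sites$n_samples <- as.integer(total[skey])
  group_counts <- table(paste(key, obs$stage, obs$class, sep = "\r"))
  max_group <- tapply(as.integer(group_counts),
                      sub("\r.*$", "", names(group_counts)), max)
  sites$max_same_stage_class <- as.integer(max_group[skey])
  keep <- ifelse(sites$is_alu,
                 sites$n_samples >= cfg$min_samples_alu,
                 sites$max_same_stage_class >=
                   cfg$min_samples_non_alu_same_stage)
  rownames(sites) <- NULL
  sites[keep, c("chrom", "pos", "is_alu", "n_samples"), drop = FALSE]
}

#' Proportion of A-to-G-compatible variants
#'
#' QC metric: the fraction of classified variants that are strand-definite
#' A-to-G or strand-ambiguous A-to-G/T-to-C, over all variants.
#'
#' @param classes data.frame from [classify_change].
#' @return fraction in `[0, 1]`; `NaN` with a warning on empty input.
#' @export
qc_a2g_proportion <- function(classes) {
  if (nrow(classes) == 0L) {
    warning("qc_a2g_proportion: empty input")
    return(NaN)
  }
  qualifying <- (classes$change == "A-to-G" &
                   classes$definiteness == "strand_definite") |
    (classes$change == "A-to-G/T-to-C" &
       classes$definiteness == "strand_ambiguous")
  mean(qualifying)
}

#' Fraction of accepted sites inside the Alu mask
#'
#' @param sites data.frame with `chrom`, `pos` (unique sites).
#' @param alu_mask [GenomicRanges::GRanges].
#' @return fraction in `[0, 1]`; `NaN` with a warning on empty input.
#' @export
qc_alu_ratio <- function(sites, alu_mask) {
  if (nrow(sites) == 0L) {
    warning("qc_alu_ratio: empty input")
    return(NaN)
  }
  mean(pos_in_mask(sites$chrom, sites$pos, alu_mask))
}

#' Overlap of RNA edit sites with DNA variant sites
#'
#' The pipeline-validation metric: of the identified RNA edits, what
#' fraction coincides with a DNA variant position in the same cell? Computed
#' per sample when `rna_edits` carries a `sample_id` column, otherwise over
#' the pooled site set.
#'
#' @param rna_edits data.frame with `chrom`, `pos` and optionally
#'   `sample_id`.
#' @param dna_variants data.frame with `chrom`, `pos` (optionally per-sample
#'   with `sample_id`).
#' @return named numeric vector of per-sample ratios (single unnamed value
#'   when no sample ids are present); `NaN` with a warning for an empty RNA
#'   set.
#' @export
dna_rna_concordance <- function(rna_edits, dna_variants) {
  ratio_one <- function(rna, dna) {
    if (nrow(rna) == 0L) {
      warning("dna_rna_concordance: empty RNA edit set")
      return(NaN)
    }
    rk <- unique(site_key(rna))
    mean(rk %in% site_key(dna))
  }
  if ("sample_id" %in% names(rna_edits)) {
    samples <- sort(unique(rna_edits$sample_id))
    per_sample_dna <- "sample_id" %in% names(dna_variants)
    out <- vapply(samples, function(s) {
      dna <- if (per_sample_dna) {
        dna_variants[dna_variants$sample_id == s, , drop = FALSE]
      } else dna_variants
      ratio_one(rna_edits[rna_edits$sample_id == s, , drop = FALSE], dna)
    }, numeric(1))
    names(out) <- samples
    out
  } else {
    ratio_one(rna_edits, dna_variants)
  }
}

#' Nucleotide context profile around edit sites
#'
#' Computes the per-position nucleotide frequencies in a window around each
#' edited adenosine, on the edited strand (minus-strand sites are
#' reverse-complemented), the standard readout of the deaminase sequence
#' preference (G depletion 5' of, G enrichment 3' of, the edited base).
#'
#' @param sites data.frame with `chrom`, `pos` and `strand` (`+`/`-`;
#'   unknown strands are treated as `+`).
#' @param genome [Biostrings::DNAStringSet].
#' @param flank window half-width in nucleotides (>= 1).
#' @return numeric matrix: rows A/C/G/T, columns positions `-flank..flank`;
#'   each column sums to 1. Sites too close to a contig edge are skipped
#'   with a warning; the count of skipped sites is in attribute `n_skipped`.
#' @export
context_profile <- function(sites, genome, flank = 3L) {
  stopifnot(flank >= 1L)
  positions <- seq(-flank, flank)
  counts <- matrix(0L, nrow = 4L, ncol = length(positions),
                   dimnames = list(c("A", "C", "G", "T"),
                                   as.character(positions)))
  n_skipped <- 0L
  for (i in seq_len(nrow(sites))) {
    chrom <- sites$chrom[i]
    pos <- sites$pos[i]
    contig <- genome[[chrom]]
    if (pos - flank < 1L || pos + flank > length(contig)) {
      n_skipped <- n_skipped + 1L
      next
    }
    s <- Biostrings::subseq(contig, pos - flank, pos + flank)
    if (!is.null(sites$strand) && identical(sites$strand[i], "-")) {
      s <- Biostrings::reverseComplement(s)
    }
    chars <- strsplit(as.character(s), "")[[1L]]
    for (j in seq_along(chars)) {
      counts[chars[j], j] <- counts[chars[j], j] + 1L
    }
  }
  if (n_skipped > 0L) {
    warning("context_profile: skipped ", n_skipped,
            " site(s) too close to a contig edge")
  }
  totals <- colSums(counts)
  freq <- sweep(counts, 2L, pmax(totals, 1L), "/")
  attr(freq, "n_skipped") <- n_skipped
  freq
}
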