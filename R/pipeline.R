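#' Filter a cohort's candidate calls down to the accepted editome
#'
#' The cohort-level filtering cascade: (1) remove calls at known genomic
#' variant positions; (2) apply the per-call coverage/level/mismatch
#' filters (Alu-aware); (3) apply the cohort support rule (Alu sites need
#' one observing sample anywhere, non-Alu sites two same-stage samples of
#' the same normal/abnormal class); (4) restrict the per-sample calls to
#' the supported sites.
#'
#' @param calls an [edit_calls] table for the cohort.
#' @param meta a [sample_meta] table.
#' @param alu_mask [GenomicRanges::GRanges] of Alu elements.
#' @param snp_sets known-variant sets for [exclude_known_variants].
#' @param cfg a [filter_config].
#' @return list: `calls` (accepted per-sample calls), `sites` (accepted
#'   site table from [apply_support_filter]), `log` (counts in/out per
#'   stage of the cascade).
#' @export
filter_cohort <- function(calls, meta, alu_mask, snp_sets = list(),
                          cfg = filter_config()) {
  n0 <- nrow(calls)
  calls <- exclude_known_variants(calls, snp_sets)
  n1 <- nrow(calls)
  flt <- apply_site_filters(calls, pos_in_mask(calls$chrom, calls$pos,
                                               alu_mask), cfg)
  accepted <- flt[flt$accept, , drop = FALSE]
  n2 <- nrow(accepted)
  sites <- apply_support_filter(accepted, meta, alu_mask, cfg)
  keep <- site_key(accepted) %in% site_key(sites)
  accepted <- accepted[keep, setdiff(names(accepted), c("accept", "reason")),
                       drop = FALSE]
  rownames(accepted) <- NULL
  list(calls = accepted, sites = sites,
       log = c(candidates = n0, after_known_variant_exclusion = n1,
               after_site_filters = n2, after_support_filter = nrow(accepted)))
}

#' Classify the MBS effect of edit sites across a gene model
#'
#' For every site lying in the 3'-UTR of at least one transcript, builds
#' the per-transcript UTR sequences and edit positions of its gene locus
#' and runs the five-way gain/loss cascade for every microRNA family.
#'
#' @param sites data.frame of edit sites (`chrom`, `pos`); sites outside
#'   every 3'-UTR are skipped.
#' @param gm a [gene_model].
#' @param genome [Biostrings::DNAStringSet].
#' @param families a [mirna_families] table.
#' @param predictor,scoring see [mbs_predictions].
#' @param keep_all keep `no_overlaps` rows (default `FALSE`: only families
#'   whose sites the edit touches are reported).
#' @return data.frame: `chrom`, `pos`, `gene_id`, `family_id`,
#'   `classification`, `n_introduced`, `n_removed`.
#' @export
annotate_mbs_deltas <- function(sites, gm, genome, families,
                                predictor = "seed",
                                scoring = align_scoring(),
                                keep_all = FALSE) {
  sites <- unique(sites[, c("chrom", "pos")])
  utr_tx <- unique(gm$features$transcript_id[gm$features$type == "UTR3"])
  utr_seqs <- as.character(utr3_sequences(gm, genome, utr_tx))
  tx2gene <- gm$transcripts$gene_id[match(utr_tx, gm$transcripts$transcript_id)]
  out <- list()
  for (i in seq_len(nrow(sites))) {
    upos <- vapply(utr_tx, function(t_id) {
      utr3_position(gm, t_id, sites$chrom[i], sites$pos[i])
    }, integer(1))
    # only adenosines on the transcript strand can carry an A-to-G edit
    is_a <- !is.na(upos) &
      substr(utr_seqs[utr_tx], upos, upos) == "A"
    upos[!is_a] <- NA_integer_
    hit_genes <- unique(tx2gene[!is.na(upos)])
    for (g in hit_genes) {
      tx <- utr_tx[tx2gene == g]
      cls <- classify_edit_mbs(utr_seqs[tx], upos[tx], families,
                               predictor, scoring)
      if (!keep_all) {
        cls <- cls[cls$classification != "no_overlaps", , drop = FALSE]
      }
      if (nrow(cls) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = sites$chrom[i], pos = sites$pos[i], gene_id = g, cls,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      gene_id = character(), family_id = character(),
                      classification = character(), n_introduced = integer(),
                      n_removed = integer()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
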