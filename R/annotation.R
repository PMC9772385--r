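#' Region classes in decreasing priority order
#'
#' The fixed priority used to reduce per-transcript classes to one label per
#' site: coding sequence, then 5'-UTR, 3'-UTR, non-coding exonic, intronic,
#' intergenic.
#'
#' @return character vector, highest priority first.
#' @export
region_priority <- function() {
  c("CDS", "UTR5", "UTR3", "noncoding_exonic", "intronic", "intergenic")
}

#' Reduce a set of per-transcript region classes to one site label
#'
#' @param classes character vector of region classes (possibly empty, which
#'   reduces to `intergenic`).
#' @return the highest-priority class present.
#' @export
reduce_region_classes <- function(classes) {
  pr <- region_priority()
  classes <- classes[classes %in% pr]
  if (length(classes) == 0L) return("intergenic")
  pr[min(match(classes, pr))]
}

per_transcript_region <- function(gm, chrom, pos) {
  tx <- gm$transcripts
  hit <- which(tx$chrom == chrom & tx$start <= pos & pos <= tx$end)
  if (length(hit) == 0L) {
    return(data.frame(gene_id = character(), transcript_id = character(),
                      class = character(), stringsAsFactors = FALSE))
  }
  f <- gm$features
  out <- lapply(hit, function(i) {
    t_id <- tx$transcript_id[i]
    ft <- f[f$transcript_id == t_id & f$start <= pos & pos <= f$end, , drop = FALSE]
    cls <- if (tx$coding[i]) {
      if ("CDS" %in% ft$type) "CDS"
      else if ("UTR5" %in% ft$type) "UTR5"
      else if ("UTR3" %in% ft$type) "UTR3"
      else "intronic"
    } else {
      if ("exon" %in% ft$type) "noncoding_exonic" else "intronic"
    }
    data.frame(gene_id = tx$gene_id[i], transcript_id = t_id, class = cls,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify edit sites by genomic region
#'
#' For every site, computes the region class on each overlapping transcript
#' (across all overlapping gene loci) and reduces them by the fixed priority
#' order of [region_priority]. Sites overlapping no transcript are
#' `intergenic`.
#'
#' @param sites data.frame with `chrom`, `pos`.
#' @param gm a [gene_model].
#' @return list with `sites` (input plus `region` and comma-separated
#'   `gene_ids`), `per_transcript` (site index, gene, transcript, class) and
#'   `per_gene` (site index, gene, class reduced within each gene).
#' @export
classify_region <- function(sites, gm) {
  per_tx <- vector("list", nrow(sites))
  region <- character(nrow(sites))
  gene_ids <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    pt <- per_transcript_region(gm, sites$chrom[i], sites$pos[i])
    region[i] <- reduce_region_classes(pt$class)
    gene_ids[i] <- paste(sort(unique(pt$gene_id)), collapse = ",")
    if (nrow(pt) > 0L) pt$site <- i
    per_tx[[i]] <- pt
  }
  per_transcript <- do.call(rbind, per_tx[lengths(lapply(per_tx, nrow)) > 0 &
                                            vapply(per_tx, nrow, 0L) > 0L])
  if (is.null(per_transcript)) {
    per_transcript <- data.frame(gene_id = character(),
                                 transcript_id = character(),
                                 class = character(), site = integer())
  }
  per_gene <- if (nrow(per_transcript) > 0L) {
    agg <- split(per_transcript,
                 paste(per_transcript$site, per_transcript$gene_id, sep = "\r"))
    do.call(rbind, lapply(agg, function(g) {
      data.frame(site = g$site[1L], gene_id = g$gene_id[1L],
                 class = reduce_region_classes(g$class),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(site = integer(), gene_id = character(), class = character())
  }
  rownames(per_gene) <- NULL
  sites$region <- region
  sites$gene_ids <- gene_ids
  list(sites = sites, per_transcript = per_transcript, per_gene = per_gene)
}

cds_blocks <- function(gm, transcript_id) {
  f <- gm$features
  b <- f[f$transcript_id == transcript_id & f$type == "CDS", , drop = FALSE]
  b[order(b$start), , drop = FALSE]
}

cds_position <- function(b, pos) {
  widths <- b$end - b$start + 1L
  hit <- which(b$start <= pos & pos <= b$end)
  if (length(hit) == 0L) return(NA_integer_)
  offset_plus <- sum(widths[seq_len(hit - 1L)]) + (pos - b$start[hit]) + 1L
  if (b$strand[1L] == "+") offset_plus else sum(widths) - offset_plus + 1L
}

cds_sequence <- function(b, genome) {
  pieces <- vapply(seq_len(nrow(b)), function(i) {
    as.character(Biostrings::subseq(genome[[b$chrom[i]]], b$start[i], b$end[i]))
  }, character(1))
  s <- paste(pieces, collapse = "")
  if (b$strand[1L] == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

#' Protein recoding effect of edits in coding sequence
#'
#' For each site falling in the CDS of one or more transcripts, substitutes
#' the alternative base on the coding strand into the affected codon and
#' reports the amino-acid change under the standard genetic code. One row
#' per affected transcript; sites outside every CDS get a single row with
#' effect `none`. Transcripts whose assembled CDS length is not a multiple
#' of 3 are skipped with a warning.
#'
#' @param sites data.frame with `chrom`, `pos` and optionally `ref`/`alt`
#'   (default edit: A-to-G on the transcript strand).
#' @param gm a [gene_model].
#' @param genome [Biostrings::DNAStringSet].
#' @return data.frame: site index, gene, transcript, codon/aa before and
#'   after, `effect` in `{missense, synonymous, stop_gained, stop_lost,
#'   none}`.
#' @export
recoding_effect <- function(sites, gm, genome) {
  code <- Biostrings::GENETIC_CODE
  out <- list()
  for (i in seq_len(nrow(sites))) {
    chrom <- sites$chrom[i]
    pos <- sites$pos[i]
    alt <- if (!is.null(sites$alt)) toupper(sites$alt[i]) else NA_character_
    tx <- gm$transcripts[gm$transcripts$coding, , drop = FALSE]
    affected <- FALSE
    for (j in seq_len(nrow(tx))) {
      b <- cds_blocks(gm, tx$transcript_id[j])
      if (nrow(b) == 0L || b$chrom[1L] != chrom) next
      cpos <- cds_position(b, pos)
      if (is.na(cpos)) next
      affected <- TRUE
      cds <- cds_sequence(b, genome)
      if (nchar(cds) %% 3L != 0L) {
        warning("recoding_effect: CDS length of ", tx$transcript_id[j],
                " is not a multiple of 3; transcript skipped")
        next
      }
      strand <- b$strand[1L]
      alt_t <- if (is.na(alt)) "G" else if (strand == "-") complement_base(alt) else alt
      codon_idx <- (cpos - 1L) %/% 3L + 1L
      within <- (cpos - 1L) %% 3L + 1L
      codon_before <- substr(cds, (codon_idx - 1L) * 3L + 1L, codon_idx * 3L)
      codon_after <- codon_before
      substr(codon_after, within, within) <- alt_t
      aa_before <- unname(code[codon_before])
      aa_after <- unname(code[codon_after])
      effect <- if (aa_before == aa_after) "synonymous"
        else if (aa_after == "*") "stop_gained"
        else if (aa_before == "*") "stop_lost"
        else "missense"
      out[[length(out) + 1L]] <- data.frame(
        site = i, gene_id = tx$gene_id[j], transcript_id = tx$transcript_id[j],
        codon_before = codon_before, codon_after = codon_after,
        aa_before = aa_before, aa_after = aa_after, effect = effect,
        stringsAsFactors = FALSE)
    }
    if (!affected) {
      out[[length(out) + 1L]] <- data.frame(
        site = i, gene_id = NA_character_, transcript_id = NA_character_,
        codon_before = NA_character_, codon_after = NA_character_,
        aa_before = NA_character_, aa_after = NA_character_, effect = "none",
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
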