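#' Read a gene model from GTF/GFF3
#'
#' Builds the internal gene model from `exon` and `CDS` features (any GTF
#' with `gene_id` and `transcript_id` attributes is accepted). Untranslated
#' regions are always derived as exon-minus-CDS, split into 5' and 3' parts
#' by their position relative to the CDS on the transcript strand, so files
#' with or without explicit UTR lines yield the same model. Transcripts
#' without any CDS are kept as non-coding.
#'
#' @param path GTF or GFF3 file.
#' @return A `gene_model` object; see [gene_model].
#' @export
read_gene_model <- function(path) {
  if (!file.exists(path)) stop("read_gene_model: no such file: ", path)
  gr <- rtracklayer::import(path)
  type <- as.character(gr$type)
  keep <- type %in% c("exon", "CDS")
  gr <- gr[keep]
  type <- type[keep]
  tx <- as.character(gr$transcript_id)
  gene <- as.character(gr$gene_id)
  gene_name <- if (!is.null(gr$gene_name)) as.character(gr$gene_name) else gene
  feats <- data.frame(
    gene_id = gene,
    gene_name = ifelse(is.na(gene_name), gene, gene_name),
    transcript_id = tx,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    type = type,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  gene_model(feats)
}

#' Construct a gene model from typed intervals
#'
#' @param feats data.frame with columns `gene_id`, `gene_name`,
#'   `transcript_id`, `chrom`, `strand` (`+` or `-`), `type` (`exon` or
#'   `CDS`), `start`, `end` (1-based closed genomic coordinates).
#' @return A `gene_model`: list with `features` (exon/CDS/UTR5/UTR3 typed
#'   intervals per transcript), `transcripts` and `genes` summary tables.
#' @export
gene_model <- function(feats) {
  feats <- as.data.frame(feats)
  feats$start <- as.integer(feats$start)
  feats$end <- as.integer(feats$end)
  if (any(feats$start > feats$end)) stop("gene_model: start > end interval")
  if (!all(feats$strand %in% c("+", "-"))) {
    stop("gene_model: strand must be '+' or '-' for every feature")
  }
  tx_ids <- unique(feats$transcript_id)
  has_exon <- tapply(feats$type == "exon", feats$transcript_id, any)
  has_cds <- tapply(feats$type == "CDS", feats$transcript_id, any)
  orphans <- names(has_cds)[has_cds & !has_exon[names(has_cds)]]
  if (length(orphans) > 0L) {
    stop("gene_model: transcript with CDS but no exons: ", orphans[1L])
  }
  out <- vector("list", length(tx_ids))
  for (i in seq_along(tx_ids)) {
    t_id <- tx_ids[i]
    f <- feats[feats$transcript_id == t_id, , drop = FALSE]
    exons <- IRanges::reduce(IRanges::IRanges(f$start[f$type == "exon"],
                                              f$end[f$type == "exon"]))
    cds <- IRanges::reduce(IRanges::IRanges(f$start[f$type == "CDS"],
                                            f$end[f$type == "CDS"]))
    strand <- f$strand[1L]
    rows <- list(typed_rows(f, exons, "exon"))
    if (length(cds) > 0L) {
      utr <- IRanges::setdiff(exons, cds)
      cds_lo <- min(IRanges::start(cds))
      cds_hi <- max(IRanges::end(cds))
      left <- utr[IRanges::end(utr) < cds_lo]
      right <- utr[IRanges::start(utr) > cds_hi]
      utr5 <- if (strand == "+") left else right
      utr3 <- if (strand == "+") right else left
      rows <- c(rows, list(typed_rows(f, cds, "CDS"),
                           typed_rows(f, utr5, "UTR5"),
                           typed_rows(f, utr3, "UTR3")))
    }
    out[[i]] <- do.call(rbind, rows)
  }
  features <- do.call(rbind, out)
  rownames(features) <- NULL
  tx_first <- features[features$type == "exon", , drop = FALSE]
  transcripts <- do.call(rbind, lapply(split(tx_first, tx_first$transcript_id),
    function(f) {
      data.frame(transcript_id = f$transcript_id[1L], gene_id = f$gene_id[1L],
                 gene_name = f$gene_name[1L], chrom = f$chrom[1L],
                 strand = f$strand[1L], start = min(f$start), end = max(f$end),
                 coding = any(features$type == "CDS" &
                                features$transcript_id == f$transcript_id[1L]),
                 stringsAsFactors = FALSE)
    }))
  rownames(transcripts) <- NULL
  genes <- do.call(rbind, lapply(split(transcripts, transcripts$gene_id),
    function(t) {
      data.frame(gene_id = t$gene_id[1L], gene_name = t$gene_name[1L],
                 chrom = t$chrom[1L], strand = t$strand[1L],
                 start = min(t$start), end = max(t$end),
                 stringsAsFactors = FALSE)
    }))
  rownames(genes) <- NULL
  structure(list(features = features, transcripts = transcripts,
                 genes = genes),
            class = "gene_model")
}

typed_rows <- function(f, ir, type) {
  if (length(ir) == 0L) {
    return(f[0L, c("gene_id", "gene_name", "transcript_id", "chrom",
                   "strand", "type", "start", "end")])
  }
  k <- length(ir)
  quick_df(list(gene_id = rep_len(f$gene_id[1L], k),
                gene_name = rep_len(f$gene_name[1L], k),
                transcript_id = rep_len(f$transcript_id[1L], k),
                chrom = rep_len(f$chrom[1L], k),
                strand = rep_len(f$strand[1L], k),
                type = rep_len(type, k),
                start = IRanges::start(ir), end = IRanges::end(ir)))
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model:", nrow(x$genes), "genes,",
      nrow(x$transcripts), "transcripts\n")
  invisible(x)
}

#' Write a gene model as GTF
#'
#' Emits exon and CDS lines (UTRs are re-derivable); suitable as input for
#' [read_gene_model].
#'
#' @param gm a `gene_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_model_gtf <- function(gm, path) {
  f <- gm$features[gm$features$type %in% c("exon", "CDS"), , drop = FALSE]
  attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                   f$gene_id, f$transcript_id, f$gene_name)
  lines <- sprintf("%s\teditome\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                   f$chrom, f$type, f$start, f$end, f$strand,
                   ifelse(f$type == "CDS", "0", "."), attrs)
  writeLines(lines, path)
  invisible(path)
}

utr3_blocks <- function(gm, transcript_id) {
  f <- gm$features
  b <- f[f$transcript_id == transcript_id & f$type == "UTR3", , drop = FALSE]
  b[order(b$start), , drop = FALSE]
}

#' Extract 3'-UTR sequences in transcript orientation
#'
#' @param gm a `gene_model`.
#' @param genome a [Biostrings::DNAStringSet] keyed by chromosome name.
#' @param transcript_ids transcripts to extract (default: all coding ones
#'   with a non-empty 3'-UTR).
#' @return A [Biostrings::DNAStringSet], one entry per transcript, 5'-to-3'
#'   in transcript orientation (minus-strand UTRs reverse-complemented).
#' @export
utr3_sequences <- function(gm, genome, transcript_ids = NULL) {
  if (is.null(transcript_ids)) {
    transcript_ids <- unique(gm$features$transcript_id[gm$features$type == "UTR3"])
  }
  seqs <- vapply(transcript_ids, function(t_id) {
    b <- utr3_blocks(gm, t_id)
    if (nrow(b) == 0L) return("")
    pieces <- vapply(seq_len(nrow(b)), function(i) {
      as.character(Biostrings::subseq(genome[[b$chrom[i]]], b$start[i], b$end[i]))
    }, character(1))
    s <- paste(pieces, collapse = "")
    if (b$strand[1L] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    s
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- transcript_ids
  out
}

#' Map a genomic position onto a transcript's 3'-UTR
#'
#' @param gm a `gene_model`.
#' @param transcript_id transcript.
#' @param chrom,pos genomic site (1-based).
#' @return 1-based position within the 3'-UTR in transcript orientation, or
#'   `NA` if the site does not fall in this transcript's 3'-UTR.
#' @export
utr3_position <- function(gm, transcript_id, chrom, pos) {
  b <- utr3_blocks(gm, transcript_id)
  if (nrow(b) == 0L || b$chrom[1L] != chrom) return(NA_integer_)
  widths <- b$end - b$start + 1L
  hit <- which(b$start <= pos & pos <= b$end)
  if (length(hit) == 0L) return(NA_integer_)
  offset_plus <- sum(widths[seq_len(hit - 1L)]) + (pos - b$start[hit]) + 1L
  if (b$strand[1L] == "+") offset_plus else sum(widths) - offset_plus + 1L
}

#' Map a 3'-UTR position back to genomic coordinates
#'
#' Inverse of [utr3_position].
#'
#' @param gm a `gene_model`.
#' @param transcript_id transcript.
#' @param utr_pos 1-based position in transcript orientation.
#' @return genomic 1-based position, or `NA` if out of range.
#' @export
utr3_genomic_position <- function(gm, transcript_id, utr_pos) {
  b <- utr3_blocks(gm, transcript_id)
  if (nrow(b) == 0L) return(NA_integer_)
  widths <- b$end - b$start + 1L
  total <- sum(widths)
  if (is.na(utr_pos) || utr_pos < 1L || utr_pos > total) return(NA_integer_)
  offset_plus <- if (b$strand[1L] == "+") utr_pos else total - utr_pos + 1L
  cum <- cumsum(widths)
  blk <- which(offset_plus <= cum)[1L]
  within <- offset_plus - (if (blk == 1L) 0L else cum[blk - 1L])
  b$start[blk] + within - 1L
}

#' Gene strand at genomic positions
#'
#' Strand assignment used for substitution-class labelling: the strand of the
#' gene(s) spanning the position. Positions outside every gene, or covered by
#' genes on both strands, are `"unknown"`.
#'
#' @param gm a `gene_model`.
#' @param chrom,pos vectors of genomic sites.
#' @return character vector in `c("+", "-", "unknown")`.
#' @export
strand_at <- function(gm, chrom, pos) {
  if (length(chrom) == 0L) return(character(0))
  g <- gm$genes
  ggr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end),
                                strand = g$strand)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hits <- GenomicRanges::findOverlaps(q, ggr, ignore.strand = TRUE)
  out <- rep("unknown", length(q))
  if (length(hits) > 0L) {
    strands <- split(as.character(GenomicRanges::strand(ggr))[S4Vectors::subjectHits(hits)],
                     S4Vectors::queryHits(hits))
    for (k in names(strands)) {
      u <- unique(strands[[k]])
      if (length(u) == 1L) out[as.integer(k)] <- u
    }
  }
  out
}
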