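#' Read a genomic interval mask from a BED file
#'
#' BED intervals are 0-based half-open; they are converted to the package's
#' internal 1-based closed `GRanges` representation at this boundary, so a
#' BED line `chr1 99 100` covers exactly the 1-based position 100. Overlapping
#' intervals are unioned (a point query hits at most once).
#'
#' @param path BED3+ file (whitespace-delimited, no header).
#' @return A reduced [GenomicRanges::GRanges] of the masked regions.
#' @export
read_interval_mask <- function(path) {
  if (!file.exists(path)) stop("read_interval_mask: no such file: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !grepl("^(track|browser|#)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("read_interval_mask: fewer than 3 BED columns at line ",
         lineno[which(nf < 3L)[1L]])
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad) > 0L) {
    stop("read_interval_mask: non-integer coordinates at line ", lineno[bad[1L]])
  }
  bad <- which(start0 >= end0)
  if (length(bad) > 0L) {
    stop("read_interval_mask: start >= end at line ", lineno[bad[1L]])
  }
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start0 + 1L, end = end0))
  GenomicRanges::reduce(gr)
}

#' Write a genomic interval set as BED3
#'
#' Inverse of [read_interval_mask]: internal 1-based closed ranges are
#' converted back to BED's 0-based half-open convention.
#'
#' @param gr a [GenomicRanges::GRanges].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interval_mask <- function(gr, path) {
  writeLines(sprintf("%s\t%d\t%d",
                     as.character(GenomicRanges::seqnames(gr)),
                     GenomicRanges::start(gr) - 1L,
                     GenomicRanges::end(gr)),
             path)
  invisible(path)
}

#' Point-membership query against an interval set
#'
#' @param chrom,pos vectors of chromosome names and 1-based positions.
#' @param mask a [GenomicRanges::GRanges] (e.g. from [read_interval_mask]).
#' @return logical vector: does each (chrom, pos) fall inside the mask?
#' @export
pos_in_mask <- function(chrom, pos, mask) {
  if (length(chrom) == 0L) return(logical(0))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  # queries on chromosomes absent from the mask are ordinary misses
  suppressWarnings(IRanges::overlapsAny(q, mask))
}
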