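#' Canonicalise a nucleotide sequence to DNA letters
#'
#' RNA and DNA inputs are interchangeable throughout the MBS module; the
#' internal alphabet is DNA (U becomes T) in upper case.
#'
#' @param seq character vector of sequences.
#' @return character vector over A/C/G/T.
#' @export
canon_dna <- function(seq) {
  gsub("U", "T", toupper(seq), fixed = TRUE)
}

revcomp_chr <- function(seq) {
  vapply(seq, function(s) {
    paste(rev(strsplit(chartr("ACGTU", "TGCAA", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# all (overlapping) occurrences of a fixed pattern in a single string
all_matches <- function(pattern, x) {
  k <- nchar(pattern)
  n <- nchar(x)
  if (n < k) return(integer(0))
  starts <- seq_len(n - k + 1L)
  starts[substring(x, starts, starts + k - 1L) == pattern]
}

as_named_chr <- function(utrs) {
  nm <- names(utrs)
  utrs <- as.character(utrs)
  names(utrs) <- nm
  utrs
}

#' Construct and validate a microRNA family table
#'
#' @param df data.frame with `family_id`, `seed` (7 nt, mature positions
#'   2-8), `mature_id`, `mature_seq`.
#' @return validated data.frame (DNA alphabet). Each mature sequence's
#'   positions 2-8 must equal its family seed; seeds must be unique per
#'   family.
#' @export
mirna_families <- function(df) {
  required <- c("family_id", "seed", "mature_id", "mature_seq")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("mirna_families: missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[, required, drop = FALSE]
  df$seed <- canon_dna(df$seed)
  df$mature_seq <- canon_dna(df$mature_seq)
  if (any(nchar(df$seed) != 7L)) {
    stop("mirna_families: seed must be exactly 7 nucleotides")
  }
  bad <- which(substr(df$mature_seq, 2L, 8L) != df$seed)
  if (length(bad) > 0L) {
    stop("mirna_families: mature sequence ", df$mature_id[bad[1L]],
         " does not carry its family seed at positions 2-8")
  }
  seed_by_family <- unique(df[, c("family_id", "seed")])
  if (anyDuplicated(seed_by_family$family_id) ||
      anyDuplicated(seed_by_family$seed)) {
    stop("mirna_families: family/seed mapping must be one-to-one")
  }
  df
}

#' Read a miRNA family table from TSV
#'
#' @param path TSV with columns `family_id`, `seed`, `mature_id`,
#'   `mature_seq`.
#' @return validated family table ([mirna_families]).
#' @export
read_mirna_families <- function(path) {
  mirna_families(utils::read.delim(path, stringsAsFactors = FALSE))
}

empty_predictions <- function() {
  quick_df(list(family_id = character(), utr_id = character(),
                start = integer(), end = integer(),
                site_type = character()))
}

#' Seed-match binding sites of one miRNA family on a 3'-UTR
#'
#' Scans the UTR (5'-to-3' in transcript orientation) for exact
#' Watson-Crick complements of the family seed; wobble pairs never count.
#' Site types follow the canonical seed-match taxonomy: the 6mer core is
#' the exact reverse complement of mature positions 2-7; extending the
#' match to position 8 gives 7mer-m8; an adenosine opposite mature position
#' 1 (immediately 3' of the core on the target) upgrades to 7mer-A1, and
#' both together give the 8mer. One site is reported per 6mer-core
#' occurrence, labelled with its longest matching type.
#'
#' @param utr_seq a single UTR sequence (character; RNA or DNA letters).
#' @param seed the family's 7-nt seed (mature positions 2-8).
#' @param family_id,utr_id identifiers copied into the output.
#' @return data.frame of predictions: `family_id`, `utr_id`, `start`,
#'   `end` (1-based inclusive UTR coordinates), `site_type`.
#' @export
seed_sites <- function(utr_seq, seed, family_id = "family", utr_id = "utr") {
  utr <- canon_dna(utr_seq)
  seed <- canon_dna(seed)
  if (nchar(seed) != 7L) stop("seed_sites: seed must be 7 nucleotides")
  n <- nchar(utr)
  if (n < 6L) return(empty_predictions())
  core <- revcomp_chr(substr(seed, 1L, 6L))          # complement of positions 2-7
  m8_base <- revcomp_chr(substr(seed, 7L, 7L))       # complement of position 8
  starts <- all_matches(core, utr)
  if (length(starts) == 0L) return(empty_predictions())
  has_m8 <- starts > 1L &
    substr(rep(utr, length(starts)), starts - 1L, starts - 1L) == m8_base
  has_a1 <- starts + 6L <= n &
    substr(rep(utr, length(starts)), starts + 6L, starts + 6L) == "A"
  site_type <- ifelse(has_m8 & has_a1, "8mer",
                      ifelse(has_m8, "7mer-m8",
                             ifelse(has_a1, "7mer-A1", "6mer")))
  start <- ifelse(has_m8, starts - 1L, starts)
  end <- ifelse(has_a1, starts + 6L, starts + 5L)
  k <- length(starts)
  quick_df(list(family_id = rep_len(family_id, k),
                utr_id = rep_len(utr_id, k), start = as.integer(start),
                end = as.integer(end), site_type = site_type))
}

#' Seed-match predictions for many families on many UTRs
#'
#' @param utrs named character vector or [Biostrings::DNAStringSet] of UTR
#'   sequences.
#' @param families a [mirna_families] table.
#' @return combined prediction data.frame (family level).
#' @export
predict_seed_sites <- function(utrs, families) {
  utrs <- as_named_chr(utrs)
  fam <- unique(families[, c("family_id", "seed")])
  out <- list()
  for (u in names(utrs)) {
    for (i in seq_len(nrow(fam))) {
      out[[length(out) + 1L]] <- seed_sites(utrs[[u]], fam$seed[i],
                                            fam$family_id[i], u)
    }
  }
  res <- do.call(rbind, c(out, list(empty_predictions())))
  rownames(res) <- NULL
  res
}

#' Default scoring for the mature-sequence aligner
#'
#' @return list of `match`, `mismatch`, `gap_open`, `gap_ext`, `min_score`.
#'   The permissive default minimum score keeps every seed-anchored site
#'   whose local context aligns at all, so the predictor intersection is
#'   governed by the seed-match logic.
#' @export
align_scoring <- function() {
  list(match = 5, mismatch = -4, gap_open = 8, gap_ext = 2, min_score = 30)
}

#' Mature-sequence alignment predictions on a 3'-UTR
#'
#' Stand-in for a full-mature-sequence predictor: the reverse complement of
#' the mature miRNA is locally aligned around every exact seed-region
#' complement on the UTR, and an alignment is reported when its score
#' reaches `scoring$min_score` and the aligned region covers the seed
#' site. Each reported alignment carries the seed-site coordinates and the
#' site type derived exactly as in [seed_sites], so that predictions can be
#' collapsed to family level and intersected.
#'
#' @param utr_seq single UTR sequence.
#' @param mature_seq full mature miRNA sequence (>= 8 nt).
#' @param mature_id,utr_id identifiers copied to the output.
#' @param scoring see [align_scoring].
#' @return data.frame: `mature_id`, `utr_id`, `start`, `end`, `site_type`,
#'   `score`.
#' @export
align_mature <- function(utr_seq, mature_seq, mature_id = "mature",
                         utr_id = "utr", scoring = align_scoring()) {
  utr <- canon_dna(utr_seq)
  mature <- canon_dna(mature_seq)
  if (nchar(mature) < 8L) stop("align_mature: mature sequence shorter than 8")
  anchors <- seed_sites(utr, substr(mature, 2L, 8L), "anchor", utr_id)
  if (nrow(anchors) == 0L) {
    return(data.frame(mature_id = character(), utr_id = character(),
                      start = integer(), end = integer(),
                      site_type = character(), score = numeric()))
  }
  query <- Biostrings::DNAString(revcomp_chr(mature))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = scoring$match,
                                                  mismatch = scoring$mismatch)
  out <- list()
  for (i in seq_len(nrow(anchors))) {
    lo <- max(1L, anchors$start[i] - nchar(mature) - 4L)
    hi <- min(nchar(utr), anchors$end[i] + nchar(mature) + 4L)
    window <- Biostrings::DNAString(substr(utr, lo, hi))
    aln <- Biostrings::pairwiseAlignment(query, window, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = scoring$gap_open,
                                         gapExtension = scoring$gap_ext)
    score <- Biostrings::score(aln)
    sub_start <- lo + Biostrings::start(Biostrings::subject(aln)@range) - 1L
    sub_end <- lo + Biostrings::end(Biostrings::subject(aln)@range) - 1L
    covers <- sub_start <= anchors$start[i] && sub_end >= anchors$end[i]
    if (score >= scoring$min_score && covers) {
      out[[length(out) + 1L]] <- data.frame(
        mature_id = mature_id, utr_id = utr_id, start = anchors$start[i],
        end = anchors$end[i], site_type = anchors$site_type[i],
        score = score, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(mature_id = character(), utr_id = character(),
                      start = integer(), end = integer(),
                      site_type = character(), score = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

prediction_key <- function(p) {
  paste(p$family_id, p$utr_id, p$site_type, p$start, p$end, sep = "\r")
}

#' Collapse mature-level alignment predictions to family level
#'
#' Predictions sharing (family, target UTR, site type, seed-site start and
#' end) become one family-level prediction; any difference in one of the
#' four properties keeps them distinct.
#'
#' @param alignment_predictions rows from [align_mature] (with `mature_id`).
#' @param families a [mirna_families] table mapping matures to families.
#' @return family-level prediction data.frame as from [seed_sites].
#' @export
collapse_predictions <- function(alignment_predictions, families) {
  p <- alignment_predictions
  if (nrow(p) == 0L) return(empty_predictions())
  idx <- match(p$mature_id, families$mature_id)
  if (anyNA(idx)) {
    stop("collapse_predictions: mature sequence not in any family: ",
         p$mature_id[which(is.na(idx))[1L]])
  }
  p$family_id <- families$family_id[idx]
  p <- p[, c("family_id", "utr_id", "start", "end", "site_type")]
  p <- unique(p)
  rownames(p) <- NULL
  p
}

#' Intersect two family-level prediction sets
#'
#' A site is kept when both sets contain a prediction with the same
#' (family, target UTR, site type, start, end). Commutative and idempotent.
#'
#' @param set_a,set_b family-level prediction data.frames.
#' @return the shared predictions.
#' @export
intersect_predictions <- function(set_a, set_b) {
  if (nrow(set_a) == 0L || nrow(set_b) == 0L) return(empty_predictions())
  out <- set_a[prediction_key(set_a) %in% prediction_key(set_b), , drop = FALSE]
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Apply an A-to-G edit to a UTR sequence
#'
#' @param utr_seq UTR sequence (transcript orientation).
#' @param utr_pos 1-based position; the base there must be adenosine.
#' @return the edited sequence (A replaced by G at `utr_pos`).
#' @export
apply_edit <- function(utr_seq, utr_pos) {
  utr <- canon_dna(utr_seq)
  if (utr_pos < 1L || utr_pos > nchar(utr)) {
    stop("apply_edit: position ", utr_pos, " out of range for UTR of length ",
         nchar(utr))
  }
  if (substr(utr, utr_pos, utr_pos) != "A") {
    stop("apply_edit: base at position ", utr_pos, " is not adenosine")
  }
  substr(utr, utr_pos, utr_pos) <- "G"
  utr
}

#' Family-level MBS predictions on a UTR set
#'
#' The package's default prediction route. `"seed"` uses the seed-match
#' scanner alone; `"intersection"` intersects the seed scanner with the
#' collapsed mature-sequence aligner (the two-predictor protocol).
#'
#' @param utrs named character vector / DNAStringSet.
#' @param families a [mirna_families] table.
#' @param predictor `"seed"` or `"intersection"`.
#' @param scoring aligner scoring for the intersection route.
#' @return family-level prediction data.frame.
#' @export
mbs_predictions <- function(utrs, families,
                            predictor = c("seed", "intersection"),
                            scoring = align_scoring()) {
  predictor <- match.arg(predictor)
  seed_preds <- predict_seed_sites(utrs, families)
  if (predictor == "seed") return(seed_preds)
  utrs <- as_named_chr(utrs)
  aln <- list()
  for (u in names(utrs)) {
    for (i in seq_len(nrow(families))) {
      aln[[length(aln) + 1L]] <- align_mature(utrs[[u]],
                                              families$mature_seq[i],
                                              families$mature_id[i], u,
                                              scoring)
    }
  }
  aln <- do.call(rbind, aln)
  collapsed <- collapse_predictions(aln, families)
  intersect_predictions(seed_preds, collapsed)
}

#' Classify an edit's per-family MBS effect from per-transcript counts
#'
#' The five-way decision cascade over all transcripts of the gene locus,
#' evaluated in order: `no_overlaps` when the edit neither falls in a
#' pre-existing site nor introduces one on any transcript; `site_unchanged`
#' when every transcript's introduced count equals its removed count;
#' `gain` when no transcript loses more than it gains and at least one
#' strictly gains; `lost` symmetrically; `mixed` otherwise (some transcript
#' strictly gains while another strictly loses).
#'
#' @param introduced,removed integer vectors, one entry per transcript of
#'   the gene: numbers of new/removed sites of the family overlapping the
#'   edit.
#' @param overlap optional logical: does the edit fall in or create any
#'   site on any transcript? Defaults to `any(introduced > 0 | removed >
#'   0)`.
#' @return one of `"no_overlaps"`, `"site_unchanged"`, `"gain"`, `"lost"`,
#'   `"mixed"`.
#' @export
classify_mbs_delta <- function(introduced, removed, overlap = NULL) {
  if (length(introduced) != length(removed)) {
    stop("classify_mbs_delta: transcript sets differ")
  }
  if (is.null(overlap)) overlap <- any(introduced > 0L | removed > 0L)
  if (!overlap) return("no_overlaps")
  if (all(introduced == removed)) return("site_unchanged")
  if (all(introduced >= removed) && any(introduced > removed)) return("gain")
  if (all(introduced <= removed) && any(introduced < removed)) return("lost")
  "mixed"
}

#' Per-transcript MBS change induced by an A-to-G edit
#'
#' Re-predicts sites on the edited UTR and compares, among the sites whose
#' span contains the edit position, the prediction keys before and after.
#'
#' @param utr_seq unedited UTR sequence.
#' @param utr_pos edit position on the UTR.
#' @param families a [mirna_families] table.
#' @param predictor,scoring see [mbs_predictions].
#' @return data.frame per family: `family_id`, `introduced`, `removed`.
#' @export
mbs_transcript_delta <- function(utr_seq, utr_pos, families,
                                 predictor = "seed",
                                 scoring = align_scoring()) {
  utrs_pre <- c(u = canon_dna(utr_seq))
  utrs_post <- c(u = apply_edit(utr_seq, utr_pos))
  pre <- mbs_predictions(utrs_pre, families, predictor, scoring)
  post <- mbs_predictions(utrs_post, families, predictor, scoring)
  pre <- pre[pre$start <= utr_pos & utr_pos <= pre$end, , drop = FALSE]
  post <- post[post$start <= utr_pos & utr_pos <= post$end, , drop = FALSE]
  fams <- unique(families$family_id)
  out <- quick_df(list(family_id = fams,
                       introduced = integer(length(fams)),
                       removed = integer(length(fams))))
  for (i in seq_along(fams)) {
    pk <- prediction_key(pre[pre$family_id == fams[i], , drop = FALSE])
    qk <- prediction_key(post[post$family_id == fams[i], , drop = FALSE])
    out$introduced[i] <- length(setdiff(qk, pk))
    out$removed[i] <- length(setdiff(pk, qk))
  }
  out
}

#' Classify an edit's MBS effect for every family on a gene locus
#'
#' Runs [mbs_transcript_delta] on each transcript of the gene that carries
#' the edit in its 3'-UTR (transcripts whose 3'-UTR does not contain the
#' edit contribute zero counts) and applies the five-way cascade per
#' family.
#'
#' @param utrs named character vector of the gene's per-transcript 3'-UTR
#'   sequences (transcript orientation).
#' @param utr_positions named integer vector aligned with `utrs`: the
#'   edit's 1-based position in each transcript's UTR (`NA` when the edit
#'   lies outside that transcript's UTR).
#' @param families a [mirna_families] table.
#' @param predictor,scoring see [mbs_predictions].
#' @return data.frame per family: `family_id`, `classification`,
#'   `n_introduced`, `n_removed` (summed over transcripts).
#' @export
classify_edit_mbs <- function(utrs, utr_positions, families,
                              predictor = "seed",
                              scoring = align_scoring()) {
  stopifnot(length(utrs) == length(utr_positions))
  fams <- unique(families$family_id)
  introduced <- matrix(0L, nrow = length(fams), ncol = length(utrs),
                       dimnames = list(fams, names(utrs)))
  removed <- introduced
  for (t in seq_along(utrs)) {
    if (is.na(utr_positions[t])) next
    d <- mbs_transcript_delta(utrs[[t]], utr_positions[[t]], families,
                              predictor, scoring)
    introduced[d$family_id, t] <- d$introduced
    removed[d$family_id, t] <- d$removed
  }
  quick_df(list(
    family_id = fams,
    classification = vapply(fams, function(f) {
      classify_mbs_delta(introduced[f, ], removed[f, ])
    }, character(1), USE.NAMES = FALSE),
    n_introduced = as.integer(rowSums(introduced)),
    n_removed = as.integer(rowSums(removed))))
}

#' Per-(gene, sample) MBS gain/loss table
#'
#' Joins classified per-edit MBS deltas with the per-sample observations of
#' those edits: for each gene and sample, counts the (edit, family) pairs
#' classified as gains and as losses among the edits observed in that
#' sample on that gene, and their difference (net change).
#'
#' @param deltas data.frame with `chrom`, `pos`, `gene_id`, `family_id`,
#'   `classification`.
#' @param per_sample_edits accepted per-sample calls (`chrom`, `pos`,
#'   `sample_id`).
#' @return data.frame: `gene_id`, `sample_id`, `gains`, `losses`, `net`
#'   (rows only for (gene, sample) pairs with at least one observed
#'   classified edit).
#' @export
per_pair_mbs_table <- function(deltas, per_sample_edits) {
  obs <- unique(per_sample_edits[, c("chrom", "pos", "sample_id")])
  merged <- merge(deltas, obs, by = c("chrom", "pos"))
  if (nrow(merged) == 0L) {
    return(data.frame(gene_id = character(), sample_id = character(),
                      gains = integer(), losses = integer(),
                      net = integer()))
  }
  key <- paste(merged$gene_id, merged$sample_id, sep = "\r")
  gains <- tapply(merged$classification == "gain", key, sum)
  losses <- tapply(merged$classification == "lost", key, sum)
  parts <- strsplit(names(gains), "\r", fixed = TRUE)
  out <- data.frame(gene_id = vapply(parts, `[[`, "", 1L),
                    sample_id = vapply(parts, `[[`, "", 2L),
                    gains = as.integer(gains),
                    losses = as.integer(losses),
                    stringsAsFactors = FALSE)
  out$net <- out$gains - out$losses
  out <- out[order(out$gene_id, out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
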