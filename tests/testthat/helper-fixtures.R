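# Small in-code fixtures shared across test files.

toy_genome <- function(seqs) Biostrings::DNAStringSet(seqs)

# A plus-strand single-exon coding gene: UTR5 1-10, CDS 11-40, UTR3 41-80.
toy_feats_plus <- function(chrom = "chr1", gene = "gA", tx = "gA.t1",
                           offset = 0L) {
  data.frame(gene_id = gene, gene_name = gene, transcript_id = tx,
             chrom = chrom, strand = "+", type = c("exon", "CDS"),
             start = c(1L, 11L) + offset, end = c(80L, 40L) + offset,
             stringsAsFactors = FALSE)
}

# Minus-strand mirror of the same architecture: genomically, the 3'-UTR is
# the left-most block (1-40), CDS 41-70, 5'-UTR 71-80.
toy_feats_minus <- function(chrom = "chr1", gene = "gB", tx = "gB.t1",
                            offset = 0L) {
  data.frame(gene_id = gene, gene_name = gene, transcript_id = tx,
             chrom = chrom, strand = "-", type = c("exon", "CDS"),
             start = c(1L, 41L) + offset, end = c(80L, 70L) + offset,
             stringsAsFactors = FALSE)
}

toy_meta <- function(n_per_stage = 4L,
                     stages = c("zygote", "2cell"),
                     conditions = "normal") {
  rows <- expand.grid(i = seq_len(n_per_stage), stage = stages,
                      condition = conditions, stringsAsFactors = FALSE)
  rows$sample_id <- sprintf("%s_%s_%02d", rows$stage, rows$condition, rows$i)
  sample_meta(rows[, c("sample_id", "stage", "condition")])
}

# calls observed at one site by a given set of samples
obs_calls <- function(chrom, pos, sample_ids, ref = "A", alt = "G",
                      AC = 5L, AN = 10L) {
  edit_calls(data.frame(sample_id = sample_ids, chrom = chrom, pos = pos,
                        ref = ref, alt = alt, AC = AC, AN = AN))
}

toy_family <- function(seed = "GAGGTAG", family_id = "let7",
                       n_matures = 1L) {
  mirna_families(data.frame(
    family_id = family_id, seed = seed,
    mature_id = paste0(family_id, "-m", seq_len(n_matures)),
    mature_seq = vapply(seq_len(n_matures), function(i) {
      paste0("T", seed, strrep(c("CA", "GT", "AC")[(i - 1L) %% 3L + 1L], 7L))
    }, character(1)),
    stringsAsFactors = FALSE))
}

revcomp_chr_test <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    gsub("U", "T", toupper(s)))))
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_seed_with_c <- function() {
  repeat {
    s <- random_dna_str(7L)
    if (grepl("C", substr(s, 1, 6))) return(s)
  }
}
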