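#' Design of a synthetic embryonic cohort
#'
#' Bundles every parameter of the synthetic-data generator. The defaults
#' describe the study conditions the pipeline is built for: a staged cohort
#' of low-depth single-cell profiles with highly recurrent planted edits
#' (per-stage detection probability 0.9), sporadic noise edits (0.2),
#' homozygous-like genomic-SNP contaminants, abnormal groups (androgenetic,
#' parthenogenetic, elder-mother) with designated complete-dropout edits,
#' an Alu mask over half the 3'-UTRs, a deaminase-like sequence context
#' (G depleted 5' of and enriched 3' of the edited base), microRNA-family
#' seed sites whose gain is enriched on maternal-clearance targets, and
#' maternal transcripts whose oocyte expression decays about four-fold by
#' the 8-cell stage.
#'
#' Detection counts for planted recurrent edits are drawn from binomial
#' distributions truncated to stay at or above the recurrence threshold
#' within their active stages (and below it for noise edits and
#' post-window residual detections), and every non-dropout recurrent edit
#' is guaranteed at least one detection in each abnormal group of its
#' active stages. This makes the ground-truth manifest an exact answer key
#' for recovery tests.
#'
#' @param seed integer seed; the entire generation is a pure function of
#'   the design (same seed, byte-identical outputs).
#' @param stages ordered stage list.
#' @param n_normal normal samples per stage.
#' @param n_abnormal abnormal samples per (stage, condition) group.
#' @param n_genes,utr5_len,utr3_len,cds_codons,intron_len,gap_len gene
#'   architecture: counts and min/max length ranges (nt; codons for the
#'   CDS).
#' @param alu_gene_fraction fraction of genes whose 3'-UTR lies in the Alu
#'   mask.
#' @param n_rees,ree_detect_prob planted recurrent edits and their
#'   per-sample detection probability within active stages.
#' @param ree_fraction recurrence threshold the truncation guards (matches
#'   the analysis default).
#' @param n_noise,noise_detect_prob sporadic noise edits and their
#'   detection probability (also the residual probability of recurrent
#'   edits after their active window).
#' @param noise_nonag_fraction fraction of noise variants planted as
#'   non-A-to-G substitutions.
#' @param n_snps genomic-contaminant positions.
#' @param snp_detect_prob per-sample presence probability of a contaminant.
#' @param dropout named counts of designated complete-loss recurrent edits
#'   per abnormal condition.
#' @param n_families microRNA families.
#' @param clearance_fraction,others_fraction fractions of genes planted as
#'   clearance targets and as non-decaying maternal genes.
#' @param gain_rate_target,gain_rate_other expected planted MBS-gaining
#'   edits per gene (Poisson) for clearance targets vs all other genes.
#' @param decay_fold planted oocyte-to-8-cell decay fold for clearance
#'   targets.
#' @param expr_base,expr_sdlog maternal expression scale (FPKM) and
#'   log-normal noise sd.
#' @param coupling editing-expression coupling strength (per-sample
#'   expression is scaled by `1 - coupling * AF` of the gene's first
#'   recurrent edit).
#' @param an_mu,an_size negative-binomial read-coverage model (shifted so
#'   AN >= 2), mimicking low-depth single-cell profiles.
#' @param context_g_minus1,context_g_plus1 G frequency immediately 5' and
#'   3' of planted edits.
#' @return list of class `cohort_design`.
#' @export
cohort_design <- function(seed = 1L,
                          stages = default_stages(),
                          n_normal = 12L,
                          n_abnormal = 4L,
                          n_genes = 80L,
                          utr5_len = c(30L, 60L),
                          utr3_len = c(120L, 240L),
                          cds_codons = c(30L, 60L),
                          intron_len = c(40L, 80L),
                          gap_len = c(60L, 150L),
                          alu_gene_fraction = 0.5,
                          n_rees = 300L,
                          ree_detect_prob = 0.9,
                          ree_fraction = 0.5,
                          n_noise = 500L,
                          noise_detect_prob = 0.2,
                          noise_nonag_fraction = 0.1,
                          n_snps = 30L,
                          snp_detect_prob = 0.8,
                          dropout = c(AG = 10L, PG = 10L, elder_mother = 0L),
                          n_families = 10L,
                          clearance_fraction = 0.3,
                          others_fraction = 0.3,
                          gain_rate_target = 1.5,
                          gain_rate_other = 0.2,
                          decay_fold = 4,
                          expr_base = 20,
                          expr_sdlog = 0.25,
                          coupling = 0.6,
                          an_mu = 8,
                          an_size = 2,
                          context_g_minus1 = 0.05,
                          context_g_plus1 = 0.5) {
  design <- list(seed = as.integer(seed), stages = stages,
                 n_normal = as.integer(n_normal),
                 n_abnormal = as.integer(n_abnormal),
                 n_genes = as.integer(n_genes), utr5_len = utr5_len,
                 utr3_len = utr3_len, cds_codons = cds_codons,
                 intron_len = intron_len, gap_len = gap_len,
                 alu_gene_fraction = alu_gene_fraction,
                 n_rees = as.integer(n_rees),
                 ree_detect_prob = ree_detect_prob,
                 ree_fraction = ree_fraction,
                 n_noise = as.integer(n_noise),
                 noise_detect_prob = noise_detect_prob,
                 noise_nonag_fraction = noise_nonag_fraction,
                 n_snps = as.integer(n_snps),
                 snp_detect_prob = snp_detect_prob, dropout = dropout,
                 n_families = as.integer(n_families),
                 clearance_fraction = clearance_fraction,
                 others_fraction = others_fraction,
                 gain_rate_target = gain_rate_target,
                 gain_rate_other = gain_rate_other,
                 decay_fold = decay_fold, expr_base = expr_base,
                 expr_sdlog = expr_sdlog, coupling = coupling,
                 an_mu = an_mu, an_size = an_size,
                 context_g_minus1 = context_g_minus1,
                 context_g_plus1 = context_g_plus1)
  probs <- c(design$ree_detect_prob, design$noise_detect_prob,
             design$snp_detect_prob, design$alu_gene_fraction,
             design$clearance_fraction, design$others_fraction,
             design$noise_nonag_fraction, design$context_g_minus1,
             design$context_g_plus1, design$ree_fraction)
  stopifnot(all(probs >= 0 & probs <= 1))
  class(design) <- "cohort_design"
  design
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rint <- function(range) sample(range[1L]:range[2L], 1L)

rbinom_trunc <- function(size, prob, lo = 0L, hi = size) {
  if (lo > hi) stop("rbinom_trunc: empty truncation range")
  repeat {
    k <- stats::rbinom(1L, size, prob)
    if (k >= lo && k <= hi) return(k)
  }
}

is_oocyte_stage <- function(stage) grepl("^oocyte", stage)

#' Generate the synthetic reference: genome, gene model, Alu mask, UTRs
#'
#' Builds a genome of single-transcript two-exon genes (intron inside the
#' CDS), plants every edit placement into the sequence (edited bases are
#' adenosines on the transcript strand, with the deaminase context bias on
#' their flanks), and plants MBS-gain slots: seed-site patterns carrying an
#' A where the site needs a G, so that the A-to-G edit completes the site.
#' Each slot is verified against the MBS classifier at generation time; an
#' infeasible placement raises an error naming the gene.
#'
#' @param design a [cohort_design].
#' @param families a [mirna_families] table (see [generate_families]).
#' @return list: `genome` (DNAStringSet), `model` ([gene_model]), `alu`
#'   (GRanges), `utrs` (per-transcript 3'-UTR DNAStringSet),
#'   `gene_groups` (gene_id, group), `placements` (one row per planted
#'   site: kind, gene, region, genomic coordinates, ref/alt, UTR position,
#'   family for gain slots).
#' @export
generate_reference <- function(design, families) {
  withr::with_seed(design$seed + 101L, {
    if (design$utr3_len[1L] < 12L) {
      stop("generate_reference: infeasible design (3'-UTR shorter than 12)")
    }
    n <- design$n_genes
    gene_ids <- sprintf("G%03d", seq_len(n))
    strands <- sample(c("+", "-"), n, replace = TRUE)
    chroms <- paste0("chr", ((seq_len(n) - 1L) %% 3L) + 1L)
    n_decay <- round(design$clearance_fraction * n)
    n_others <- round(design$others_fraction * n)
    group <- sample(c(rep("decay_at_8cell", n_decay),
                      rep("others", n_others),
                      rep("not_maternal", n - n_decay - n_others)))
    alu_gene <- sample(c(TRUE, FALSE), n, replace = TRUE,
                       prob = c(design$alu_gene_fraction,
                                1 - design$alu_gene_fraction))

    fam_tab <- unique(families[, c("family_id", "seed")])
    # eligible pattern positions: a G inside the 8mer site pattern
    fam_tab$pattern <- paste0(revcomp_chr(fam_tab$seed), "A")

    genes <- vector("list", n)
    for (g in seq_len(n)) {
      u5 <- rint(design$utr5_len)
      codons <- rint(design$cds_codons)
      cds_len <- 3L * codons
      c1 <- 3L * rint(c(5L, codons - 5L))
      c2 <- cds_len - c1
      intr <- rint(design$intron_len)
      u3 <- rint(design$utr3_len)
      L <- u5 + c1 + intr + c2 + u3
      chars <- strsplit(rand_dna(L), "")[[1L]]
      # a clean open reading frame start/stop
      chars[(u5 + 1L):(u5 + 3L)] <- c("A", "T", "G")
      stop_at <- u5 + c1 + intr + c2
      chars[(stop_at - 2L):stop_at] <- c("T", "A", "A")
      genes[[g]] <- list(id = gene_ids[g], strand = strands[g],
                         chrom = chroms[g], u5 = u5, c1 = c1, intr = intr,
                         c2 = c2, u3 = u3, L = L, chars = chars,
                         reserved = rep(FALSE, L),
                         group = group[g], alu = alu_gene[g])
    }

    utr3_t0 <- function(ge) ge$L - ge$u3   # t = utr3_t0 + utr_pos

    # --- plant MBS-gain slots --------------------------------------------
    slot_rows <- list()
    for (g in seq_len(n)) {
      ge <- genes[[g]]
      rate <- if (ge$group == "decay_at_8cell") design$gain_rate_target
              else design$gain_rate_other
      # each slot reserves a 24-nt span; cap well below the packing limit
      # so retries always find room despite fragmentation
      capacity <- max(0L, (ge$u3 - 20L) %/% 48L)
      n_slots <- min(stats::rpois(1L, rate), capacity)
      if (n_slots == 0L) next
      for (s in seq_len(n_slots)) {
        placed <- FALSE
        for (try in seq_len(40L)) {
          fi <- sample(nrow(fam_tab), 1L)
          pattern <- strsplit(fam_tab$pattern[fi], "")[[1L]]
          gpos_ok <- which(pattern[1:7] == "G")
          if (length(gpos_ok) == 0L) next
          q <- gpos_ok[sample.int(length(gpos_ok), 1L)]
          j <- sample(seq(2L, ge$u3 - 9L), 1L)   # utr coords of pattern start
          span <- (j - 8L):(j + 15L)             # pattern +/- 8 nt margin
          span <- span[span >= 1L & span <= ge$u3]
          if (any(ge$reserved[utr3_t0(ge) + span])) next
          planted <- pattern
          planted[q] <- "A"
          ge$chars[utr3_t0(ge) + (j:(j + 7L))] <- planted
          utr_str <- paste(ge$chars[(utr3_t0(ge) + 1L):ge$L], collapse = "")
          cls <- classify_edit_mbs(stats::setNames(utr_str, "t"),
                                   stats::setNames(j + q - 1L, "t"),
                                   families)
          if (cls$classification[cls$family_id == fam_tab$family_id[fi]] ==
                "gain") {
            ge$reserved[utr3_t0(ge) + span] <- TRUE
            genes[[g]] <- ge
            slot_rows[[length(slot_rows) + 1L]] <- data.frame(
              kind = "ree", gene_id = ge$id, region = "UTR3",
              utr_pos = j + q - 1L, t_pos = utr3_t0(ge) + j + q - 1L,
              family_id = fam_tab$family_id[fi], is_gain_slot = TRUE,
              stringsAsFactors = FALSE)
            placed <- TRUE
            break
          }
          # undo tentative write before retrying
          ge$chars <- genes[[g]]$chars
        }
        if (!placed) {
          stop("generate_reference: MBS-gain placement infeasible for gene ",
               ge$id, " (no verifiable slot position found)")
        }
      }
    }
    n_slots_total <- length(slot_rows)

    # --- plant plain edit placements -------------------------------------
    region_tpos <- function(ge, region) {
      switch(region,
             UTR3 = (utr3_t0(ge) + 2L):(ge$L - 1L),
             CDS = c((ge$u5 + 4L):(ge$u5 + ge$c1),
                     (ge$u5 + ge$c1 + ge$intr + 1L):(ge$L - ge$u3 - 3L)),
             intronic = (ge$u5 + ge$c1 + 2L):(ge$u5 + ge$c1 + ge$intr - 1L))
    }
    plant_site <- function(kind, base = "A", context = TRUE) {
      for (try in seq_len(400L)) {
        g <- sample(n, 1L)
        ge <- genes[[g]]
        region <- sample(c("UTR3", "CDS", "intronic"), 1L,
                         prob = c(0.6, 0.2, 0.2))
        cand <- region_tpos(ge, region)
        t <- cand[sample(length(cand), 1L)]
        if (any(ge$reserved[(t - 1L):(t + 1L)])) next
        ge$chars[t] <- base
        if (context) {
          ge$chars[t - 1L] <- sample(c("G", "C", "A", "T"), 1L,
                                     prob = c(design$context_g_minus1,
                                              rep((1 - design$context_g_minus1) / 3, 3)))
          ge$chars[t + 1L] <- sample(c("G", "C", "A", "T"), 1L,
                                     prob = c(design$context_g_plus1,
                                              rep((1 - design$context_g_plus1) / 3, 3)))
        }
        ge$reserved[(t - 1L):(t + 1L)] <- TRUE
        genes[[g]] <<- ge
        return(quick_df(list(kind = kind, gene_id = ge$id, region = region,
                             utr_pos = if (region == "UTR3") t - utr3_t0(ge)
                                       else NA_integer_,
                             t_pos = t, family_id = NA_character_,
                             is_gain_slot = FALSE)))
      }
      stop("generate_reference: placement infeasible (genome too crowded)")
    }
    n_plain_rees <- max(0L, design$n_rees - n_slots_total)
    plain <- lapply(seq_len(n_plain_rees), function(i) plant_site("ree"))
    n_nonag <- round(design$noise_nonag_fraction * design$n_noise)
    noise_ag <- lapply(seq_len(design$n_noise - n_nonag),
                       function(i) plant_site("noise"))
    noise_nonag <- lapply(seq_len(n_nonag),
                          function(i) plant_site("noise_nonag", base = "C",
                                                 context = FALSE))
    placements <- do.call(rbind, c(slot_rows, plain, noise_ag, noise_nonag))

    # --- SNP contaminants at untouched positions -------------------------
    snp_rows <- list()
    for (i in seq_len(design$n_snps)) {
      repeat {
        g <- sample(n, 1L)
        ge <- genes[[g]]
        t <- sample(ge$L - 2L, 1L) + 1L
        if (!any(ge$reserved[(t - 1L):(t + 1L)])) {
          ge$reserved[t] <- TRUE
          genes[[g]] <- ge
          snp_rows[[length(snp_rows) + 1L]] <- data.frame(
            kind = "snp", gene_id = ge$id, region = NA_character_,
            utr_pos = NA_integer_, t_pos = t, family_id = NA_character_,
            is_gain_slot = FALSE, stringsAsFactors = FALSE)
          break
        }
      }
    }
    placements <- rbind(placements, do.call(rbind, snp_rows))

    # --- assemble genome and model ---------------------------------------
    offsets <- stats::setNames(rep(0L, 3L), paste0("chr", 1:3))
    chrom_seqs <- stats::setNames(rep("", 3L), paste0("chr", 1:3))
    feats <- list()
    alu_iv <- list()
    for (g in seq_len(n)) {
      ge <- genes[[g]]
      gap <- rint(design$gap_len)
      gap_seq <- rand_dna(gap)
      gs <- offsets[[ge$chrom]] + gap + 1L
      locus <- paste(ge$chars, collapse = "")
      block <- if (ge$strand == "+") locus else revcomp_chr(locus)
      chrom_seqs[[ge$chrom]] <- paste0(chrom_seqs[[ge$chrom]], gap_seq, block)
      offsets[[ge$chrom]] <- gs + ge$L - 1L
      genes[[g]]$gstart <- gs
      genes[[g]]$gend <- gs + ge$L - 1L
      t2g <- function(t) if (ge$strand == "+") gs + t - 1L else
        gs + ge$L - t
      iv <- function(t1, t2) {
        a <- t2g(t1); b <- t2g(t2)
        c(min(a, b), max(a, b))
      }
      ex1 <- iv(1L, ge$u5 + ge$c1)
      ex2 <- iv(ge$u5 + ge$c1 + ge$intr + 1L, ge$L)
      cd1 <- iv(ge$u5 + 1L, ge$u5 + ge$c1)
      cd2 <- iv(ge$u5 + ge$c1 + ge$intr + 1L,
                ge$u5 + ge$c1 + ge$intr + ge$c2)
      tid <- paste0(ge$id, ".t1")
      feats[[g]] <- data.frame(
        gene_id = ge$id, gene_name = ge$id, transcript_id = tid,
        chrom = ge$chrom, strand = ge$strand,
        type = c("exon", "exon", "CDS", "CDS"),
        start = c(ex1[1L], ex2[1L], cd1[1L], cd2[1L]),
        end = c(ex1[2L], ex2[2L], cd1[2L], cd2[2L]),
        stringsAsFactors = FALSE)
      if (ge$alu) {
        u3iv <- iv(ge$L - ge$u3 + 1L, ge$L)
        alu_iv[[length(alu_iv) + 1L]] <- data.frame(
          chrom = ge$chrom, start = u3iv[1L], end = u3iv[2L])
      }
    }
    genome <- Biostrings::DNAStringSet(chrom_seqs)
    model <- gene_model(do.call(rbind, feats))
    alu_df <- do.call(rbind, c(alu_iv, list(data.frame(chrom = character(),
                                                       start = integer(),
                                                       end = integer()))))
    alu <- if (nrow(alu_df) > 0L) {
      GenomicRanges::reduce(GenomicRanges::GRanges(
        alu_df$chrom, IRanges::IRanges(alu_df$start, alu_df$end)))
    } else GenomicRanges::GRanges()

    # genomic coordinates, ref and alt for every placement
    gidx <- match(placements$gene_id, gene_ids)
    placements$chrom <- vapply(gidx, function(g) genes[[g]]$chrom, "")
    placements$strand <- vapply(gidx, function(g) genes[[g]]$strand, "")
    placements$pos <- mapply(function(g, t) {
      ge <- genes[[g]]
      if (ge$strand == "+") ge$gstart + t - 1L else ge$gstart + ge$L - t
    }, gidx, placements$t_pos)
    placements$ref <- mapply(function(chrom, pos) {
      as.character(Biostrings::subseq(genome[[chrom]], pos, pos))
    }, placements$chrom, placements$pos)
    tstrand_alt <- ifelse(placements$kind == "noise_nonag", "T", "G")
    placements$alt <- ifelse(placements$strand == "+", tstrand_alt,
                             complement_base(tstrand_alt))
    snp <- placements$kind == "snp"
    placements$alt[snp] <- vapply(placements$ref[snp], function(r) {
      sample(setdiff(c("A", "C", "G", "T"), r), 1L)
    }, character(1))
    placements$transcript_id <- paste0(placements$gene_id, ".t1")
    rownames(placements) <- NULL

    list(genome = genome, model = model, alu = alu,
         utrs = utr3_sequences(model, genome),
         gene_groups = data.frame(gene_id = gene_ids, group = group,
                                  stringsAsFactors = FALSE),
         placements = placements)
  })
}

#' Generate a synthetic microRNA family table
#'
#' Each family has 1-3 mature sequences sharing an identical 7-nt seed at
#' mature positions 2-8; seeds are unique across families and always
#' contain a cytosine among positions 2-7 (so that an A-to-G edit on a
#' target can complete a site, which the gain-slot planting relies on).
#'
#' @param design a [cohort_design].
#' @return a [mirna_families] table.
#' @export
generate_families <- function(design) {
  withr::with_seed(design$seed + 202L, {
    seeds <- character(0)
    while (length(seeds) < design$n_families) {
      s <- rand_dna(7L)
      if (!grepl("C", substr(s, 1L, 6L))) next   # positions 2-7 of the mature
      if (s %in% seeds) next                     # duplicate seed: regenerate
      seeds <- c(seeds, s)
    }
    rows <- lapply(seq_along(seeds), function(i) {
      k <- sample(3L, 1L)
      data.frame(family_id = sprintf("fam%02d", i), seed = seeds[i],
                 mature_id = sprintf("fam%02d-m%d", i, seq_len(k)),
                 mature_seq = vapply(seq_len(k), function(j) {
                   paste0(substr(rand_dna(1L), 1L, 1L), seeds[i],
                          rand_dna(13L))
                 }, character(1)),
                 stringsAsFactors = FALSE)
    })
    mirna_families(do.call(rbind, rows))
  })
}

sim_meta <- function(design) {
  rows <- list()
  for (st in design$stages) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("%s_N%02d", st, seq_len(design$n_normal)),
      stage = st, condition = "normal", stringsAsFactors = FALSE)
    conds <- if (is_oocyte_stage(st)) "elder_mother" else c("AG", "PG")
    for (cond in conds) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("%s_%s%02d", st, cond, seq_len(design$n_abnormal)),
        stage = st, condition = cond, stringsAsFactors = FALSE)
    }
  }
  sample_meta(do.call(rbind, rows), stages = design$stages)
}

draw_counts <- function(n_detect, an_mu, an_size, af, min_ac) {
  an <- 2L + stats::rnbinom(n_detect, size = an_size,
                            mu = max(an_mu - 2, 0.5))
  min_needed <- pmax(ceiling(0.1 * an), min_ac)
  ac <- stats::rbinom(n_detect, an, af)
  ac <- pmin(pmax(ac, min_needed), an)
  list(AC = as.integer(ac), AN = as.integer(an))
}

#' Generate per-sample variant tables, metadata and the truth manifest
#'
#' Plants each recurrent edit over a contiguous window of stages: within
#' the window it is detected in normal samples at the design probability
#' (truncated to stay at or above the recurrence threshold) and in each
#' abnormal group at least once, except for designated dropout edits,
#' which are never detected in their (stage, condition) group. After the
#' window, residual sub-threshold detections occur at the noise
#' probability. Noise edits stay below the recurrence threshold
#' everywhere; genomic contaminants appear as homozygous-like high-AF
#' variants at known-SNP positions in any sample. AC/AN are drawn from a
#' shifted negative-binomial coverage model with per-site beta editing
#' levels, constrained to pass the per-call filters.
#'
#' @param design a [cohort_design].
#' @param reference output of [generate_reference].
#' @param families a [mirna_families] table.
#' @return list: `meta` ([sample_meta]), `calls` ([edit_calls] for the
#'   whole cohort), `snp_positions` (data.frame), and `truth` manifest
#'   (planted REEs with stage windows and gain slots, per-stage REE site
#'   keys, noise sites, dropout designations, context parameters).
#' @export
generate_cohort <- function(design, reference, families) {
  withr::with_seed(design$seed + 303L, {
    meta <- sim_meta(design)
    stages <- design$stages
    n_stage <- length(stages)
    pl <- reference$placements
    rees <- pl[pl$kind == "ree", , drop = FALSE]
    noise <- pl[pl$kind %in% c("noise", "noise_nonag"), , drop = FALSE]
    snps <- pl[pl$kind == "snp", , drop = FALSE]
    thresh <- ceiling(design$ree_fraction * design$n_normal)

    # stage windows
    w_start <- sample(n_stage, nrow(rees), replace = TRUE)
    w_len <- 1L + stats::rgeom(nrow(rees), 0.35)
    w_end <- pmin(w_start + w_len, n_stage)
    rees$stage_first <- stages[w_start]
    rees$stage_last <- stages[w_end]
    rees$af <- 0.15 + 0.75 * stats::rbeta(nrow(rees), 2, 2)
    noise$af <- 0.15 + 0.75 * stats::rbeta(nrow(noise), 2, 2)

    # dropout designations: distinct REEs, one (stage, condition) each
    dropout <- data.frame(chrom = character(), pos = integer(),
                          stage = character(), condition = character())
    taken <- integer(0)
    for (cond in names(design$dropout)) {
      n_drop <- design$dropout[[cond]]
      if (n_drop == 0L) next
      ok_stage <- if (cond == "elder_mother") {
        is_oocyte_stage(stages)
      } else !is_oocyte_stage(stages)
      cand <- which(vapply(seq_len(nrow(rees)), function(i) {
        any(ok_stage[w_start[i]:w_end[i]])
      }, logical(1)))
      cand <- setdiff(cand, taken)
      if (length(cand) < n_drop) {
        stop("generate_cohort: not enough recurrent edits in eligible ",
             "stages to designate ", n_drop, " ", cond, " dropouts")
      }
      pick <- sample(cand, n_drop)
      taken <- c(taken, pick)
      st <- vapply(pick, function(i) {
        elig <- stages[w_start[i]:w_end[i]]
        elig <- elig[if (cond == "elder_mother") is_oocyte_stage(elig)
                     else !is_oocyte_stage(elig)]
        sample(elig, 1L)
      }, character(1))
      dropout <- rbind(dropout, data.frame(
        chrom = rees$chrom[pick], pos = rees$pos[pick], stage = st,
        condition = cond, stringsAsFactors = FALSE))
    }
    drop_key <- paste(dropout$chrom, dropout$pos, dropout$stage,
                      dropout$condition, sep = "\r")

    is_alu_site <- pos_in_mask(c(rees$chrom, noise$chrom),
                               c(rees$pos, noise$pos), reference$alu)
    rees$alu <- is_alu_site[seq_len(nrow(rees))]
    noise$alu <- is_alu_site[nrow(rees) + seq_len(nrow(noise))]

    calls <- list()
    emit <- function(site, sample_ids, af, min_ac) {
      if (length(sample_ids) == 0L) return()
      cnt <- draw_counts(length(sample_ids), design$an_mu, design$an_size,
                         af, min_ac)
      calls[[length(calls) + 1L]] <<- data.frame(
        sample_id = sample_ids, chrom = site$chrom, pos = site$pos,
        ref = site$ref, alt = site$alt, AC = cnt$AC, AN = cnt$AN,
        stringsAsFactors = FALSE)
    }

    by_group <- split(meta$sample_id, paste(meta$stage, meta$condition,
                                            sep = "\r"))
    for (i in seq_len(nrow(rees))) {
      site <- list(chrom = rees$chrom[i], pos = rees$pos[i],
                   ref = rees$ref[i], alt = rees$alt[i], af = rees$af[i])
      min_ac <- if (rees$alu[i]) 1L else 2L
      for (si in seq_len(n_stage)) {
        st <- stages[si]
        in_window <- si >= w_start[i] && si <= w_end[i]
        after <- si > w_end[i]
        # normal samples
        ids <- by_group[[paste(st, "normal", sep = "\r")]]
        if (in_window) {
          k <- rbinom_trunc(length(ids), design$ree_detect_prob, lo = thresh)
          emit(site, sample(ids, k), site$af, min_ac)
        } else if (after) {
          k <- rbinom_trunc(length(ids), design$noise_detect_prob,
                            hi = thresh - 1L)
          if (k > 0L) emit(site, sample(ids, k), site$af, min_ac)
        }
        # abnormal groups
        conds <- if (is_oocyte_stage(st)) "elder_mother" else c("AG", "PG")
        for (cond in conds) {
          ids <- by_group[[paste(st, cond, sep = "\r")]]
          if (is.null(ids)) next
          key <- paste(site$chrom, site$pos, st, cond, sep = "\r")
          if (key %in% drop_key) next
          if (in_window) {
            k <- rbinom_trunc(length(ids), design$ree_detect_prob, lo = 1L)
            emit(site, sample(ids, k), site$af, min_ac)
          } else if (after) {
            k <- stats::rbinom(1L, length(ids), design$noise_detect_prob)
            if (k > 0L) emit(site, sample(ids, k), site$af, min_ac)
          }
        }
      }
    }

    for (i in seq_len(nrow(noise))) {
      site <- list(chrom = noise$chrom[i], pos = noise$pos[i],
                   ref = noise$ref[i], alt = noise$alt[i], af = noise$af[i])
      min_ac <- if (noise$alu[i]) 1L else 2L
      for (grp in names(by_group)) {
        ids <- by_group[[grp]]
        normal <- endsWith(grp, "normal")
        hi <- if (normal) thresh - 1L else length(ids)
        k <- if (normal) {
          rbinom_trunc(length(ids), design$noise_detect_prob, hi = hi)
        } else stats::rbinom(1L, length(ids), design$noise_detect_prob)
        if (k > 0L) emit(site, sample(ids, k), site$af, min_ac)
      }
    }

    for (i in seq_len(nrow(snps))) {
      site <- list(chrom = snps$chrom[i], pos = snps$pos[i],
                   ref = snps$ref[i], alt = snps$alt[i])
      present <- meta$sample_id[stats::runif(nrow(meta)) <
                                  design$snp_detect_prob]
      if (length(present) == 0L) next
      an <- 8L + stats::rnbinom(length(present), size = design$an_size,
                                mu = design$an_mu)
      ac <- an - stats::rbinom(length(present), an, 0.03)
      k <- length(present)
      calls[[length(calls) + 1L]] <- quick_df(list(
        sample_id = present, chrom = rep_len(site$chrom, k),
        pos = rep_len(site$pos, k), ref = rep_len(site$ref, k),
        alt = rep_len(site$alt, k), AC = as.integer(ac),
        AN = as.integer(an)))
    }

    calls <- edit_calls(do.call(rbind, calls))
    ree_sites_by_stage <- lapply(stats::setNames(seq_len(n_stage), stages),
      function(si) {
        idx <- w_start <= si & w_end >= si
        paste0(rees$chrom[idx], ":", rees$pos[idx])
      })

    truth <- list(
      rees = rees[, c("chrom", "pos", "gene_id", "transcript_id", "region",
                      "utr_pos", "strand", "stage_first", "stage_last",
                      "is_gain_slot", "family_id", "alu", "af")],
      ree_sites_by_stage = ree_sites_by_stage,
      noise = noise[, c("chrom", "pos", "gene_id", "region", "kind")],
      snps = snps[, c("chrom", "pos", "ref", "alt")],
      dropout = dropout,
      context = list(g_minus1 = design$context_g_minus1,
                     g_plus1 = design$context_g_plus1))
    list(meta = meta, calls = calls,
         snp_positions = snps[, c("chrom", "pos")], truth = truth)
  })
}

#' Generate the synthetic FPKM expression matrix
#'
#' Clearance-target genes are given oocyte medians about `decay_fold` times
#' their 8-cell median; other maternal genes keep a flat profile; planted
#' non-maternal genes stay below the maternal threshold in both oocyte
#' stages. Log-normal noise is applied per sample, per-sample expression
#' is coupled negatively to the editing level of the gene's first planted
#' recurrent edit, and group definitions are then enforced exactly on the
#' empirical medians (deterministic per-stage rescaling), so the planted
#' clearance annotation is recovered by construction.
#'
#' @param design a [cohort_design].
#' @param reference output of [generate_reference].
#' @param cohort output of [generate_cohort].
#' @return numeric matrix, genes x samples (FPKM).
#' @export
generate_expression <- function(design, reference, cohort) {
  withr::with_seed(design$seed + 404L, {
    meta <- cohort$meta
    groups <- reference$gene_groups
    genes <- groups$gene_id
    base <- design$expr_base * exp(stats::rnorm(length(genes), 0,
                                                design$expr_sdlog))
    oocyte <- is_oocyte_stage(meta$stage)
    expr <- matrix(0, nrow = length(genes), ncol = nrow(meta),
                   dimnames = list(genes, meta$sample_id))
    for (i in seq_along(genes)) {
      grp <- groups$group[i]
      mu_oo <- switch(grp, decay_at_8cell = base[i], others = base[i],
                      not_maternal = 1)
      mu_late <- switch(grp, decay_at_8cell = base[i] / design$decay_fold,
                        others = base[i], not_maternal = 1)
      mu <- ifelse(oocyte, mu_oo, mu_late)
      expr[i, ] <- mu * exp(stats::rnorm(nrow(meta), 0, design$expr_sdlog))
    }
    # editing-expression coupling through the gene's first recurrent edit
    rees <- cohort$truth$rees
    first_ree <- rees[!duplicated(rees$gene_id), , drop = FALSE]
    calls <- cohort$calls
    ckey <- paste(site_key(calls), calls$sample_id, sep = "\r")
    for (i in seq_len(nrow(first_ree))) {
      g <- first_ree$gene_id[i]
      skey <- paste0(first_ree$chrom[i], ":", first_ree$pos[i])
      af <- calls$AF[match(paste(skey, colnames(expr), sep = "\r"), ckey)]
      af[is.na(af)] <- 0
      expr[g, ] <- expr[g, ] * (1 - design$coupling * af)
    }
    # enforce the planted group definitions on the empirical medians
    # (only meaningful when the cohort carries the three defining stages)
    if (all(c("oocyte_GV", "oocyte_MII", "8cell") %in%
              meta$stage[meta$condition == "normal"])) {
      med <- function(g, stage) {
        ids <- meta$sample_id[meta$stage == stage & meta$condition == "normal"]
        stats::median(expr[g, ids])
      }
      cells8 <- meta$sample_id[meta$stage == "8cell" &
                                 meta$condition == "normal"]
      for (i in seq_along(genes)) {
        g <- genes[i]
        grp <- groups$group[i]
        m_gv <- med(g, "oocyte_GV"); m_mii <- med(g, "oocyte_MII")
        m_8 <- med(g, "8cell")
        lo <- min(m_gv, m_mii)
        if (grp == "decay_at_8cell") {
          if (!(lo > 2 * m_8) && m_8 > 0) {
            expr[g, cells8] <- expr[g, cells8] * lo / (2.5 * m_8)
          }
        } else if (grp == "others") {
          if (lo > 2 * m_8) {
            expr[g, cells8] <- expr[g, cells8] * lo / (1.5 * max(m_8, 1e-6))
          }
        } else {
          for (st in c("oocyte_GV", "oocyte_MII")) {
            m <- med(g, st)
            if (m > 2) {
              ids <- meta$sample_id[meta$stage == st &
                                      meta$condition == "normal"]
              expr[g, ids] <- expr[g, ids] * 1.5 / m
            }
          }
        }
      }
    }
    expr
  })
}

#' Generate a complete synthetic cohort
#'
#' Orchestrates [generate_families], [generate_reference],
#' [generate_cohort] and [generate_expression]; the result is a pure
#' function of the design.
#'
#' @param design a [cohort_design].
#' @return list: `design`, `families`, `reference`, `meta`, `calls`,
#'   `truth`, `fpkm`.
#' @export
simulate_cohort <- function(design = cohort_design()) {
  families <- generate_families(design)
  reference <- generate_reference(design, families)
  cohort <- generate_cohort(design, reference, families)
  fpkm <- generate_expression(design, reference, cohort)
  list(design = design, families = families, reference = reference,
       meta = cohort$meta, calls = cohort$calls, truth = cohort$truth,
       snp_positions = cohort$snp_positions, fpkm = fpkm)
}

#' Write a simulated cohort to plain-text files
#'
#' Emits `genome.fa`, `model.gtf`, `alu.bed`, `utrs.fa`, `families.tsv`,
#' `calls.tsv`, `meta.tsv`, `fpkm.tsv`, `snps.tsv` and `truth.json` under
#' `dir`.
#'
#' @param sim output of [simulate_cohort].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$reference$genome,
                              file.path(dir, "genome.fa"))
  write_gene_model_gtf(sim$reference$model, file.path(dir, "model.gtf"))
  write_interval_mask(sim$reference$alu, file.path(dir, "alu.bed"))
  Biostrings::writeXStringSet(sim$reference$utrs, file.path(dir, "utrs.fa"))
  tsv <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  tsv(sim$families, "families.tsv")
  tsv(as.data.frame(sim$calls), "calls.tsv")
  tsv(as.data.frame(sim$meta), "meta.tsv")
  tsv(sim$snp_positions, "snps.tsv")
  fp <- data.frame(gene_id = rownames(sim$fpkm), sim$fpkm,
                   check.names = FALSE)
  tsv(fp, "fpkm.tsv")
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Count-level simulation of per-(gene, sample) MBS-gain statistics
#'
#' Calibration mode for the clearance-enrichment test: draws the
#' per-(gene, sample) counts of observed MBS-gaining edits directly, as
#' independent Poisson counts thinned by the detection probability,
#' without building sequences. With `rate_target == rate_other` this is
#' the generator's null (no planted excess).
#'
#' @param n_target,n_other numbers of clearance-target and other maternal
#'   genes.
#' @param n_samples samples per gene.
#' @param rate_target,rate_other expected planted MBS-gaining edits per
#'   gene.
#' @param detect_prob per-sample detection probability.
#' @return list of numeric vectors `x` (targets) and `y` (others).
#' @export
simulate_pair_counts <- function(n_target, n_other, n_samples,
                                 rate_target, rate_other,
                                 detect_prob = 0.9) {
  draw <- function(n_genes, rate) {
    stats::rpois(n_genes * n_samples, rate * detect_prob)
  }
  list(x = draw(n_target, rate_target), y = draw(n_other, rate_other))
}
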