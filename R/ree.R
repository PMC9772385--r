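#' Detect Recurrent Embryonic Edits (REEs) for one stage
#'
#' An edit site is an REE of a stage when it is observed (i.e. passed the
#' per-call filters) in at least `ree_fraction` of the stage's normal
#' samples. Abnormal samples enter neither the numerator nor the
#' denominator; the denominator is all normal samples of the stage
#' regardless of per-site coverage.
#'
#' @param per_sample_edits data.frame of accepted per-sample calls with
#'   `chrom`, `pos`, `sample_id`.
#' @param meta a [sample_meta] table.
#' @param stage stage to evaluate.
#' @param ree_fraction recurrence threshold in `[0, 1]` (default 0.5).
#' @return data.frame in the `ree` schema: `stage`, `chrom`, `pos`,
#'   `n_observed`, `n_samples`, `fraction`, with attribute `ree_fraction`.
#' @export
detect_rees <- function(per_sample_edits, meta, stage, ree_fraction = 0.5) {
  normal <- meta$sample_id[meta$stage == stage & meta$condition == "normal"]
  if (length(normal) == 0L) {
    stop("detect_rees: stage '", stage, "' has no normal samples")
  }
  obs <- per_sample_edits[per_sample_edits$sample_id %in% normal, , drop = FALSE]
  obs <- unique(obs[, c("chrom", "pos", "sample_id")])
  if (nrow(obs) == 0L) {
    out <- data.frame(stage = character(), chrom = character(),
                      pos = integer(), n_observed = integer(),
                      n_samples = integer(), fraction = numeric())
    attr(out, "ree_fraction") <- ree_fraction
    return(out)
  }
  counts <- table(site_key(obs))
  sites <- unique(obs[, c("chrom", "pos")])
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  n_obs <- as.integer(counts[site_key(sites)])
  frac <- n_obs / length(normal)
  keep <- frac >= ree_fraction
  k <- sum(keep)
  out <- data.frame(stage = rep_len(stage, k), chrom = sites$chrom[keep],
                    pos = sites$pos[keep], n_observed = n_obs[keep],
                    n_samples = rep_len(length(normal), k),
                    fraction = frac[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "ree_fraction") <- ree_fraction
  out
}

#' Detect REE-targeted genes for one stage
#'
#' A gene is REE-targeted in a stage when at least one of its REEs is
#' observed in at least `gene_fraction` of the stage's normal samples (the
#' union over the gene's REEs is taken within each sample).
#'
#' @param rees output of [detect_rees] for the stage.
#' @param per_sample_edits accepted per-sample calls (`chrom`, `pos`,
#'   `sample_id`).
#' @param meta a [sample_meta] table.
#' @param annotation data.frame mapping sites to genes: `chrom`, `pos`,
#'   `gene_id` (a site may map to several genes).
#' @param gene_fraction threshold in `[0, 1]` (default 0.8).
#' @return data.frame per gene carrying >= 1 REE: `gene_id`,
#'   `n_samples_with_ree`, `n_samples`, `fraction`, `targeted`.
#' @export
detect_ree_targeted_genes <- function(rees, per_sample_edits, meta,
                                      annotation, gene_fraction = 0.8) {
  stage <- unique(rees$stage)
  normal <- meta$sample_id[meta$stage %in% stage & meta$condition == "normal"]
  ree_keys <- site_key(rees)
  ann <- annotation[site_key(annotation) %in% ree_keys, , drop = FALSE]
  if (nrow(ann) == 0L) {
    return(data.frame(gene_id = character(), n_samples_with_ree = integer(),
                      n_samples = integer(), fraction = numeric(),
                      targeted = logical()))
  }
  obs <- per_sample_edits[per_sample_edits$sample_id %in% normal &
                            site_key(per_sample_edits) %in% ree_keys, ,
                          drop = FALSE]
  obs <- unique(obs[, c("chrom", "pos", "sample_id")])
  okey <- site_key(obs)
  genes <- sort(unique(ann$gene_id))
  res <- lapply(genes, function(g) {
    gkeys <- site_key(ann[ann$gene_id == g, , drop = FALSE])
    n_with <- length(unique(obs$sample_id[okey %in% gkeys]))
    data.frame(gene_id = g, n_samples_with_ree = n_with,
               n_samples = length(normal),
               fraction = n_with / length(normal),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$targeted <- out$fraction >= gene_fraction
  rownames(out) <- NULL
  attr(out, "gene_fraction") <- gene_fraction
  out
}

#' Persistence of REEs across a stage transition
#'
#' Classifies every REE of the source stage by its fate in the target
#' stage: still an REE (`remained_REE`), observed in at least one normal
#' target-stage sample but below the recurrence threshold
#' (`detected_not_REE`), or not observed at all (`not_detected`). The three
#' counts always sum to the size of the source REE set.
#'
#' @param rees_source,rees_target outputs of [detect_rees] for the two
#'   stages.
#' @param per_sample_edits_target accepted per-sample calls.
#' @param meta a [sample_meta] table.
#' @return list with `counts` (named integer vector) and `per_site`
#'   (data.frame of source REEs with `fate`).
#' @export
stage_flow <- function(rees_source, rees_target, per_sample_edits_target,
                       meta) {
  target_stage <- unique(rees_target$stage)
  normal <- meta$sample_id[meta$stage %in% target_stage &
                             meta$condition == "normal"]
  obs <- per_sample_edits_target[
    per_sample_edits_target$sample_id %in% normal, , drop = FALSE]
  src <- site_key(rees_source)
  fate <- ifelse(src %in% site_key(rees_target), "remained_REE",
                 ifelse(src %in% site_key(obs), "detected_not_REE",
                        "not_detected"))
  counts <- c(remained_REE = sum(fate == "remained_REE"),
              detected_not_REE = sum(fate == "detected_not_REE"),
              not_detected = sum(fate == "not_detected"))
  per_site <- rees_source[, c("chrom", "pos")]
  per_site$fate <- fate
  list(counts = counts, per_site = per_site)
}

#' Correlation between REE editing level and target-gene expression
#'
#' For each REE mapped to one gene, correlates the per-sample editing level
#' (AF; 0 in samples where the edit was not observed) with the gene's
#' per-sample expression, over the supplied samples. Rank-based (Spearman)
#' by default.
#'
#' @param ree_af data.frame with `chrom`, `pos`, `sample_id`, `AF`.
#' @param fpkm numeric matrix, genes x samples.
#' @param gene_map data.frame mapping each REE to one gene: `chrom`, `pos`,
#'   `gene_id`.
#' @param samples sample ids to pair over.
#' @param method correlation method (default `"spearman"`).
#' @return data.frame per REE: `chrom`, `pos`, `gene_id`, `n`, `rho`,
#'   `reason` (`NA` when defined; otherwise why the coefficient is
#'   undefined).
#' @export
ree_expression_correlation <- function(ree_af, fpkm, gene_map, samples,
                                       method = "spearman") {
  akey <- paste(site_key(ree_af), ree_af$sample_id, sep = "\r")
  out <- lapply(seq_len(nrow(gene_map)), function(i) {
    g <- gene_map$gene_id[i]
    skey <- paste0(gene_map$chrom[i], ":", gene_map$pos[i])
    row <- data.frame(chrom = gene_map$chrom[i], pos = gene_map$pos[i],
                      gene_id = g, n = length(samples), rho = NA_real_,
                      reason = NA_character_, stringsAsFactors = FALSE)
    if (!g %in% rownames(fpkm)) {
      row$reason <- "gene_not_in_expression_matrix"
      return(row)
    }
    af <- ree_af$AF[match(paste(skey, samples, sep = "\r"), akey)]
    af[is.na(af)] <- 0
    expr <- fpkm[g, samples]
    if (length(samples) < 3L) {
      row$reason <- "fewer_than_3_paired_observations"
    } else if (stats::sd(af) == 0) {
      row$reason <- "constant_editing_level"
    } else if (stats::sd(expr) == 0) {
      row$reason <- "constant_expression"
    } else {
      row$rho <- suppressWarnings(stats::cor(af, expr, method = method))
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' The default condition-specific loss-scan groups
#'
#' Twelve (stage, abnormal condition) pairs: elder-mother oocytes at both
#' oocyte stages, and androgenetic/parthenogenetic embryos at zygote, 2-cell,
#' 4-cell, 8-cell and morula.
#'
#' @return data.frame with `stage` and `condition`.
#' @export
default_loss_groups <- function() {
  rbind(
    data.frame(stage = c("oocyte_GV", "oocyte_MII"),
               condition = "elder_mother", stringsAsFactors = FALSE),
    expand.grid(stage = c("zygote", "2cell", "4cell", "8cell", "morula"),
                condition = c("AG", "PG"), stringsAsFactors = FALSE)
  )
}

#' Scan for condition-specific loss of REEs
#'
#' For each (stage, condition) group, reports the stage's REEs that are
#' detected in at most `max_detection_fraction` of the group's abnormal
#' samples (default 0: complete loss, i.e. not detected in any sample of
#' the group). The result is the union over groups, one row per (REE,
#' group).
#'
#' @param rees_by_stage data.frame of REEs across stages (rows as returned
#'   by [detect_rees], possibly concatenated).
#' @param abnormal_edits accepted per-sample calls for the cohort (abnormal
#'   samples are selected via `meta`).
#' @param meta a [sample_meta] table.
#' @param group_specs data.frame with `stage`, `condition` (default: the 12
#'   groups of [default_loss_groups]).
#' @param max_detection_fraction maximum tolerated detection fraction within
#'   a group (default 0).
#' @return data.frame in the `loss_scan` schema: `chrom`, `pos`, `stage`,
#'   `condition`, `n_group_samples`, `n_detected`.
#' @export
scan_loss <- function(rees_by_stage, abnormal_edits, meta,
                      group_specs = default_loss_groups(),
                      max_detection_fraction = 0) {
  out <- list()
  for (i in seq_len(nrow(group_specs))) {
    st <- as.character(group_specs$stage[i])
    cond <- as.character(group_specs$condition[i])
    grp <- meta$sample_id[meta$stage == st & meta$condition == cond]
    if (length(grp) == 0L) {
      warning("scan_loss: group (", st, ", ", cond,
              ") has no samples; skipped")
      next
    }
    rees <- rees_by_stage[rees_by_stage$stage == st, , drop = FALSE]
    if (nrow(rees) == 0L) next
    obs <- abnormal_edits[abnormal_edits$sample_id %in% grp, , drop = FALSE]
    obs <- unique(obs[, c("chrom", "pos", "sample_id")])
    counts <- table(site_key(obs))
    n_det <- as.integer(counts[site_key(rees)])
    n_det[is.na(n_det)] <- 0L
    keep <- n_det <= max_detection_fraction * length(grp)
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      chrom = rees$chrom[keep], pos = rees$pos[keep], stage = st,
      condition = cond, n_group_samples = length(grp),
      n_detected = n_det[keep], stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      stage = character(), condition = character(),
                      n_group_samples = integer(), n_detected = integer()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
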