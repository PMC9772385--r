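#' Construct and validate a table of per-sample edit calls
#'
#' An edit-call table is the package's central flat container: one row per
#' candidate (or accepted) editing event in one sample. Positions are 1-based
#' genomic coordinates on the forward strand of the reference. `AF` is always
#' recomputed as `AC / AN`; any `AF` column supplied by the caller is ignored,
#' so the read counts are the single source of truth for the editing level.
#'
#' @param df data.frame with columns `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `AC`, `AN`.
#' @return A validated data.frame of class `edit_calls` with the canonical
#'   column order and an `AF` column equal to `AC / AN`.
#' @examples
#' edit_calls(data.frame(sample_id = "s1", chrom = "chr1", pos = 100L,
#'                       ref = "A", alt = "G", AC = 3L, AN = 10L))
#' @export
edit_calls <- function(df) {
  required <- c("sample_id", "chrom", "pos", "ref", "alt", "AC", "AN")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("edit_calls: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[, required, drop = FALSE]
  df$sample_id <- as.character(df$sample_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  df$AC <- as.integer(df$AC)
  df$AN <- as.integer(df$AN)
  validate_edit_calls(df)
  df$AF <- df$AC / df$AN
  class(df) <- c("edit_calls", "data.frame")
  df
}

validate_edit_calls <- function(df, line = NULL) {
  where <- function(i) {
    if (is.null(line)) paste0("row ", i) else paste0("line ", line[i])
  }
  bad <- which(!(df$ref %in% c("A", "C", "G", "T")) |
                 !(df$alt %in% c("A", "C", "G", "T")))
  if (length(bad) > 0L) {
    stop("edit_calls: non-ACGT ref/alt at ", where(bad[1L]))
  }
  bad <- which(is.na(df$pos) | df$pos < 1L)
  if (length(bad) > 0L) {
    stop("edit_calls: invalid position at ", where(bad[1L]))
  }
  bad <- which(is.na(df$AN) | df$AN < 1L)
  if (length(bad) > 0L) {
    stop("edit_calls: AN must be >= 1 at ", where(bad[1L]))
  }
  bad <- which(is.na(df$AC) | df$AC < 0L | df$AC > df$AN)
  if (length(bad) > 0L) {
    stop("edit_calls: AC must satisfy 0 <= AC <= AN at ", where(bad[1L]))
  }
  invisible(df)
}

#' Site keys for edit positions
#'
#' @param x data.frame with `chrom` and `pos` columns.
#' @return character vector `"chrom:pos"` identifying each genomic site.
#' @keywords internal
#' @export
site_key <- function(x) paste0(x$chrom, ":", x$pos)

#' Read per-sample candidate edit calls
#'
#' Reads a candidate variant table in either a minimal VCF dialect (CHROM,
#' POS, ID, REF, ALT, QUAL, FILTER, INFO with `AC=` and `AN=` keys) or a
#' headered TSV with columns `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#' `AC`, `AN`. The editing level `AF` is recomputed from `AC/AN`; a
#' malformed record raises an error naming its line number.
#'
#' @param path file path.
#' @param dialect `"vcf_subset"` or `"tsv"`.
#' @param sample_id sample identifier attached to every record when the file
#'   itself carries none (required for `vcf_subset`; for `tsv`, overrides the
#'   file's `sample_id` column if supplied).
#' @return An [edit_calls] data.frame (possibly zero rows).
#' @export
read_edit_calls <- function(path, dialect = c("vcf_subset", "tsv"),
                            sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_edit_calls: no such file: ", path)
  lines <- readLines(path)
  if (dialect == "vcf_subset") {
    if (is.null(sample_id)) {
      stop("read_edit_calls: sample_id is required for the vcf_subset dialect")
    }
    keep <- !grepl("^#", lines) & nzchar(lines)
    lineno <- which(keep)
    body <- lines[keep]
    if (length(body) == 0L) {
      return(empty_edit_calls())
    }
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 8L)) {
      stop("read_edit_calls: malformed VCF record (fewer than 8 fields) at line ",
           lineno[which(nf < 8L)[1L]])
    }
    get <- function(i) vapply(fields, `[[`, "", i)
    info <- get(8L)
    ac <- info_value(info, "AC")
    an <- info_value(info, "AN")
    bad <- which(is.na(ac) | is.na(an))
    if (length(bad) > 0L) {
      stop("read_edit_calls: INFO field without numeric AC and AN at line ",
           lineno[bad[1L]])
    }
    pos <- suppressWarnings(as.integer(get(2L)))
    bad <- which(is.na(pos))
    if (length(bad) > 0L) {
      stop("read_edit_calls: non-integer POS at line ", lineno[bad[1L]])
    }
    df <- data.frame(sample_id = sample_id, chrom = get(1L), pos = pos,
                     ref = toupper(get(4L)), alt = toupper(get(5L)),
                     AC = ac, AN = an, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (nrow(df) == 0L) return(empty_edit_calls())
    if (!is.null(sample_id)) df$sample_id <- sample_id
    if (!"sample_id" %in% names(df)) {
      stop("read_edit_calls: tsv dialect needs a sample_id column or argument")
    }
    lineno <- seq_len(nrow(df)) + 1L  # header occupies line 1
  }
  required <- c("sample_id", "chrom", "pos", "ref", "alt", "AC", "AN")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("read_edit_calls: missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df$pos <- as.integer(df$pos)
  df$AC <- as.integer(df$AC)
  df$AN <- as.integer(df$AN)
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  if (dialect == "vcf_subset") {
    validate_edit_calls(df, line = lineno)
  } else {
    validate_edit_calls(df, line = lineno)
  }
  edit_calls(df)
}

empty_edit_calls <- function() {
  edit_calls(data.frame(sample_id = character(), chrom = character(),
                        pos = integer(), ref = character(), alt = character(),
                        AC = integer(), AN = integer(),
                        stringsAsFactors = FALSE))
}

info_value <- function(info, key) {
  pattern <- paste0("(?:^|;)", key, "=([0-9]+)")
  m <- regmatches(info, regexec(pattern, info))
  vapply(m, function(x) {
    if (length(x) == 2L) suppressWarnings(as.integer(x[[2L]])) else NA_integer_
  }, integer(1))
}

#' Write per-sample edit calls in the minimal VCF dialect
#'
#' @param calls an [edit_calls] table for a single sample.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edit_calls_vcf <- function(calls, path) {
  header <- c("##fileformat=VCFv4.2",
              "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Edited read count\">",
              "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Read coverage\">",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tAC=%d;AN=%d",
                  calls$chrom, calls$pos, calls$ref, calls$alt,
                  calls$AC, calls$AN)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read sample metadata
#'
#' @param path TSV with columns `sample_id`, `stage`, `condition`.
#' @param stages ordered character vector of allowed stages.
#' @return validated data.frame of class `sample_meta`.
#' @export
read_sample_meta <- function(path, stages = default_stages()) {
  sample_meta(utils::read.delim(path, stringsAsFactors = FALSE),
              stages = stages)
}

#' Developmental stages in their default temporal order
#'
#' @return character vector of stage names, ordered from germinal-vesicle
#'   oocyte to morula.
#' @export
default_stages <- function() {
  c("oocyte_GV", "oocyte_MII", "zygote", "2cell", "4cell", "8cell", "morula")
}

#' Conditions recognised in sample metadata
#'
#' `normal` samples drive edit/REE definitions; the remaining conditions are
#' abnormal groups (androgenetic, parthenogenetic, elder-mother oocytes,
#' non-control treatment).
#' @return character vector.
#' @export
conditions <- function() c("normal", "AG", "PG", "elder_mother", "treated")

#' Construct and validate sample metadata
#'
#' @param df data.frame with `sample_id`, `stage`, `condition`.
#' @param stages ordered vector of allowed stage names.
#' @return data.frame of class `sample_meta` with a `stages` attribute
#'   preserving the configured order.
#' @export
sample_meta <- function(df, stages = default_stages()) {
  required <- c("sample_id", "stage", "condition")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("sample_meta: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[, required, drop = FALSE]
  df$sample_id <- as.character(df$sample_id)
  df$stage <- as.character(df$stage)
  df$condition <- as.character(df$condition)
  if (anyDuplicated(df$sample_id)) {
    stop("sample_meta: duplicated sample_id: ",
         df$sample_id[anyDuplicated(df$sample_id)])
  }
  bad <- setdiff(unique(df$stage), stages)
  if (length(bad) > 0L) {
    stop("sample_meta: stage not in configured list: ",
         paste(bad, collapse = ", "))
  }
  bad <- setdiff(unique(df$condition), conditions())
  if (length(bad) > 0L) {
    stop("sample_meta: unknown condition: ", paste(bad, collapse = ", "))
  }
  attr(df, "stages") <- stages
  class(df) <- c("sample_meta", "data.frame")
  df
}
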