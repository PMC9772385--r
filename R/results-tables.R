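#' Registered result-table schemas
#'
#' Each pipeline product is written as a headered TSV with a fixed column
#' order and a deterministic row sort, so results round-trip losslessly and
#' diff cleanly between runs.
#'
#' @return named list: for each schema, its column names, column classes and
#'   sort keys.
#' @export
result_schemas <- function() {
  list(
    ree = list(
      columns = c(stage = "character", chrom = "character", pos = "integer",
                  n_observed = "integer", n_samples = "integer",
                  fraction = "numeric"),
      sort = c("stage", "chrom", "pos")
    ),
    loss_scan = list(
      columns = c(chrom = "character", pos = "integer", stage = "character",
                  condition = "character", n_group_samples = "integer",
                  n_detected = "integer"),
      sort = c("stage", "condition", "chrom", "pos")
    ),
    mbs_delta = list(
      columns = c(chrom = "character", pos = "integer", gene_id = "character",
                  family_id = "character", classification = "character",
                  n_introduced = "integer", n_removed = "integer"),
      sort = c("chrom", "pos", "gene_id", "family_id")
    ),
    stats = list(
      columns = c(test = "character", group = "character", n_x = "integer",
                  n_y = "integer", statistic = "numeric", p_value = "numeric",
                  p_adjusted = "numeric", estimate = "numeric",
                  conf_low = "numeric"),
      sort = c("test", "group")
    )
  )
}

#' Write a result table under a registered schema
#'
#' @param records data.frame conforming to one of [result_schemas].
#' @param path output path.
#' @param schema_name one of `names(result_schemas())`.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path, schema_name) {
  schema <- result_schemas()[[schema_name]]
  if (is.null(schema)) stop("write_results_table: unknown schema: ", schema_name)
  cols <- names(schema$columns)
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols) > 0L) {
    stop("write_results_table: records missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records)[, cols, drop = FALSE]
  if (nrow(records) > 0L) {
    ord <- do.call(order, c(unname(records[schema$sort]), list(method = "radix")))
    records <- records[ord, , drop = FALSE]
  }
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a result table written by [write_results_table]
#'
#' @param path file path.
#' @param schema_name one of `names(result_schemas())`.
#' @return data.frame with the schema's column classes.
#' @export
read_results_table <- function(path, schema_name) {
  schema <- result_schemas()[[schema_name]]
  if (is.null(schema)) stop("read_results_table: unknown schema: ", schema_name)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = unname(schema$columns))
  names(df) <- names(schema$columns)
  df
}
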