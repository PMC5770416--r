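#' Read / write a log2 expression matrix as TSV
#'
#' The on-disk format is tab-separated UTF-8 with a `feature_id` first column
#' and one column per sample; decimal point is `.`.
#'
#' @param path File path.
#' @return `read_expression_tsv()` returns a numeric matrix with feature row
#'   names and sample column names.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "feature_id")
    stop("expression TSV must have 'feature_id' as its first column: ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$feature_id
  storage.mode(m) <- "double"
  assert_expression_matrix(m, paste0("expression matrix (", path, ")"))
  m
}

#' @param m Numeric feature x sample matrix.
#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample sheet as TSV
#'
#' Columns: `sample_id`, `patient_id`, `site` (NBI/WL/T), `platform`
#' (miRNA/mRNA), `included` (1 = array passed QC, 0 = excluded).
#'
#' @param path File path.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  sheet$included <- as.integer(sheet$included)
  sheet$patient_id <- as.integer(sheet$patient_id)
  assert_sample_sheet(sheet)
  sheet
}

#' @param sheet Sample sheet data.frame.
#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a validated miRNA-target interaction catalog as TSV
#'
#' Required columns `mirna_id`, `mrna_id`; optional `evidence` and genomic
#' coordinate columns (`mirna_chrom`, `mirna_start`, `mirna_end`,
#' `mrna_chrom`, `mrna_start`, `mrna_end`) used for link-table output.
#'
#' @param path File path.
#' @export
read_catalog_tsv <- function(path) {
  cat_df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_catalog(cat_df)
  cat_df
}

#' @param catalog Catalog data.frame.
#' @rdname read_catalog_tsv
#' @export
write_catalog_tsv <- function(catalog, path) {
  utils::write.table(catalog, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_catalog <- function(catalog) {
  if (!is.data.frame(catalog) ||
      !all(c("mirna_id", "mrna_id") %in% names(catalog)))
    stop("catalog must be a data.frame with columns mirna_id, mrna_id")
  if (anyDuplicated(pair_key(catalog$mirna_id, catalog$mrna_id)))
    stop("catalog contains duplicate (mirna, mrna) pairs")
  for (side in c("mirna", "mrna")) {
    s <- catalog[[paste0(side, "_start")]]
    e <- catalog[[paste0(side, "_end")]]
    if (!is.null(s) && !is.null(e)) {
      ok <- is.na(s) | is.na(e) | (s >= 0 & s < e)
      if (!all(ok)) stop("catalog ", side, " coordinates must satisfy ",
                         "0 <= start < end")
    }
  }
  invisible(catalog)
}
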