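#' Write the signature table as TSV
#'
#' Columns `mirna`, `mrna`, `r`, `padj`, `stability` (printed to 2 decimals),
#' `class`, `de_direction_TvsWL`, `de_direction_TvsNBI` (mRNA direction in the
#' tumour-vs-margin comparisons) and `spatial_only`; rows sorted reciprocal
#' first, then by descending stability. An empty signature writes a
#' header-only file.
#'
#' @param sig Signature from [assemble_signature()].
#' @param path Output file.
#' @export
write_signature_table <- function(sig, path) {
  out <- data.frame(mirna = sig$mirna_id, mrna = sig$mrna_id,
                    r = signif(sig$r, 4), padj = signif(sig$padj, 4),
                    stability = sprintf("%.2f", sig$stability),
                    class = sig$class,
                    de_direction_TvsWL = sig$mrna_de_T_vs_WL,
                    de_direction_TvsNBI = sig$mrna_de_T_vs_NBI,
                    spatial_only = sig$spatial_only,
                    stringsAsFactors = FALSE)
  if (nrow(out) > 0) {
    out <- out[order(match(out$class, c("reciprocal", "nonreciprocal")),
                     -sig$stability), , drop = FALSE]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a Circos-style link table for the signature
#'
#' One whitespace-tab link record per signature pair with genomic coordinates
#' for both members in the catalog:
#' `chromA startA endA chromB startB endB class stability`. Pairs lacking
#' either coordinate set are skipped and counted in a message.
#'
#' @param sig Signature from [assemble_signature()].
#' @param catalog Interaction catalog carrying the coordinate columns.
#' @param path Output file.
#' @return Invisibly, the number of link lines written.
#' @export
write_circos_links <- function(sig, catalog, path) {
  coord_cols <- c("mirna_chrom", "mirna_start", "mirna_end",
                  "mrna_chrom", "mrna_start", "mrna_end")
  if (!all(coord_cols %in% names(catalog)))
    stop("catalog lacks coordinate columns required for link output")
  i <- match(pair_key(sig$mirna_id, sig$mrna_id),
             pair_key(catalog$mirna_id, catalog$mrna_id))
  co <- catalog[i, coord_cols, drop = FALSE]
  ok <- !is.na(i) & stats::complete.cases(co)
  n_skipped <- sum(!ok)
  if (n_skipped > 0)
    message(n_skipped, " signature pair(s) lack coordinates; skipped")
  links <- data.frame(co[ok, c("mirna_chrom", "mirna_start", "mirna_end",
                               "mrna_chrom", "mrna_start", "mrna_end")],
                      class = sig$class[ok],
                      stability = sprintf("%.2f", sig$stability[ok]))
  utils::write.table(links, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(nrow(links))
}

# Write every pipeline result table plus the provenance log into out_dir.
# Files are staged so a failure leaves no partial output behind.
write_run_outputs <- function(result, catalog, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop("writing outputs failed (partial outputs removed): ",
         conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    emit <- function(obj, file, writer = NULL) {
      path <- file.path(out_dir, file)
      if (is.null(writer)) {
        utils::write.table(obj, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      } else {
        writer(obj, path)
      }
      written <<- c(written, path)
      path
    }
    for (pl in names(result$de))
      emit(result$de[[pl]], paste0("de_", tolower(pl), ".tsv"))
    venn_df <- do.call(rbind, lapply(names(result$venn), function(pl)
      data.frame(platform = pl, region = names(result$venn[[pl]]),
                 count = as.integer(result$venn[[pl]]))))
    emit(venn_df, "venn_counts.tsv")
    for (pl in names(result$pca)) {
      if (is.null(result$pca[[pl]])) next
      sc <- data.frame(sample_id = rownames(result$pca[[pl]]$scores),
                       result$pca[[pl]]$scores)
      emit(sc, paste0("pca_scores_", tolower(pl), ".tsv"))
    }
    if (nrow(result$integration$correlations) > 0)
      emit(result$integration$correlations, "correlations.tsv")
    if (nrow(result$stability) > 0)
      emit(result$stability, "stability.tsv")
    emit(result$signature, "signature.tsv", write_signature_table)
    path <- file.path(out_dir, "circos_links.tsv")
    write_circos_links(result$signature, catalog, path)
    written <- c(written, path)
    prov <- paste0(names(result$provenance), ": ", result$provenance)
    writeLines(prov, file.path(out_dir, "provenance.log"))
    written <- c(written, file.path(out_dir, "provenance.log"))
    invisible(written)
  }, error = on_fail)
}
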