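#' Coefficient-of-variation filter
#'
#' Removes features whose coefficient of variation (sample SD over mean,
#' computed on the log2 intensity scale with the n-1 denominator) falls below
#' `threshold`. This reproduces the preliminary filter that removes
#' near-invariant probes before differential expression; with the
#' conventional threshold of 0.1, probes with CV < 0.1 across all arrays are
#' dropped.
#'
#' @param m Numeric feature x sample matrix of log2 intensities.
#' @param threshold Minimum CV retained (default 0.1). Features with
#'   CV >= `threshold` are kept, order preserved.
#' @return The filtered matrix.
#' @export
cv_filter <- function(m, threshold = 0.1) {
  assert_expression_matrix(m)
  if (ncol(m) < 2) stop("CV filter requires at least 2 samples per feature")
  mu <- rowMeans(m)
  if (any(mu <= 0))
    stop("non-positive row mean for feature(s): ",
         paste(utils::head(rownames(m)[mu <= 0], 5), collapse = ", "))
  cv <- apply(m, 1, stats::sd) / mu
  m[cv >= threshold, , drop = FALSE]
}

#' Quantile normalization
#'
#' Forces every column to share the same empirical distribution: each value is
#' replaced by the mean, across columns, of the values at its rank, with ties
#' assigned the average over the tied ranks (via
#' [limma::normalizeQuantiles()]). Idempotent; a single-column matrix is
#' returned unchanged with a warning.
#'
#' @param m Numeric feature x sample matrix; no missing values.
#' @return The normalized matrix with the input dimnames.
#' @export
quantile_normalize <- function(m) {
  assert_expression_matrix(m)
  if (ncol(m) == 1) {
    warning("single-column matrix: quantile normalization is a no-op")
    return(m)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Patients with both members of a paired comparison included
#'
#' For a site comparison such as `"T_vs_NBI"`, returns the patients whose
#' arrays at *both* sites passed QC on the given platform -- the set over
#' which paired differences can be formed.
#'
#' @param sheet Sample sheet (see [read_sample_sheet()]).
#' @param comparison One of `"T_vs_WL"`, `"T_vs_NBI"`, `"WL_vs_NBI"`.
#' @param platform `"miRNA"` or `"mRNA"`.
#' @return Sorted integer vector of patient ids.
#' @export
complete_pairs <- function(sheet, comparison, platform = PLATFORMS) {
  assert_sample_sheet(sheet)
  platform <- match.arg(platform)
  sites <- comparison_sites(comparison)
  sub <- sheet[sheet$platform == platform & sheet$included == 1L &
                 sheet$site %in% sites, ]
  tab <- table(sub$patient_id)
  sort(as.integer(names(tab)[tab == 2L]))
}

#' Collapse probes to gene-level features
#'
#' Where several probes map to one gene symbol, keeps the probe with maximal
#' sample variance and renames it to the gene.
#'
#' @param m Feature x sample matrix with probe row names.
#' @param probe_to_gene Named character vector: names are probe ids, values
#'   gene symbols. Probes absent from the map are kept under their own id.
#' @return Gene-level matrix.
#' @export
collapse_probes <- function(m, probe_to_gene) {
  assert_expression_matrix(m)
  gene <- probe_to_gene[rownames(m)]
  gene[is.na(gene)] <- rownames(m)[is.na(gene)]
  v <- apply(m, 1, stats::var)
  ord <- order(gene, -v)
  keep <- ord[!duplicated(gene[ord])]
  out <- m[sort(keep), , drop = FALSE]
  rownames(out) <- gene[sort(keep)]
  out
}

#' QC inclusion pattern of the 18-patient OSCC margin cohort
#'
#' The per-array quality-control verdicts of the three-site, two-platform
#' oral squamous cell carcinoma margin study this package models: all tumour
#' and white-light mRNA arrays passed, five NBI mRNA arrays failed, and ten
#' miRNA arrays failed (one T, one WL, eight NBI). Useful as a realistic
#' pairing structure for examples and tests.
#'
#' @return A sample sheet data.frame (see [read_sample_sheet()]).
#' @export
oscc_qc_sheet <- function() {
  flags <- list(
    mRNA = list(T = rep(1L, 18),
                WL = rep(1L, 18),
                NBI = c(1L,1L,1L,1L,0L,0L,0L,1L,1L,1L,1L,0L,0L,1L,1L,1L,1L,1L)),
    miRNA = list(T = c(1L,1L,1L,1L,1L,1L,1L,1L,1L,1L,1L,1L,0L,1L,1L,1L,1L,1L),
                 WL = c(1L,1L,1L,1L,1L,1L,1L,1L,1L,1L,1L,1L,1L,0L,1L,1L,1L,1L),
                 NBI = c(1L,1L,1L,1L,1L,0L,0L,1L,0L,1L,0L,1L,1L,1L,0L,0L,0L,0L)))
  rows <- do.call(rbind, lapply(PLATFORMS, function(pl) {
    do.call(rbind, lapply(SITES, function(s) {
      data.frame(sample_id = sprintf("P%03d_%s_%s", 1:18, s, pl),
                 patient_id = 1:18, site = s, platform = pl,
                 included = flags[[pl]][[s]], stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  assert_sample_sheet(rows)
  rows
}
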