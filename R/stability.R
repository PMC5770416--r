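#' Stability Rate of a cross-validated selection
#'
#' Fraction of leave-one-patient-out folds in which a miRNA-mRNA pair was
#' selected, rounded to two decimals for reporting (so 6 of 18 folds reports
#' 0.33 and 18 of 18 reports 1.0); set `digits = NULL` for the exact
#' fraction. Inclusion decisions elsewhere in the package always use the
#' exact fraction.
#'
#' @param selected_count Folds in which the pair was selected.
#' @param total_folds Total folds (> 0).
#' @param digits Reporting precision (default 2); `NULL` = exact.
#' @return Numeric stability rate(s).
#' @export
stability_rate <- function(selected_count, total_folds, digits = 2) {
  if (any(total_folds == 0)) stop("total_folds must be >= 1")
  if (any(selected_count < 0 | selected_count > total_folds))
    stop("selected_count must be between 0 and total_folds")
  s <- selected_count / total_folds
  if (is.null(digits)) s else round(s, digits)
}

#' Leave-one-patient-out selection counts for candidate pairs
#'
#' Omits each patient in turn, rebuilds the matched observation blocks, refits
#' the sPLS model with the sparsity tuned on the full data, and counts, for
#' every full-data candidate pair, the folds in which it is selected again.
#' A fold that loses an entire biopsy site is skipped with a warning and
#' `total_folds` reduced accordingly.
#'
#' @inheritParams integrate_mirna_mrna
#' @param candidates Full-data candidate pairs
#'   (from [integrate_mirna_mrna()]).
#' @param keepY Sparsity fixed from the full-data tuning.
#' @return data.frame of stability records: `mirna_id`, `mrna_id`,
#'   `selected_count`, `total_folds`, `stability` (exact fraction).
#' @export
loocv_selection_counts <- function(mirna_m, mrna_m, sheet, catalog, de_mirnas,
                                   candidates, keepY,
                                   mode = c("per_sample", "site_median"),
                                   n_comp = 3, keepX = NULL) {
  mode <- match.arg(mode)
  patients <- sort(unique(sheet$patient_id))
  if (length(patients) < 3) stop("need at least 3 patients for LOOCV")
  if (nrow(candidates) == 0)
    return(data.frame(mirna_id = character(0), mrna_id = character(0),
                      selected_count = integer(0), total_folds = integer(0),
                      stability = numeric(0)))
  keys <- pair_key(candidates$mirna_id, candidates$mrna_id)
  counts <- stats::setNames(integer(length(keys)), keys)
  total <- 0L
  skipped <- integer(0)
  for (p in patients) {
    fold <- tryCatch(
      integrate_mirna_mrna(mirna_m, mrna_m, sheet, catalog, de_mirnas,
                           mode = mode, n_comp = n_comp, keepX = keepX,
                           keepY = keepY, patients = setdiff(patients, p)),
      error = function(e) e)
    if (inherits(fold, "error")) {
      skipped <- c(skipped, p)
      next
    }
    total <- total + 1L
    fk <- pair_key(fold$candidates$mirna_id, fold$candidates$mrna_id)
    hit <- keys %in% fk
    counts[hit] <- counts[hit] + 1L
  }
  if (length(skipped) > 0)
    warning("skipped fold(s) for patient(s) ",
            paste(skipped, collapse = ", "),
            " (a biopsy site lost all matched samples); total_folds = ",
            total)
  out <- data.frame(mirna_id = candidates$mirna_id,
                    mrna_id = candidates$mrna_id,
                    selected_count = unname(counts),
                    total_folds = total,
                    stability = unname(counts) / total,
                    stringsAsFactors = FALSE)
  attr(out, "skipped_patients") <- skipped
  out
}

#' Assemble the stability-validated miRNA-mRNA signature
#'
#' Joins stability records with the spatial correlation records and retains
#' pairs with `stability >= stability_min` (inclusive, on the exact fraction)
#' and `padj < fdr_max`, annotating the linkage class (sign of r), the DE
#' direction of each member in the T-vs-WL and T-vs-NBI comparisons, and a
#' `spatial_only` flag for interactions whose mRNA is not differentially
#' expressed in any pairwise comparison -- pairs discovered only through the
#' spatial axis.
#'
#' @param stability_records From [loocv_selection_counts()].
#' @param correlations Correlation records (with `padj`) from
#'   [integrate_mirna_mrna()].
#' @param de_mirna_table,de_mrna_table DE tables from [de_all_comparisons()].
#' @param stability_min Minimum Stability Rate (default 0.5, inclusive).
#' @param fdr_max Maximum BH-adjusted correlation p-value (default 0.05,
#'   strict).
#' @param de_alpha DE threshold used for the direction annotations.
#' @return Signature data.frame sorted by class (reciprocal first) then
#'   descending stability.
#' @export
assemble_signature <- function(stability_records, correlations,
                               de_mirna_table = NULL, de_mrna_table = NULL,
                               stability_min = 0.5, fdr_max = 0.05,
                               de_alpha = 0.01) {
  empty <- data.frame(mirna_id = character(0), mrna_id = character(0),
                      r = numeric(0), p = numeric(0), padj = numeric(0),
                      n_points = integer(0), selected_count = integer(0),
                      total_folds = integer(0), stability = numeric(0),
                      class = character(0),
                      mirna_de_T_vs_WL = character(0),
                      mirna_de_T_vs_NBI = character(0),
                      mrna_de_T_vs_WL = character(0),
                      mrna_de_T_vs_NBI = character(0),
                      spatial_only = logical(0), stringsAsFactors = FALSE)
  if (is.null(stability_records) || nrow(stability_records) == 0 ||
      is.null(correlations) || nrow(correlations) == 0)
    return(empty)
  sig <- merge(stability_records, correlations,
               by = c("mirna_id", "mrna_id"))
  sig <- sig[!is.na(sig$padj) & !sig$undefined &
               sig$stability >= stability_min & sig$padj < fdr_max, ,
             drop = FALSE]
  if (nrow(sig) == 0) return(empty)
  sig$class <- classify_linkage(sig$r)

  direction <- function(de_table, ids, comparison) {
    if (is.null(de_table) || nrow(de_table) == 0)
      return(rep("ns", length(ids)))
    sub <- de_table[de_table$comparison == comparison, ]
    i <- match(ids, sub$feature_id)
    dir <- ifelse(!is.na(i) & sub$padj[i] < de_alpha,
                  ifelse(sub$mean_diff[i] > 0, "up", "down"), "ns")
    dir
  }
  sig$mirna_de_T_vs_WL <- direction(de_mirna_table, sig$mirna_id, "T_vs_WL")
  sig$mirna_de_T_vs_NBI <- direction(de_mirna_table, sig$mirna_id, "T_vs_NBI")
  sig$mrna_de_T_vs_WL <- direction(de_mrna_table, sig$mrna_id, "T_vs_WL")
  sig$mrna_de_T_vs_NBI <- direction(de_mrna_table, sig$mrna_id, "T_vs_NBI")
  de_mrnas <- select_de_features(de_mrna_table, de_alpha)
  sig$spatial_only <- !(sig$mrna_id %in% de_mrnas)

  sig <- sig[order(match(sig$class, c("reciprocal", "nonreciprocal")),
                   -sig$stability, sig$mirna_id, sig$mrna_id), ,
             drop = FALSE]
  rownames(sig) <- NULL
  sig[, names(empty)]
}
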