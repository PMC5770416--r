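`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

SITES <- c("NBI", "WL", "T")
PLATFORMS <- c("miRNA", "mRNA")
COMPARISONS <- c("T_vs_WL", "T_vs_NBI", "WL_vs_NBI")

# Split a comparison label like "T_vs_NBI" into its two site tokens,
# first token = the "A" side of the difference A - B.
comparison_sites <- function(comparison) {
  if (!(is.character(comparison) && length(comparison) == 1 &&
        comparison %in% COMPARISONS)) {
    stop("unknown comparison label: ", paste(comparison, collapse = ", "),
         "; must be one of ", paste(COMPARISONS, collapse = ", "))
  }
  strsplit(comparison, "_vs_", fixed = TRUE)[[1]]
}

assert_expression_matrix <- function(m, what = "expression matrix") {
  if (!is.matrix(m) || !is.numeric(m)) stop(what, " must be a numeric matrix")
  if (nrow(m) == 0 || ncol(m) == 0) stop(what, " is empty")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop(what, " must have unique row (feature) names")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    stop(what, " must have unique column (sample) names")
  if (anyNA(m) || any(!is.finite(m)))
    stop(what, " contains missing or non-finite values; values must be ",
         "complete log2 intensities")
  invisible(m)
}

assert_sample_sheet <- function(sheet) {
  needed <- c("sample_id", "patient_id", "site", "platform", "included")
  if (!is.data.frame(sheet) || !all(needed %in% names(sheet)))
    stop("sample sheet must be a data.frame with columns ",
         paste(needed, collapse = ", "))
  if (!all(sheet$site %in% SITES))
    stop("sample sheet sites must be in {", paste(SITES, collapse = ", "), "}")
  if (!all(sheet$platform %in% PLATFORMS))
    stop("sample sheet platforms must be in {",
         paste(PLATFORMS, collapse = ", "), "}")
  key <- paste(sheet$patient_id, sheet$site, sheet$platform)
  if (anyDuplicated(key))
    stop("duplicate (patient, site, platform) rows in sample sheet")
  if (!all(sheet$included %in% c(0L, 1L)))
    stop("'included' must be 0/1")
  invisible(sheet)
}

pair_key <- function(mirna, mrna) paste(mirna, mrna, sep = "\t")
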