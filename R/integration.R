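#' Map differentially expressed miRNAs to validated, measured targets
#'
#' Restricts the interaction catalog to pairs whose miRNA is in the DE set and
#' whose target mRNA is present in the measured mRNA universe; DE miRNAs with
#' no catalog entry at all are reported separately.
#'
#' @param de_mirnas Character vector of DE miRNA ids.
#' @param catalog Interaction catalog data.frame (`mirna_id`, `mrna_id`, ...).
#' @param mrna_universe Character vector of measured mRNA ids.
#' @return List with `pairs` (catalog subset) and `unmapped` (DE miRNAs with
#'   no catalog entry).
#' @export
map_validated_targets <- function(de_mirnas, catalog, mrna_universe) {
  validate_catalog(catalog)
  de_mirnas <- unique(de_mirnas)
  keep <- catalog$mirna_id %in% de_mirnas &
    catalog$mrna_id %in% mrna_universe
  pairs <- catalog[keep, , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       unmapped = sort(setdiff(de_mirnas, catalog$mirna_id)))
}

#' Median expression profile per biopsy site
#'
#' Per feature, the median across patients within each site, ordered along
#' the spatial axis NBI, WL, T.
#'
#' @param m Feature x sample log2 matrix.
#' @param sheet Sample sheet.
#' @param platform Platform of `m`.
#' @param patients Optional patient subset.
#' @return Feature x 3 matrix with columns `NBI`, `WL`, `T`.
#' @export
site_median_profile <- function(m, sheet, platform = PLATFORMS,
                                patients = NULL) {
  assert_expression_matrix(m)
  assert_sample_sheet(sheet)
  platform <- match.arg(platform)
  sub <- sheet[sheet$platform == platform & sheet$included == 1L &
                 sheet$sample_id %in% colnames(m), ]
  if (!is.null(patients)) sub <- sub[sub$patient_id %in% patients, ]
  prof <- sapply(SITES, function(s) {
    ids <- sub$sample_id[sub$site == s]
    if (length(ids) == 0) stop("site ", s, " has no included ", platform,
                               " samples")
    apply(m[, ids, drop = FALSE], 1, stats::median)
  })
  # sapply drops to a vector for single-feature input; always return a matrix
  matrix(prof, nrow = nrow(m), dimnames = list(rownames(m), SITES))
}

#' Patient-site observations present on both platforms
#'
#' The integration uses only biopsies with both a miRNA and an mRNA array
#' included. Returns one row per matched (patient, site) with the sample id
#' on each platform.
#'
#' @param sheet Sample sheet.
#' @return data.frame with `patient_id`, `site`, `mirna_sample`,
#'   `mrna_sample`.
#' @export
matched_observations <- function(sheet) {
  assert_sample_sheet(sheet)
  inc <- sheet[sheet$included == 1L, ]
  mi <- inc[inc$platform == "miRNA", c("patient_id", "site", "sample_id")]
  mr <- inc[inc$platform == "mRNA", c("patient_id", "site", "sample_id")]
  names(mi)[3] <- "mirna_sample"; names(mr)[3] <- "mrna_sample"
  mm <- merge(mi, mr, by = c("patient_id", "site"))
  mm <- mm[order(mm$patient_id, match(mm$site, SITES)), ]
  rownames(mm) <- NULL
  mm
}

# Build the observation x feature blocks for integration.
# per_sample: rows are matched (patient, site) biopsies.
# site_median: rows are the three site medians over the matched biopsies.
build_integration_matrices <- function(mirna_m, mrna_m, sheet, mirnas, mrnas,
                                       mode = c("per_sample", "site_median"),
                                       patients = NULL) {
  mode <- match.arg(mode)
  mm <- matched_observations(sheet)
  mm <- mm[mm$mirna_sample %in% colnames(mirna_m) &
             mm$mrna_sample %in% colnames(mrna_m), ]
  if (!is.null(patients)) mm <- mm[mm$patient_id %in% patients, ]
  if (any(!SITES %in% mm$site))
    stop("site(s) ", paste(setdiff(SITES, mm$site), collapse = ", "),
         " have no matched biopsies")
  if (mode == "per_sample") {
    X <- t(mirna_m[mirnas, mm$mirna_sample, drop = FALSE])
    Y <- t(mrna_m[mrnas, mm$mrna_sample, drop = FALSE])
    obs <- sprintf("P%03d_%s", mm$patient_id, mm$site)
    rownames(X) <- rownames(Y) <- obs
  } else {
    med <- function(m, samples, feats) {
      sapply(SITES, function(s) {
        ids <- samples[mm$site == s]
        apply(m[feats, ids, drop = FALSE], 1, stats::median)
      })
    }
    X <- t(med(mirna_m, mm$mirna_sample, mirnas))
    Y <- t(med(mrna_m, mm$mrna_sample, mrnas))
    rownames(X) <- rownames(Y) <- SITES
  }
  list(X = X, Y = Y, observations = mm)
}

#' Catalog-validated pairs selected on a common sPLS component
#'
#' Pairs (miRNA, mRNA) such that the miRNA has a nonzero X-loading and the
#' mRNA a nonzero Y-loading on the *same* component, and the pair is present
#' in the validated catalog.
#'
#' @param model Fitted [spls_fit()] model.
#' @param catalog Interaction catalog.
#' @return data.frame `mirna_id`, `mrna_id`, `component` (first component on
#'   which the pair is selected), deduplicated.
#' @export
extract_candidate_pairs <- function(model, catalog) {
  validate_catalog(catalog)
  cat_keys <- pair_key(catalog$mirna_id, catalog$mrna_id)
  out <- list()
  for (h in seq_len(model$n_comp)) {
    ms <- rownames(model$X_loadings)[model$X_loadings[, h] != 0]
    gs <- rownames(model$Y_loadings)[model$Y_loadings[, h] != 0]
    if (length(ms) == 0 || length(gs) == 0) next
    grid <- expand.grid(mirna_id = ms, mrna_id = gs,
                        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    grid <- grid[pair_key(grid$mirna_id, grid$mrna_id) %in% cat_keys, ,
                 drop = FALSE]
    if (nrow(grid)) {
      grid$component <- h
      out[[h]] <- grid
    }
  }
  if (length(out) == 0)
    return(data.frame(mirna_id = character(0), mrna_id = character(0),
                      component = integer(0)))
  res <- do.call(rbind, out)
  res <- res[!duplicated(pair_key(res$mirna_id, res$mrna_id)), , drop = FALSE]
  res <- res[order(res$mirna_id, res$mrna_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Pearson correlation of a miRNA-mRNA pair along the spatial axis
#'
#' Product-moment correlation over the matched observations (default) or the
#' three site medians, with a two-sided p-value from the t transform on
#' `n_points - 2` degrees of freedom. When `patients` is supplied (per-sample
#' mode), the repeated-measures form is used instead: both vectors are
#' centered within patient before the product-moment formula and the test has
#' `n_points - k - 1` degrees of freedom for `k` patients, which respects the
#' clustering of the 2-3 biopsies contributed by each patient. A
#' zero-variance member yields a record flagged `undefined`, which is
#' excluded from the FDR set.
#'
#' @param x,y Numeric vectors of matched miRNA / mRNA values.
#' @param mirna_id,mrna_id Pair labels.
#' @param mode `"per_sample"` or `"site_median"` (recorded in the output).
#' @param patients Optional vector of patient ids, one per observation,
#'   switching on the repeated-measures (within-patient centered) form.
#' @return One-row data.frame: `mirna_id`, `mrna_id`, `r`, `p`, `df`, `mode`,
#'   `n_points`, `undefined`.
#' @export
spatial_pearson <- function(x, y, mirna_id = "miRNA", mrna_id = "mRNA",
                            mode = c("per_sample", "site_median"),
                            patients = NULL) {
  mode <- match.arg(mode)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 matched points")
  undefined_rec <- function() {
    data.frame(mirna_id = mirna_id, mrna_id = mrna_id, r = NA_real_,
               p = NA_real_, df = NA_real_, mode = mode, n_points = n,
               undefined = TRUE, stringsAsFactors = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(undefined_rec())
  if (is.null(patients)) {
    ct <- stats::cor.test(x, y, method = "pearson",
                          alternative = "two.sided")
    return(data.frame(mirna_id = mirna_id, mrna_id = mrna_id,
                      r = unname(ct$estimate), p = ct$p.value,
                      df = n - 2, mode = mode, n_points = n,
                      undefined = FALSE, stringsAsFactors = FALSE))
  }
  if (length(patients) != n)
    stop("patients must have one entry per observation")
  xc <- x - stats::ave(x, patients)
  yc <- y - stats::ave(y, patients)
  df <- n - length(unique(patients)) - 1
  if (df < 1 || stats::sd(xc) == 0 || stats::sd(yc) == 0)
    return(undefined_rec())
  r <- stats::cor(xc, yc)
  tstat <- r * sqrt(df) / sqrt(1 - r^2)
  data.frame(mirna_id = mirna_id, mrna_id = mrna_id, r = r,
             p = 2 * stats::pt(-abs(tstat), df = df), df = df, mode = mode,
             n_points = n, undefined = FALSE, stringsAsFactors = FALSE)
}

# Correlation records for a set of candidate pairs, BH-adjusted over the
# defined records only.
correlate_pairs <- function(pairs, X, Y, mode, patients = NULL) {
  recs <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    spatial_pearson(X[, pairs$mirna_id[i]], Y[, pairs$mrna_id[i]],
                    pairs$mirna_id[i], pairs$mrna_id[i], mode,
                    patients = patients)
  }))
  recs$padj <- NA_real_
  ok <- !recs$undefined
  recs$padj[ok] <- bh_adjust(recs$p[ok])
  recs
}

#' Classify a correlated interaction as reciprocal or non-reciprocal
#'
#' Reciprocal (negative correlation, consistent with direct miRNA repression)
#' iff `r < 0`; non-reciprocal iff `r > 0`; the measure-zero case `r = 0` is
#' classed non-reciprocal with a warning.
#'
#' @param r Pearson correlation coefficient(s).
#' @return Character vector in `{"reciprocal", "nonreciprocal"}`.
#' @export
classify_linkage <- function(r) {
  if (anyNA(r)) stop("cannot classify an undefined correlation")
  if (any(r == 0)) warning("r exactly 0 classified as nonreciprocal")
  ifelse(r < 0, "reciprocal", "nonreciprocal")
}

#' Sparse-PLS integration of DE miRNAs with validated targets
#'
#' One integration pass: maps DE miRNAs onto the validated catalog, builds the
#' matched observation blocks, tunes `keepY` by leave-one-out prediction error
#' (unless fixed), fits the sPLS model, extracts catalog-validated pairs
#' selected on a common component, and tests each pair's spatial Pearson
#' correlation with BH FDR over the candidate set.
#'
#' @param mirna_m,mrna_m Feature x sample log2 matrices.
#' @param sheet Sample sheet.
#' @param catalog Interaction catalog.
#' @param de_mirnas DE miRNA ids (from [select_de_features()]).
#' @param mode Correlation/observation mode; `"per_sample"` (default) uses all
#'   matched biopsies, `"site_median"` the three site medians.
#' @param patient_adjust In per-sample mode, use the repeated-measures
#'   correlation (within-patient centering, `n - k - 1` df) rather than
#'   treating biopsies from the same patient as independent (default TRUE).
#' @param n_comp Number of sPLS components (default 3).
#' @param keepX Predictors retained per component (default all).
#' @param keepY_grid Grid for tuning `keepY`; ignored when `keepY` is given.
#' @param keepY Fixed `keepY` (skips tuning).
#' @param patients Optional patient subset (used by the LOOCV driver).
#' @return List with `pairs` (mapped catalog subset), `unmapped`, `X`, `Y`,
#'   `keepY`, `loo_mse`, `model`, `candidates` and `correlations`. When no DE
#'   miRNA maps to a measured target, the integration is empty but
#'   well-formed.
#' @export
integrate_mirna_mrna <- function(mirna_m, mrna_m, sheet, catalog, de_mirnas,
                                 mode = c("per_sample", "site_median"),
                                 patient_adjust = TRUE,
                                 n_comp = 3, keepX = NULL,
                                 keepY_grid = NULL, keepY = NULL,
                                 patients = NULL) {
  mode <- match.arg(mode)
  empty <- list(
    pairs = data.frame(mirna_id = character(0), mrna_id = character(0)),
    unmapped = character(0), X = NULL, Y = NULL, keepY = NA_integer_,
    loo_mse = NULL, model = NULL,
    candidates = data.frame(mirna_id = character(0), mrna_id = character(0),
                            component = integer(0)),
    correlations = data.frame(mirna_id = character(0), mrna_id = character(0),
                              r = numeric(0), p = numeric(0), df = numeric(0),
                              mode = character(0), n_points = integer(0),
                              undefined = logical(0), padj = numeric(0)),
    mode = mode)
  if (length(de_mirnas) == 0) return(empty)
  mapped <- map_validated_targets(de_mirnas, catalog, rownames(mrna_m))
  if (nrow(mapped$pairs) == 0) {
    empty$unmapped <- mapped$unmapped
    return(empty)
  }
  mirnas <- sort(intersect(unique(mapped$pairs$mirna_id), rownames(mirna_m)))
  mrnas <- sort(unique(mapped$pairs$mrna_id))
  if (length(mirnas) == 0) return(empty)
  blocks <- build_integration_matrices(mirna_m, mrna_m, sheet, mirnas, mrnas,
                                       mode, patients)
  loo <- NULL
  if (is.null(keepY)) {
    if (!is.null(keepY_grid) && length(keepY_grid) > 0 &&
        nrow(blocks$X) >= 3) {
      loo <- tune_spls_keepy(blocks$X, blocks$Y, keepY_grid,
                             keepX = keepX %||% ncol(blocks$X),
                             n_comp = n_comp)
      keepY <- loo$keepY
    } else {
      keepY <- ncol(blocks$Y)
    }
  }
  model <- spls_fit(blocks$X, blocks$Y, keepX = keepX %||% ncol(blocks$X),
                    keepY = keepY, n_comp = n_comp)
  candidates <- extract_candidate_pairs(model, catalog)
  corr_patients <- if (mode == "per_sample" && patient_adjust)
    blocks$observations$patient_id else NULL
  correlations <- if (nrow(candidates) > 0) {
    correlate_pairs(candidates, blocks$X, blocks$Y, mode,
                    patients = corr_patients)
  } else empty$correlations
  list(pairs = mapped$pairs, unmapped = mapped$unmapped,
       X = blocks$X, Y = blocks$Y, keepY = keepY,
       loo_mse = loo$loo_mse, model = model, candidates = candidates,
       correlations = correlations, mode = mode)
}
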