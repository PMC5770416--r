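#' Pipeline configuration
#'
#' Bundles the thresholds and options of the end-to-end margin analysis:
#' CV filter minimum 0.1, DE significance `padj < 0.01`, correlation FDR
#' `padj < 0.05`, Stability Rate `>= 0.5`.
#'
#' @param cv_min Minimum coefficient of variation retained.
#' @param de_alpha DE threshold on adjusted p-values (strict `<`).
#' @param corr_fdr FDR threshold on spatial correlations (strict `<`).
#' @param stability_min Minimum Stability Rate (inclusive).
#' @param corr_mode `"per_sample"` (default) or `"site_median"`.
#' @param patient_adjust Use the repeated-measures (within-patient centered)
#'   correlation in per-sample mode (default TRUE).
#' @param n_comp sPLS components (default 6).
#' @param keepY_grid Grid of `keepY` values tuned by leave-one-out error;
#'   `NULL` keeps all response features.
#' @param quantile_norm Apply quantile normalization before filtering.
#' @param seed Seed recorded in the provenance log (the pipeline itself is
#'   deterministic given its inputs).
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(cv_min = 0.1, de_alpha = 0.01, corr_fdr = 0.05,
                            stability_min = 0.5,
                            corr_mode = c("per_sample", "site_median"),
                            patient_adjust = TRUE,
                            n_comp = 6, keepY_grid = c(10, 20, 40, 80),
                            quantile_norm = TRUE, seed = 1L) {
  corr_mode <- match.arg(corr_mode)
  stopifnot(cv_min >= 0, de_alpha > 0, de_alpha <= 1, corr_fdr > 0,
            corr_fdr <= 1, stability_min >= 0, stability_min <= 1,
            n_comp >= 1)
  structure(list(cv_min = cv_min, de_alpha = de_alpha, corr_fdr = corr_fdr,
                 stability_min = stability_min, corr_mode = corr_mode,
                 patient_adjust = isTRUE(patient_adjust),
                 n_comp = n_comp, keepY_grid = keepY_grid,
                 quantile_norm = quantile_norm, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as plain `key = value` text
#'
#' @param path File path.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  cfg <- pipeline_config()
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (!k %in% names(cfg)) stop("unknown config key: ", k)
    cfg[[k]] <- switch(k,
                       corr_mode = vals[i],
                       keepY_grid = as.numeric(strsplit(vals[i], ",")[[1]]),
                       quantile_norm = as.logical(vals[i]),
                       patient_adjust = as.logical(vals[i]),
                       seed = as.integer(vals[i]),
                       n_comp = as.integer(vals[i]),
                       as.numeric(vals[i]))
  }
  do.call(pipeline_config, unclass(cfg))
}

#' @param cfg A [pipeline_config()].
#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(cfg, path) {
  fmt <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    paste0(k, " = ", paste(v, collapse = ","))
  }, "")
  writeLines(fmt, path)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full margin integration pipeline
#'
#' Executes preprocessing (optional quantile normalization, CV filter),
#' paired moderated-t differential expression for the three site comparisons
#' on both platforms, Venn partitioning and PCA of the DE features, sPLS
#' integration of DE miRNAs with validated targets, spatial Pearson
#' correlation with BH FDR, leave-one-patient-out stability selection, and
#' signature assembly. With `out_dir`, all result tables and a provenance log
#' are written as TSV/plain text; on a stage error no partial outputs remain.
#'
#' @param mirna,mrna Feature x sample log2 matrices.
#' @param sheet Sample sheet covering both platforms.
#' @param catalog Validated interaction catalog.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return List with elements `de` (per-platform DE tables), `de_features`,
#'   `venn`, `pca`, `integration`, `stability`, `signature`, `provenance`.
#' @export
run_pipeline <- function(mirna, mrna, sheet, catalog,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  assert_sample_sheet(sheet)
  validate_catalog(catalog)

  pre <- stage("preprocess", {
    prep <- function(m) {
      assert_expression_matrix(m)
      if (config$quantile_norm) m <- quantile_normalize(m)
      cv_filter(m, config$cv_min)
    }
    list(mirna = prep(mirna), mrna = prep(mrna))
  })

  de <- stage("diffexpr", {
    lapply(stats::setNames(PLATFORMS, PLATFORMS), function(pl) {
      m <- if (pl == "miRNA") pre$mirna else pre$mrna
      de_all_comparisons(m, sheet, platform = pl, alpha = config$de_alpha)
    })
  })
  de_features <- lapply(de, select_de_features, alpha = config$de_alpha)

  venn <- stage("venn", {
    lapply(de, function(tab) {
      sets <- lapply(COMPARISONS, function(cmp)
        tab$feature_id[tab$comparison == cmp & tab$padj < config$de_alpha])
      v <- venn_partition(sets[[1]], sets[[2]], sets[[3]])
      names(v) <- sub("A", COMPARISONS[1],
                      sub("B", COMPARISONS[2],
                          sub("C", COMPARISONS[3], names(v))))
      v
    })
  })

  pca <- stage("pca", {
    lapply(stats::setNames(PLATFORMS, PLATFORMS), function(pl) {
      m <- if (pl == "miRNA") pre$mirna else pre$mrna
      feats <- intersect(de_features[[pl]], rownames(m))
      if (length(feats) < 2 || ncol(m) < 3) return(NULL)
      pca_scores(m[feats, , drop = FALSE],
                 n_components = min(2, length(feats), ncol(m) - 1))
    })
  })

  integration <- stage("integration", {
    integrate_mirna_mrna(pre$mirna, pre$mrna, sheet, catalog,
                         de_mirnas = de_features$miRNA,
                         mode = config$corr_mode,
                         patient_adjust = config$patient_adjust,
                         n_comp = config$n_comp,
                         keepY_grid = config$keepY_grid)
  })

  stability <- stage("stability", {
    if (nrow(integration$candidates) == 0) {
      data.frame(mirna_id = character(0), mrna_id = character(0),
                 selected_count = integer(0), total_folds = integer(0),
                 stability = numeric(0))
    } else {
      loocv_selection_counts(pre$mirna, pre$mrna, sheet, catalog,
                             de_mirnas = de_features$miRNA,
                             candidates = integration$candidates,
                             keepY = integration$keepY,
                             mode = config$corr_mode,
                             n_comp = config$n_comp)
    }
  })

  signature <- stage("signature", {
    assemble_signature(stability, integration$correlations,
                       de_mirna_table = de$miRNA, de_mrna_table = de$mRNA,
                       stability_min = config$stability_min,
                       fdr_max = config$corr_fdr,
                       de_alpha = config$de_alpha)
  })

  provenance <- c(
    package = paste0("spatmir ",
                     as.character(utils::packageVersion("spatmir"))),
    r_version = R.version.string,
    seed = config$seed,
    cv_min = config$cv_min,
    de_alpha = config$de_alpha,
    corr_fdr = config$corr_fdr,
    stability_min = config$stability_min,
    corr_mode = config$corr_mode,
    patient_adjust = config$patient_adjust,
    n_comp = config$n_comp,
    keepY_grid = paste(config$keepY_grid, collapse = ","),
    keepY_chosen = integration$keepY,
    quantile_norm = config$quantile_norm,
    n_mirna_input = nrow(mirna), n_mrna_input = nrow(mrna),
    n_mirna_filtered = nrow(pre$mirna), n_mrna_filtered = nrow(pre$mrna),
    n_samples_excluded = sum(sheet$included == 0L),
    n_de_mirna = length(de_features$miRNA),
    n_de_mrna = length(de_features$mRNA),
    n_unmapped_de_mirna = length(integration$unmapped),
    n_candidate_pairs = nrow(integration$candidates),
    n_significant_correlations =
      sum(integration$correlations$padj < config$corr_fdr, na.rm = TRUE),
    n_signature = nrow(signature))

  result <- list(de = de, de_features = de_features, venn = venn, pca = pca,
                 integration = integration, stability = stability,
                 signature = signature, provenance = provenance,
                 config = config)
  if (!is.null(out_dir)) write_run_outputs(result, catalog, out_dir)
  result
}
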