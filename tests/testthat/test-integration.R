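test_that("map_validated_targets restricts to DE miRNAs and measured mRNAs", {
  cat_df <- data.frame(mirna_id = c("m1", "m1", "m2", "m3"),
                       mrna_id = c("g1", "g2", "g1", "g9"),
                       stringsAsFactors = FALSE)
  res <- map_validated_targets(c("m1", "m3", "m4"), cat_df,
                               mrna_universe = c("g1", "g2"))
  expect_equal(res$pairs$mirna_id, c("m1", "m1"))
  expect_equal(res$pairs$mrna_id, c("g1", "g2"))
  expect_equal(res$unmapped, "m4")
})

test_that("site_median_profile takes medians within site", {
  sheet <- toy_sheet(3)
  m <- toy_matrix(sheet, "mRNA", 0, features = "f1")
  m["f1", sprintf("P%03d_NBI_mRNA", 1:3)] <- c(1, 2, 100)
  m["f1", sprintf("P%03d_WL_mRNA", 1:3)] <- c(5, 6, 7)
  m["f1", sprintf("P%03d_T_mRNA", 1:3)] <- c(9, 9, 9)
  prof <- site_median_profile(m, sheet, "mRNA")
  expect_equal(prof["f1", ], c(NBI = 2, WL = 6, T = 9))
  # single patient: profile equals that patient's values
  prof1 <- site_median_profile(m, sheet, "mRNA", patients = 2)
  expect_equal(prof1["f1", ], c(NBI = 2, WL = 6, T = 9))
  sheet$included[sheet$site == "WL" & sheet$platform == "mRNA"] <- 0L
  expect_error(site_median_profile(m, sheet, "mRNA"), "WL")
})

test_that("matched_observations pairs biopsies present on both platforms", {
  sheet <- oscc_qc_sheet()
  mm <- matched_observations(sheet)
  expect_equal(nrow(mm), 41) # 17 T + 17 WL + 7 NBI with both arrays
  expect_equal(sum(mm$site == "NBI"), 7)
  expect_true(all(!duplicated(paste(mm$patient_id, mm$site))))
})

test_that("extract_candidate_pairs intersects same-component support with the catalog", {
  model <- structure(list(
    X_loadings = matrix(c(1, 0, 0, 1, 1, 0), 3, 2,
                        dimnames = list(c("m1", "m2", "m3"), NULL)),
    Y_loadings = matrix(c(1, 1, 0, 0, 0, 1), 3, 2,
                        dimnames = list(c("g1", "g2", "g3"), NULL)),
    n_comp = 2L), class = "spls_model")
  cat_df <- data.frame(mirna_id = c("m1", "m2", "m1", "m3"),
                       mrna_id = c("g1", "g3", "g3", "g2"),
                       stringsAsFactors = FALSE)
  res <- extract_candidate_pairs(model, cat_df)
  # component 1 support: {m1} x {g1, g2}; component 2: {m2, m1} x {g3}
  expect_equal(paste(res$mirna_id, res$mrna_id),
               c("m1 g1", "m1 g3", "m2 g3"))
  expect_equal(res$component[res$mirna_id == "m1" & res$mrna_id == "g1"], 1)
})

test_that("spatial_pearson matches cor.test without patient adjustment", {
  set.seed(601)
  x <- rnorm(12); y <- 0.5 * x + rnorm(12)
  rec <- spatial_pearson(x, y)
  ct <- stats::cor.test(x, y)
  expect_equal(rec$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(rec$p, ct$p.value, tolerance = 1e-12)
  expect_equal(rec$df, 10)
  perfect <- spatial_pearson(1:6, -(1:6))
  expect_equal(perfect$r, -1)
  expect_lt(perfect$p, 1e-10)
})

test_that("the repeated-measures correlation matches its formula", {
  set.seed(602)
  patients <- rep(1:4, each = 3)
  x <- rnorm(12); y <- rnorm(12)
  rec <- spatial_pearson(x, y, patients = patients)
  xc <- x - stats::ave(x, patients)
  yc <- y - stats::ave(y, patients)
  r <- stats::cor(xc, yc)
  df <- 12 - 4 - 1
  tstat <- r * sqrt(df) / sqrt(1 - r^2)
  expect_equal(rec$r, r, tolerance = 1e-12)
  expect_equal(rec$df, df)
  expect_equal(rec$p, 2 * stats::pt(-abs(tstat), df), tolerance = 1e-12)
})

test_that("patient adjustment removes purely between-patient association", {
  set.seed(603)
  patients <- rep(1:9, each = 3)
  eff <- rnorm(9, sd = 3)[patients]
  x <- eff + rnorm(27, sd = 0.2)
  y <- eff + rnorm(27, sd = 0.2)
  naive <- spatial_pearson(x, y)
  adjusted <- spatial_pearson(x, y, patients = patients)
  expect_gt(naive$r, 0.9)           # confounded by the shared patient effect
  expect_lt(abs(adjusted$r), 0.5)   # within-patient there is no relation
  expect_gt(adjusted$p, 0.01)
})

test_that("degenerate correlations are flagged undefined", {
  rec <- spatial_pearson(rep(1, 5), rnorm(5))
  expect_true(rec$undefined)
  expect_true(is.na(rec$r))
  # constant within patient: centering removes all variance
  rec2 <- spatial_pearson(c(1, 1, 2, 2), c(0, 1, 0, 1),
                          patients = c(1, 1, 2, 2))
  expect_true(rec2$undefined)
  expect_error(spatial_pearson(1:2, 1:2), "3 matched points")
})

test_that("classify_linkage follows the sign of r", {
  expect_equal(classify_linkage(c(-0.8, 0.3)),
               c("reciprocal", "nonreciprocal"))
  expect_warning(cls <- classify_linkage(0), "exactly 0")
  expect_equal(cls, "nonreciprocal")
  expect_error(classify_linkage(NA_real_), "undefined")
})

test_that("integrate_mirna_mrna recovers planted pairs on the small cohort", {
  co <- small_cohort()
  mirna <- cv_filter(quantile_normalize(co$mirna), 0.1)
  mrna <- cv_filter(quantile_normalize(co$mrna), 0.1)
  de <- de_all_comparisons(mirna, co$sheet, platform = "miRNA")
  res <- suppressWarnings(
    integrate_mirna_mrna(mirna, mrna, co$sheet, co$catalog,
                         select_de_features(de), n_comp = 4,
                         keepY_grid = c(4, 8, 16)))
  expect_true(res$keepY %in% pmin(c(4, 8, 16), ncol(res$Y)))
  truth_keys <- paste(co$truth$planted_pairs$mirna_id,
                      co$truth$planted_pairs$mrna_id)
  cand_keys <- paste(res$candidates$mirna_id, res$candidates$mrna_id)
  expect_gt(length(intersect(cand_keys, truth_keys)) / length(truth_keys),
            0.6)
  expect_equal(nrow(res$correlations), nrow(res$candidates))
  ok <- !res$correlations$undefined
  expect_true(all(res$correlations$padj[ok] >= res$correlations$p[ok] - 1e-12))
})

test_that("integration with no DE miRNAs is empty but well-formed", {
  co <- small_cohort()
  res <- integrate_mirna_mrna(co$mirna, co$mrna, co$sheet, co$catalog,
                              de_mirnas = character(0))
  expect_equal(nrow(res$candidates), 0)
  expect_equal(nrow(res$correlations), 0)
  expect_true(is.na(res$keepY))
  # DE miRNAs absent from the catalog are reported unmapped
  res2 <- integrate_mirna_mrna(co$mirna, co$mrna, co$sheet, co$catalog,
                               de_mirnas = "miR-absent")
  expect_equal(res2$unmapped, "miR-absent")
  expect_equal(nrow(res2$candidates), 0)
})
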