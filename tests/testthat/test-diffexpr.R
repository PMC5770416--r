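test_that("paired differences are A minus B, paired by patient id", {
  sheet <- toy_sheet(3)
  # shuffle row order so any column-order pairing would be wrong
  sheet <- sheet[rev(seq_len(nrow(sheet))), ]
  m <- toy_matrix(toy_sheet(3), "miRNA", 0, features = "f1")
  for (p in 1:3) {
    m["f1", sprintf("P%03d_T_miRNA", p)] <- 10 + p
    m["f1", sprintf("P%03d_NBI_miRNA", p)] <- 2 * p
    m["f1", sprintf("P%03d_WL_miRNA", p)] <- 5
  }
  d <- paired_log_differences(m, sheet, "T_vs_NBI", "miRNA")
  expect_equal(d["f1", c("1", "2", "3")], c(`1` = 9, `2` = 8, `3` = 7))
  # a patient missing one member raises an error naming the patient
  sheet$included[sheet$patient_id == 2 & sheet$site == "NBI" &
                   sheet$platform == "miRNA"] <- 0L
  expect_error(paired_log_differences(m, sheet, "T_vs_NBI", "miRNA",
                                      patients = 1:3), "2")
})

test_that("trigamma_inverse inverts trigamma", {
  y <- c(0.3, 1, 4, 25)
  expect_equal(spatmir:::trigamma_inverse(trigamma(y)), y, tolerance = 1e-8)
  expect_error(spatmir:::trigamma_inverse(-1), "positive")
})

test_that("variance prior recovers known hyperparameters by simulation", {
  set.seed(401)
  d0 <- 4; s0 <- 2; d <- 6; n <- 5000
  sigma2 <- d0 * s0 / stats::rchisq(n, df = d0)
  s2 <- sigma2 * stats::rchisq(n, df = d) / d
  prior <- estimate_variance_prior(s2, d)
  expect_lt(abs(prior$d0 - d0) / d0, 0.25)
  expect_lt(abs(prior$s0_sq - s0) / s0, 0.25)
})

test_that("equal variances degrade the prior to a point mass", {
  prior <- estimate_variance_prior(rep(3, 10), d = 5)
  expect_identical(prior$d0, Inf)
  expect_equal(prior$s0_sq, 3)
})

test_that("variance prior agrees with limma's squeezeVar", {
  set.seed(402)
  s2 <- 1.5 * stats::rchisq(300, df = 5) / 5 *
    (4 / stats::rchisq(300, df = 4)) # heterogeneous truth
  sq <- limma::squeezeVar(s2, df = 5)
  prior <- estimate_variance_prior(s2, d = 5)
  expect_equal(prior$d0, sq$df.prior, tolerance = 1e-4)
  expect_equal(prior$s0_sq, sq$var.prior, tolerance = 1e-4)
  post <- moderated_paired_t(rep(0, 300), s2, n = 6, prior$d0, prior$s0_sq)
  expect_equal(post$s2_post, sq$var.post, tolerance = 1e-4)
})

test_that("moderated t with d0 = 0 is the classical paired t", {
  set.seed(403)
  diffs <- matrix(rnorm(20 * 8), 20, 8)
  res <- moderated_paired_t(rowMeans(diffs), apply(diffs, 1, stats::var),
                            n = 8, d0 = 0, s0_sq = 1)
  for (g in 1:20) {
    tt <- stats::t.test(diffs[g, ])
    expect_equal(res$t_mod[g], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(res$p[g], tt$p.value, tolerance = 1e-12)
  }
})

test_that("moderated t with d0 = Inf uses the common variance", {
  res <- moderated_paired_t(c(1, -2), c(5, 0.1), n = 4, d0 = Inf, s0_sq = 2)
  expect_equal(res$t_mod, c(1, -2) / sqrt(2 / 4))
  expect_equal(res$p, 2 * stats::pnorm(-abs(res$t_mod)))
})

test_that("zero posterior variance is handled without NaN", {
  res <- moderated_paired_t(c(0, 3), c(0, 0), n = 3, d0 = 0, s0_sq = 0)
  expect_equal(res$t_mod[1], 0)
  expect_equal(res$p[1], 1)
  expect_equal(res$p[2], 0)
  expect_true(all(res$degenerate))
})

test_that("bh_adjust matches the hand-computed step-up example", {
  p <- c(0.05, 0.005, 0.009)
  expect_equal(bh_adjust(p), c(0.05, 0.0135, 0.0135))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "missing")
})

test_that("DE tables flag planted gradient features", {
  co <- small_cohort()
  m <- cv_filter(quantile_normalize(co$mirna), 0.1)
  de <- de_all_comparisons(m, co$sheet, platform = "miRNA", alpha = 0.01)
  found <- select_de_features(de, 0.01)
  truth <- co$truth$de_features$feature_id[
    co$truth$de_features$platform == "miRNA"]
  expect_gte(length(intersect(found, truth)) / length(truth), 0.7)
  expect_true(all(c("feature_id", "comparison", "padj", "de") %in% names(de)))
  expect_setequal(unique(de$comparison),
                  c("T_vs_WL", "T_vs_NBI", "WL_vs_NBI"))
})

test_that("venn_partition counts the seven exclusive regions", {
  v <- venn_partition(a = c("x", "y", "z"), b = c("y", "z", "w"),
                      c = c("z", "w", "q"))
  expect_equal(v, c(A_only = 1L, B_only = 0L, C_only = 1L, AB_only = 1L,
                    AC_only = 0L, BC_only = 1L, ABC = 1L))
  expect_equal(sum(venn_partition(letters[1:3], letters[2:4], letters[3:5])),
               5L)
})

test_that("pca_scores matches a direct SVD oracle", {
  set.seed(404)
  m <- matrix(rnorm(12), 4, 3,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  res <- pca_scores(m, n_components = 2)
  x <- scale(t(m), center = TRUE, scale = FALSE)
  sv <- svd(x)
  expect_equal(abs(unname(res$scores)),
               abs(sv$u[, 1:2] %*% diag(sv$d[1:2])), tolerance = 1e-10)
  expect_equal(res$explained_variance, sv$d[1:2]^2 / 2, tolerance = 1e-10)
  # sign convention: dominant loading positive
  for (j in 1:2)
    expect_gt(res$loadings[which.max(abs(res$loadings[, j])), j], 0)
  expect_error(pca_scores(m, n_components = 5), "exceeds")
})

test_that("hierarchical clustering merges at hand-computed heights", {
  m <- matrix(c(0, 1, 10), 1, 3,
              dimnames = list("f1", c("a", "b", "c")))
  m <- rbind(m, f2 = c(0, 1, 10)) # need >= 1 row; duplicate keeps geometry
  hc <- hierarchical_cluster(m, distance = "euclidean", linkage = "average")
  expect_equal(hc$height, c(sqrt(2), mean(c(sqrt(200), sqrt(162)))),
               tolerance = 1e-12)
  expect_error(hierarchical_cluster(m[, 1, drop = FALSE]), "2 samples")
})
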