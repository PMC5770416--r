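#' Per-patient paired log2 differences for a site comparison
#'
#' For comparison label `"A_vs_B"` returns, per feature and patient, the
#' difference `value(A) - value(B)`. Pairing is by patient id in the sample
#' sheet, never by column order. Only patients from [complete_pairs()] are
#' admissible; a patient lacking either member raises an error.
#'
#' @param m Feature x sample log2 matrix.
#' @param sheet Sample sheet.
#' @param comparison Comparison label, e.g. `"T_vs_NBI"`.
#' @param platform Platform of `m`.
#' @param patients Optional patient ids; defaults to [complete_pairs()].
#' @return Feature x patient matrix of differences; column names are patient
#'   ids.
#' @export
paired_log_differences <- function(m, sheet, comparison,
                                   platform = PLATFORMS, patients = NULL) {
  assert_expression_matrix(m)
  assert_sample_sheet(sheet)
  platform <- match.arg(platform)
  sites <- comparison_sites(comparison)
  patients <- patients %||% complete_pairs(sheet, comparison, platform)
  if (length(patients) == 0) stop("no complete pairs for ", comparison)
  sample_of <- function(site) {
    idx <- match(paste(patients, site, platform),
                 paste(sheet$patient_id, sheet$site, sheet$platform))
    ids <- sheet$sample_id[idx]
    bad <- is.na(idx) | sheet$included[idx] != 1L | !(ids %in% colnames(m))
    if (any(bad))
      stop("patient(s) ", paste(patients[bad], collapse = ", "),
           " lack an included ", site, " ", platform, " sample")
    ids
  }
  d <- m[, sample_of(sites[1]), drop = FALSE] -
    m[, sample_of(sites[2]), drop = FALSE]
  colnames(d) <- as.character(patients)
  d
}

# Newton inversion of the trigamma function (monotone decreasing, convex
# in log-space), used by the variance-prior moment matching.
trigamma_inverse <- function(x) {
  if (any(x <= 0)) stop("trigamma_inverse requires positive input")
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

#' Empirical-Bayes prior for paired-difference variances
#'
#' Fits a scaled inverse-chi-squared prior \eqn{s_0^2 d_0 / \chi^2_{d_0}} to
#' the per-feature sample variances by moment matching on the log scale:
#' \eqn{d_0} solves \eqn{trigamma(d_0/2) = var(\log s^2) - trigamma(d/2)};
#' when the right-hand side is non-positive (observed variances no more
#' dispersed than pure chi-squared sampling noise) the prior degenerates to a
#' point mass, \eqn{d_0 = \infty}, at the geometric mean of the variances.
#' For finite \eqn{d_0}, \eqn{s_0^2} is recovered from the matched mean of
#' \eqn{\log s^2}.
#'
#' @param s2 Vector of per-feature sample variances (paired differences).
#' @param d Residual degrees of freedom per feature (n pairs - 1).
#' @return List with `d0` (possibly `Inf`) and `s0_sq`.
#' @export
estimate_variance_prior <- function(s2, d) {
  pos <- s2[is.finite(s2) & s2 > 0]
  if (length(pos) < 2)
    stop("need at least 2 features with positive variance")
  ls <- log(pos)
  rhs <- stats::var(ls) - trigamma(d / 2)
  if (!is.finite(rhs) || rhs <= 0) {
    return(list(d0 = Inf, s0_sq = exp(mean(ls))))
  }
  d0 <- 2 * trigamma_inverse(rhs)
  s0_sq <- exp(mean(ls) - (digamma(d / 2) - log(d / 2)) +
                 (digamma(d0 / 2) - log(d0 / 2)))
  if (!is.finite(d0) || !is.finite(s0_sq))
    stop("variance prior estimation produced non-finite values")
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated paired t-statistics
#'
#' Shrinks each feature's paired-difference variance toward the prior and
#' forms the one-sample (paired) t-statistic on the posterior variance:
#' \deqn{\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}, \qquad
#' \tilde t_g = \frac{\bar\Delta_g}{\sqrt{\tilde s_g^2 / n}},}
#' with two-sided p-values from the t distribution on \eqn{d_0 + d_g} degrees
#' of freedom. `d0 = 0` recovers the classical paired t; `d0 = Inf` fully
#' replaces each variance with `s0_sq`.
#'
#' @param mean_diff Per-feature mean of the paired differences.
#' @param s2 Per-feature sample variance of the differences.
#' @param n Number of pairs (>= 2).
#' @param d0,s0_sq Prior degrees of freedom and variance (see
#'   [estimate_variance_prior()]).
#' @return data.frame with columns `mean_diff`, `s2_g`, `d_g`, `s2_post`,
#'   `t_mod`, `p`, `degenerate`; attributes `d0` and `s0_sq`.
#' @export
moderated_paired_t <- function(mean_diff, s2, n, d0, s0_sq) {
  if (n < 2) stop("need at least 2 pairs")
  d_g <- n - 1
  s2_post <- if (is.infinite(d0)) {
    rep(s0_sq, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * s0_sq + d_g * s2) / (d0 + d_g)
  }
  df_total <- d0 + d_g
  t_mod <- ifelse(s2_post > 0, mean_diff / sqrt(s2_post / n), NA_real_)
  degenerate <- s2_post == 0
  # zero posterior variance: zero mean -> t = 0, p = 1; nonzero mean -> p = 0
  t_mod[degenerate] <- ifelse(mean_diff[degenerate] == 0, 0,
                              sign(mean_diff[degenerate]) * Inf)
  p <- ifelse(is.infinite(t_mod), 0,
              2 * stats::pt(-abs(t_mod), df = df_total))
  out <- data.frame(mean_diff = mean_diff, s2_g = s2, d_g = d_g,
                    s2_post = s2_post, t_mod = t_mod, p = p,
                    degenerate = degenerate)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment via [stats::p.adjust()] (cumulative-minimum
#' construction, tie-safe), with input validation.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, order preserved.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must be in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

#' Paired moderated-t differential expression for one comparison
#'
#' Computes per-patient paired differences, fits the variance prior across
#' features, forms moderated t-statistics and BH-adjusted p-values, and flags
#' features with `padj < alpha`.
#'
#' @inheritParams paired_log_differences
#' @param alpha DE significance threshold on the adjusted p-value
#'   (default 0.01, strict `<`).
#' @return A DE table: data.frame with `feature_id`, `comparison`,
#'   `n_pairs`, the moderated statistics, `padj` and logical `de`; the prior
#'   (`d0`, `s0_sq`) and `alpha` as attributes.
#' @export
paired_moderated_de <- function(m, sheet, comparison, platform = PLATFORMS,
                                alpha = 0.01) {
  platform <- match.arg(platform)
  diffs <- paired_log_differences(m, sheet, comparison, platform)
  n <- ncol(diffs)
  mean_diff <- rowMeans(diffs)
  s2 <- apply(diffs, 1, stats::var)
  prior <- estimate_variance_prior(s2, d = n - 1)
  stats_df <- moderated_paired_t(mean_diff, s2, n, prior$d0, prior$s0_sq)
  out <- data.frame(feature_id = rownames(diffs), comparison = comparison,
                    n_pairs = n, stats_df, stringsAsFactors = FALSE)
  out$padj <- bh_adjust(out$p)
  out$de <- out$padj < alpha
  rownames(out) <- NULL
  attr(out, "d0") <- prior$d0
  attr(out, "s0_sq") <- prior$s0_sq
  attr(out, "alpha") <- alpha
  out
}

#' Differential expression over all three site comparisons
#'
#' @inheritParams paired_moderated_de
#' @param comparisons Comparison labels (default all three).
#' @return A single DE table stacking the per-comparison results.
#' @export
de_all_comparisons <- function(m, sheet, platform = PLATFORMS, alpha = 0.01,
                               comparisons = COMPARISONS) {
  platform <- match.arg(platform)
  out <- do.call(rbind, lapply(comparisons, function(cmp)
    paired_moderated_de(m, sheet, cmp, platform, alpha)))
  attr(out, "alpha") <- alpha
  out
}

#' Features differentially expressed in at least one comparison
#'
#' @param de_table DE table from [de_all_comparisons()].
#' @param alpha Threshold on `padj` (strict `<`).
#' @return Character vector of feature ids (union over comparisons).
#' @export
select_de_features <- function(de_table, alpha = 0.01) {
  if (is.null(de_table) || nrow(de_table) == 0) return(character(0))
  sort(unique(de_table$feature_id[de_table$padj < alpha]))
}

#' Counts of the seven exclusive regions of a three-set Venn diagram
#'
#' @param a,b,c Vectors of ids (coerced to sets).
#' @return Named integer vector: `A_only`, `B_only`, `C_only`, `AB_only`,
#'   `AC_only`, `BC_only`, `ABC`.
#' @export
venn_partition <- function(a, b, c) {
  a <- unique(a); b <- unique(b); c <- unique(c)
  u <- union(union(a, b), c)
  ina <- u %in% a; inb <- u %in% b; inc <- u %in% c
  c(A_only = sum(ina & !inb & !inc),
    B_only = sum(!ina & inb & !inc),
    C_only = sum(!ina & !inb & inc),
    AB_only = sum(ina & inb & !inc),
    AC_only = sum(ina & !inb & inc),
    BC_only = sum(!ina & inb & inc),
    ABC = sum(ina & inb & inc))
}

#' Principal component scores of samples
#'
#' Samples are the observations (matrix columns); features are centered
#' internally. Scores are projections onto the right singular vectors of the
#' centered sample x feature matrix. Sign convention: within each component
#' the largest-magnitude feature loading is made positive.
#'
#' @param m Feature x sample matrix.
#' @param n_components Number of components (<= min(n samples, n features)).
#' @return List with `scores` (sample x component), `loadings`
#'   (feature x component), `explained_variance` (squared singular values /
#'   (n - 1)) and `proportion`.
#' @export
pca_scores <- function(m, n_components = 2) {
  assert_expression_matrix(m)
  x <- scale(t(m), center = TRUE, scale = FALSE)
  k_max <- min(dim(x))
  if (n_components > k_max)
    stop("n_components exceeds min(n samples, n features) = ", k_max)
  sv <- svd(x, nu = n_components, nv = n_components)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)],
                          nrow = n_components)
  loadings <- sv$v
  for (j in seq_len(n_components)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(colnames(m), paste0("PC", seq_len(n_components)))
  dimnames(loadings) <- list(rownames(m), paste0("PC", seq_len(n_components)))
  ev <- sv$d^2 / (ncol(m) - 1)
  list(scores = scores, loadings = loadings,
       explained_variance = ev[seq_len(n_components)],
       proportion = (ev / sum(ev))[seq_len(n_components)])
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of the matrix columns, by default under
#' correlation distance (1 - Pearson) with average linkage.
#'
#' @param m Feature x sample matrix.
#' @param distance `"pearson"` (1 - correlation) or `"euclidean"`.
#' @param linkage Linkage method passed to [stats::hclust()].
#' @return An `hclust` object with samples as leaves.
#' @export
hierarchical_cluster <- function(m, distance = c("pearson", "euclidean"),
                                 linkage = "average") {
  assert_expression_matrix(m)
  distance <- match.arg(distance)
  if (ncol(m) < 2) stop("need at least 2 samples to cluster")
  d <- switch(distance,
              pearson = stats::as.dist(1 - stats::cor(m)),
              euclidean = stats::dist(t(m)))
  stats::hclust(d, method = linkage)
}
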