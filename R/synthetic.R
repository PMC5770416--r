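#' Configuration for the synthetic margin-cohort generator
#'
#' Builds the parameter list driving [generate_sample_sheet()],
#' [simulate_expression()] and [generate_catalog()]. The defaults emulate the
#' structure of an 18-patient oral squamous cell carcinoma margin cohort with
#' three biopsy sites per patient -- narrow-band-imaging margin (NBI),
#' white-light margin (WL) and tumour core (T) -- profiled on separate miRNA
#' and mRNA arrays, with occasional QC dropout of non-tumour arrays.
#'
#' The generative model for a non-target feature g in patient p at site s is
#' \deqn{x_{gps} = \mu_g + a_{gp} + \delta_g z_s + \varepsilon,}
#' where \eqn{\mu_g \sim U(4, 12)} log2 units, \eqn{a_{gp} \sim N(0,
#' \sigma_{patient}^2)} is a per-feature patient effect (patient identity is
#' shared between the two platforms so leave-one-patient-out folds remove a
#' coherent block of data), \eqn{z_s} is the spatial score of the site
#' (NBI = 0, WL = 0.5, T = 1 by default) and \eqn{\varepsilon \sim N(0,
#' \sigma_{noise}^2)}. \eqn{\delta_g} is zero except for the designated
#' gradient (differentially expressed) features. A planted target mRNA t of
#' miRNA m follows
#' \deqn{x_t = \mu_t + a_{tp} \mp \beta (x_m - \mu_m) + \varepsilon,}
#' with the minus sign for reciprocal (repressive) pairs and plus for
#' non-reciprocal pairs, so reciprocal pairs have negative and non-reciprocal
#' pairs positive population correlation.
#'
#' @param n_patients Number of patients (default 18).
#' @param site_scores Named numeric vector of spatial scores, strictly
#'   increasing over `c(NBI, WL, T)`.
#' @param n_mirna,n_mrna Number of miRNA / mRNA features.
#' @param n_de_mirna,n_de_mrna Number of gradient-driven (differentially
#'   expressed) features per platform.
#' @param n_reciprocal_pairs,n_nonreciprocal_pairs Planted miRNA-target pairs
#'   of each linkage class. Pair miRNAs are drawn from the gradient miRNAs;
#'   pair targets are mRNAs outside the gradient set, one per pair.
#' @param gradient_delta Log2 expression change per unit spatial score for
#'   gradient features.
#' @param coupling_beta Regression weight of the miRNA deviation on its
#'   planted target.
#' @param patient_sd SD of the per-feature patient random effect (log2 units).
#' @param noise_sd SD of the residual measurement noise (log2 units).
#' @param dropout_prob Probability that a non-tumour array fails QC and is
#'   excluded; tumour arrays are always included.
#' @param n_decoy_pairs Number of validated-but-uncoupled catalog pairs added
#'   by [generate_catalog()].
#' @param mu_range Range of baseline log2 intensities.
#' @param seed Integer seed; all three generator operations are deterministic
#'   given the seed.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_patients = 18L,
                       site_scores = c(NBI = 0, WL = 0.5, T = 1),
                       n_mirna = 200L, n_mrna = 1000L,
                       n_de_mirna = 50L, n_de_mrna = 150L,
                       n_reciprocal_pairs = 30L, n_nonreciprocal_pairs = 10L,
                       gradient_delta = 1, coupling_beta = 1.2,
                       patient_sd = 1.5, noise_sd = 0.5,
                       dropout_prob = 0.2, n_decoy_pairs = 300L,
                       mu_range = c(4, 12), seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients), site_scores = site_scores,
              n_mirna = as.integer(n_mirna), n_mrna = as.integer(n_mrna),
              n_de_mirna = as.integer(n_de_mirna),
              n_de_mrna = as.integer(n_de_mrna),
              n_reciprocal_pairs = as.integer(n_reciprocal_pairs),
              n_nonreciprocal_pairs = as.integer(n_nonreciprocal_pairs),
              gradient_delta = gradient_delta, coupling_beta = coupling_beta,
              patient_sd = patient_sd, noise_sd = noise_sd,
              dropout_prob = dropout_prob,
              n_decoy_pairs = as.integer(n_decoy_pairs),
              mu_range = mu_range, seed = as.integer(seed))
  counts <- c(cfg$n_patients, cfg$n_mirna, cfg$n_mrna, cfg$n_de_mirna,
              cfg$n_de_mrna, cfg$n_reciprocal_pairs, cfg$n_nonreciprocal_pairs,
              cfg$n_decoy_pairs)
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (cfg$dropout_prob < 0 || cfg$dropout_prob >= 1)
    stop("dropout_prob must be in [0, 1)")
  if (!identical(names(site_scores), SITES) || any(diff(site_scores) <= 0))
    stop("site_scores must be named NBI, WL, T and strictly increasing")
  n_pairs <- cfg$n_reciprocal_pairs + cfg$n_nonreciprocal_pairs
  if (n_pairs > 0 && cfg$n_de_mirna < 1)
    stop("planted pairs require at least one gradient miRNA")
  if (n_pairs > cfg$n_mrna - cfg$n_de_mrna)
    stop("not enough non-gradient mRNAs to host ", n_pairs, " planted targets")
  if (cfg$n_de_mirna > cfg$n_mirna || cfg$n_de_mrna > cfg$n_mrna)
    stop("gradient feature counts exceed platform sizes")
  structure(cfg, class = "sim_config")
}

#' Generate a patient/site/platform sample sheet with QC dropout
#'
#' One row per (patient, site, platform). Tumour (T) arrays are always
#' included; each non-tumour array is excluded independently with probability
#' `cfg$dropout_prob`, mirroring the per-array QC verdicts of a margin cohort.
#'
#' @param cfg A [sim_config()].
#' @return A data.frame with columns `sample_id`, `patient_id`, `site`,
#'   `platform`, `included` (0/1).
#' @export
generate_sample_sheet <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  grid <- expand.grid(site = SITES, patient_id = seq_len(cfg$n_patients),
                      platform = PLATFORMS, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("patient_id", "site", "platform")]
  grid$sample_id <- sprintf("P%03d_%s_%s", grid$patient_id, grid$site,
                            grid$platform)
  grid$included <- 1L
  nont <- grid$site != "T"
  grid$included[nont] <- with_local_seed(cfg$seed, {
    as.integer(stats::runif(sum(nont)) >= cfg$dropout_prob)
  })
  sheet <- grid[, c("sample_id", "patient_id", "site", "platform", "included")]
  rownames(sheet) <- NULL
  assert_sample_sheet(sheet)
  sheet
}

#' Simulate paired miRNA and mRNA expression matrices with planted structure
#'
#' Draws log2 expression for every (patient, site) combination under the model
#' described in [sim_config()], then emits only the samples flagged as
#' included in `sheet`. Planted targets are coupled to the *underlying* miRNA
#' tissue value at the same (patient, site), regardless of whether that miRNA
#' array passed QC.
#'
#' @param cfg A [sim_config()].
#' @param sheet Sample sheet covering both platforms (from
#'   [generate_sample_sheet()]).
#' @return A list with elements `mirna` and `mrna` (feature x sample log2
#'   matrices restricted to included samples) and `truth`, a list holding
#'   `de_features` (feature_id, platform, delta) and `planted_pairs`
#'   (mirna_id, mrna_id, class, beta).
#' @export
simulate_expression <- function(cfg, sheet) {
  stopifnot(inherits(cfg, "sim_config"))
  assert_sample_sheet(sheet)
  if (!all(PLATFORMS %in% sheet$platform))
    stop("sample sheet must cover both platforms")

  mirna_ids <- sprintf("miR-sim-%04d", seq_len(cfg$n_mirna))
  mrna_ids <- sprintf("GENE%04d", seq_len(cfg$n_mrna))
  n_pairs <- cfg$n_reciprocal_pairs + cfg$n_nonreciprocal_pairs

  grid <- expand.grid(site = SITES, patient_id = seq_len(cfg$n_patients),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  z <- cfg$site_scores[grid$site]
  n_cols <- nrow(grid)

  out <- with_local_seed(cfg$seed + 1L, {
    de_mirna_idx <- sort(sample.int(cfg$n_mirna, cfg$n_de_mirna))
    de_mrna_idx <- sort(sample.int(cfg$n_mrna, cfg$n_de_mrna))
    delta_mirna <- numeric(cfg$n_mirna)
    delta_mirna[de_mirna_idx] <- cfg$gradient_delta *
      sample(c(-1, 1), cfg$n_de_mirna, replace = TRUE)
    delta_mrna <- numeric(cfg$n_mrna)
    delta_mrna[de_mrna_idx] <- cfg$gradient_delta *
      sample(c(-1, 1), cfg$n_de_mrna, replace = TRUE)

    if (n_pairs > 0) {
      pair_mirna_idx <- sample(de_mirna_idx, n_pairs,
                               replace = n_pairs > cfg$n_de_mirna)
      target_pool <- setdiff(seq_len(cfg$n_mrna), de_mrna_idx)
      pair_mrna_idx <- sample(target_pool, n_pairs)
      pair_class <- rep(c("reciprocal", "nonreciprocal"),
                        c(cfg$n_reciprocal_pairs, cfg$n_nonreciprocal_pairs))
    } else {
      pair_mirna_idx <- integer(0); pair_mrna_idx <- integer(0)
      pair_class <- character(0)
    }

    mu_mirna <- stats::runif(cfg$n_mirna, cfg$mu_range[1], cfg$mu_range[2])
    mu_mrna <- stats::runif(cfg$n_mrna, cfg$mu_range[1], cfg$mu_range[2])

    a_mirna <- matrix(stats::rnorm(cfg$n_mirna * cfg$n_patients,
                                   sd = cfg$patient_sd),
                      cfg$n_mirna, cfg$n_patients)
    a_mrna <- matrix(stats::rnorm(cfg$n_mrna * cfg$n_patients,
                                  sd = cfg$patient_sd),
                     cfg$n_mrna, cfg$n_patients)

    x_mirna <- mu_mirna + a_mirna[, grid$patient_id] +
      outer(delta_mirna, z) +
      matrix(stats::rnorm(cfg$n_mirna * n_cols, sd = cfg$noise_sd),
             cfg$n_mirna, n_cols)
    x_mrna <- mu_mrna + a_mrna[, grid$patient_id] +
      outer(delta_mrna, z) +
      matrix(stats::rnorm(cfg$n_mrna * n_cols, sd = cfg$noise_sd),
             cfg$n_mrna, n_cols)

    # overwrite planted targets: coupled to the miRNA deviation, no own
    # gradient term
    if (n_pairs > 0) {
      sgn <- ifelse(pair_class == "reciprocal", -1, 1)
      for (k in seq_len(n_pairs)) {
        m <- pair_mirna_idx[k]; t <- pair_mrna_idx[k]
        x_mrna[t, ] <- mu_mrna[t] + a_mrna[t, grid$patient_id] +
          sgn[k] * cfg$coupling_beta * (x_mirna[m, ] - mu_mirna[m]) +
          stats::rnorm(n_cols, sd = cfg$noise_sd)
      }
    }
    list(x_mirna = x_mirna, x_mrna = x_mrna,
         de_mirna_idx = de_mirna_idx, de_mrna_idx = de_mrna_idx,
         delta_mirna = delta_mirna, delta_mrna = delta_mrna,
         pair_mirna_idx = pair_mirna_idx, pair_mrna_idx = pair_mrna_idx,
         pair_class = pair_class)
  })

  dimnames(out$x_mirna) <- list(mirna_ids,
                                sprintf("P%03d_%s_miRNA", grid$patient_id,
                                        grid$site))
  dimnames(out$x_mrna) <- list(mrna_ids,
                               sprintf("P%03d_%s_mRNA", grid$patient_id,
                                       grid$site))

  keep <- function(platform, m) {
    ids <- sheet$sample_id[sheet$platform == platform & sheet$included == 1L]
    ids <- ids[ids %in% colnames(m)]
    m[, ids, drop = FALSE]
  }

  truth <- list(
    de_features = rbind(
      data.frame(feature_id = mirna_ids[out$de_mirna_idx], platform = "miRNA",
                 delta = out$delta_mirna[out$de_mirna_idx],
                 stringsAsFactors = FALSE),
      data.frame(feature_id = mrna_ids[out$de_mrna_idx], platform = "mRNA",
                 delta = out$delta_mrna[out$de_mrna_idx],
                 stringsAsFactors = FALSE)),
    planted_pairs = data.frame(
      mirna_id = mirna_ids[out$pair_mirna_idx],
      mrna_id = mrna_ids[out$pair_mrna_idx],
      class = out$pair_class,
      beta = rep(cfg$coupling_beta, n_pairs),
      stringsAsFactors = FALSE)
  )

  list(mirna = keep("miRNA", out$x_mirna),
       mrna = keep("mRNA", out$x_mrna),
       truth = truth)
}

#' Generate a validated-interaction catalog containing the planted pairs
#'
#' Emulates a curated miRNA-to-target catalog: all planted pairs plus decoy
#' validated pairs between uncoupled features, with synthetic genomic
#' coordinates for link-table output. Decoy targets are never planted-target
#' mRNAs, so a decoy pair has zero direct coupling in the ground truth. A
#' small fraction of decoy rows lack mRNA coordinates, as real catalogs do.
#'
#' @param cfg A [sim_config()].
#' @param truth The `truth` element returned by [simulate_expression()].
#' @return A data.frame with columns `mirna_id`, `mrna_id`, `evidence`, and
#'   coordinate columns `mirna_chrom`, `mirna_start`, `mirna_end`,
#'   `mrna_chrom`, `mrna_start`, `mrna_end`.
#' @export
generate_catalog <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"), is.list(truth))
  mirna_ids <- sprintf("miR-sim-%04d", seq_len(cfg$n_mirna))
  mrna_ids <- sprintf("GENE%04d", seq_len(cfg$n_mrna))
  planted <- truth$planted_pairs
  if (nrow(planted) > 0 &&
      (!all(planted$mirna_id %in% mirna_ids) ||
       !all(planted$mrna_id %in% mrna_ids)))
    stop("planted pair references a feature absent from the configuration")

  with_local_seed(cfg$seed + 2L, {
    # per-feature synthetic coordinates
    coord <- function(ids) {
      chrom <- paste0("chr", sample(c(1:22, "X"), length(ids), replace = TRUE))
      start <- sample.int(1e8, length(ids))
      data.frame(id = ids, chrom = chrom, start = start,
                 end = start + sample(500:5000, length(ids), replace = TRUE),
                 stringsAsFactors = FALSE)
    }
    mirna_coord <- coord(mirna_ids)
    mrna_coord <- coord(mrna_ids)

    # decoy targets are null for the spatial axis: neither planted targets
    # nor gradient-driven mRNAs, so a decoy pair has no expression
    # relationship of any kind with its miRNA
    de_mrnas <- truth$de_features$feature_id[
      truth$de_features$platform == "mRNA"]
    decoy_pool_mrna <- setdiff(mrna_ids, c(planted$mrna_id, de_mrnas))
    n_decoy <- cfg$n_decoy_pairs
    decoys <- data.frame(mirna_id = character(0), mrna_id = character(0))
    if (n_decoy > 0) {
      # oversample then deduplicate to get distinct pairs
      dm <- sample(mirna_ids, 4L * n_decoy, replace = TRUE)
      dg <- sample(decoy_pool_mrna, 4L * n_decoy, replace = TRUE)
      keep <- !duplicated(pair_key(dm, dg))
      decoys <- data.frame(mirna_id = dm[keep], mrna_id = dg[keep],
                           stringsAsFactors = FALSE)
      decoys <- utils::head(decoys, n_decoy)
    }
    cat_pairs <- rbind(
      planted[, c("mirna_id", "mrna_id"), drop = FALSE],
      decoys)
    cat_pairs <- cat_pairs[!duplicated(pair_key(cat_pairs$mirna_id,
                                                cat_pairs$mrna_id)), ,
                           drop = FALSE]
    cat_pairs$evidence <- sample(c("reporter_assay", "western_blot", "qPCR",
                                   "CLIP_seq"),
                                 nrow(cat_pairs), replace = TRUE)
    mi <- match(cat_pairs$mirna_id, mirna_coord$id)
    mg <- match(cat_pairs$mrna_id, mrna_coord$id)
    cat_pairs$mirna_chrom <- mirna_coord$chrom[mi]
    cat_pairs$mirna_start <- mirna_coord$start[mi]
    cat_pairs$mirna_end <- mirna_coord$end[mi]
    cat_pairs$mrna_chrom <- mrna_coord$chrom[mg]
    cat_pairs$mrna_start <- mrna_coord$start[mg]
    cat_pairs$mrna_end <- mrna_coord$end[mg]
    # withhold mRNA coordinates for ~5% of decoy rows
    is_decoy <- !(pair_key(cat_pairs$mirna_id, cat_pairs$mrna_id) %in%
                    pair_key(planted$mirna_id, planted$mrna_id))
    drop_coord <- is_decoy & stats::runif(nrow(cat_pairs)) < 0.05
    cat_pairs$mrna_chrom[drop_coord] <- NA_character_
    cat_pairs$mrna_start[drop_coord] <- NA_integer_
    cat_pairs$mrna_end[drop_coord] <- NA_integer_
    rownames(cat_pairs) <- NULL
    cat_pairs
  })
}

#' Generate a complete synthetic margin-cohort dataset
#'
#' Convenience wrapper running [generate_sample_sheet()],
#' [simulate_expression()] and [generate_catalog()] under one configuration.
#'
#' @param cfg A [sim_config()].
#' @return A list with `sheet`, `mirna`, `mrna`, `catalog` and `truth`.
#' @export
simulate_margin_cohort <- function(cfg = sim_config()) {
  sheet <- generate_sample_sheet(cfg)
  expr <- simulate_expression(cfg, sheet)
  catalog <- generate_catalog(cfg, expr$truth)
  list(sheet = sheet, mirna = expr$mirna, mrna = expr$mrna,
       catalog = catalog, truth = expr$truth)
}
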