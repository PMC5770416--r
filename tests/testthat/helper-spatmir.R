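# Shared fixtures: a reduced cohort small enough for fast unit tests, with
# the same structure as the default generator output, plus a cached pipeline
# run reused by the pipeline/report tests.

small_config <- function(seed = 11L, ...) {
  sim_config(n_patients = 10L, n_mirna = 40L, n_mrna = 120L,
             n_de_mirna = 10L, n_de_mrna = 20L,
             n_reciprocal_pairs = 6L, n_nonreciprocal_pairs = 2L,
             n_decoy_pairs = 40L, dropout_prob = 0.1, noise_sd = 0.35,
             seed = seed, ...)
}

small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_margin_cohort(small_config())
    cache
  }
})

small_pipeline_config <- function(seed = 11L) {
  pipeline_config(n_comp = 4, keepY_grid = c(4, 8, 16), seed = seed)
}

small_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- small_cohort()
      cache <<- suppressWarnings(
        run_pipeline(co$mirna, co$mrna, co$sheet, co$catalog,
                     small_pipeline_config()))
    }
    cache
  }
})

# A tiny hand-checkable sample sheet: 3 patients, all arrays included.
toy_sheet <- function(n_patients = 3) {
  grid <- expand.grid(site = c("NBI", "WL", "T"),
                      patient_id = seq_len(n_patients),
                      platform = c("miRNA", "mRNA"),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  data.frame(sample_id = sprintf("P%03d_%s_%s", grid$patient_id, grid$site,
                                 grid$platform),
             patient_id = grid$patient_id, site = grid$site,
             platform = grid$platform, included = 1L,
             stringsAsFactors = FALSE)
}

toy_matrix <- function(sheet, platform, values, features = "f1") {
  ids <- sheet$sample_id[sheet$platform == platform]
  matrix(values, nrow = length(features), ncol = length(ids),
         byrow = TRUE, dimnames = list(features, ids))
}
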