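# Shared fixture builders (all generated in code at test time).

# synthetic cohort with the five AKI outcome columns merged in
cohort_with_outcomes <- function(config, intercept = NULL) {
  synth <- generate_synthetic_cohort(config, intercept = intercept)
  out <- compute_aki_outcomes(synth$cohort)
  for (col in c("hours_below_05", "hours_below_03", "kdigo_ordinal",
                "kdigo_binary"))
    synth$cohort[[col]] <- out[[col]]
  synth$outcomes <- out[setdiff(names(out), "row_id")]
  synth
}

# small default: quick to generate, enough rows per gender for the smooth
small_cohort <- function(n = 240, k = 3, seed = 5, ...) {
  cohort_with_outcomes(sim_config(n_patients = n, n_latent_clusters = k,
                                  seed = seed, ...))
}
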