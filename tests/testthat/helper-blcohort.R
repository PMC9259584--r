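# a scaled-down cohort configuration for fast tests: smaller cohorts and
# background panels, same statistical structure as the defaults
small_config <- function(seed = 1, ...) {
  cohort_config(
    n_pediatric = 60, n_adult = 30, n_normals = 12, seed = seed,
    n_snp_sites = 80, n_rare_sites = 150, n_artifact_sites = 25,
    noise_per_sample = 60, ...
  )
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
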