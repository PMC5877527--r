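# Compact cohort configurations for module mechanics tests (the acceptance
# suite exercises the full default study conditions).

small_cohort_config <- function(seed = 1L, ...) {
  cohort_config(
    n_copd = 10, n_control = 8,
    gold_counts = c(A = 2, B = 2, C = 3, D = 3),
    n_peaks = 60,
    seed = seed, ...
  )
}

small_integrated <- function(cfg = small_cohort_config()) {
  co <- generate_cohort(cfg)
  im <- suppressWarnings(integrate_blocks(co$subjects, co$targeted, co$peaks))
  list(cohort = co, im = im)
}
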