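# Small shared synthetic fixtures; heavier cohorts are built lazily and
# cached for the session so several test files can reuse them.

tiny_config <- function(seed = 42, stillness_lead_ms = 2000, ...) {
  scenario_config(subjects = 1, sessions_per_subject = 1,
                  activity_sequences = list(c("take_snack", "drink_water")),
                  duration_range_ms = c(2000, 3000),
                  stillness_lead_ms = stillness_lead_ms, seed = seed, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# moderate-noise confusable instance table, seed 1 (used by several files)
confusable_instances <- function(seed = 1) {
  cached(paste0("confusable_", seed), function() {
    cohort_instances(generate_cohort(confusable_moderate_noise_config(seed)))
  })
}
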