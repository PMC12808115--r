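# shared fixtures: tiny phantoms and datasets, built once per test run

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- build()
  fixture_env[[name]]
}

tiny_spec <- function(...) {
  phantom_spec(image_size = 16L, n_slices = 4L, ...)
}

# noiseless, jitter-free, bias-free phantom: the exactly learnable task
clean_spec <- function(image_size = 16L, n_slices = 4L) {
  phantom_spec(image_size = image_size, n_slices = n_slices,
               noise_sd = 0, intensity_jitter_sd = 0, bias_field_amplitude = 0)
}

tiny_cohort <- function() {
  fixture("tiny_cohort", function() generate_cohort(tiny_spec(), 6))
}

clean_dataset_16 <- function() {
  fixture("clean_ds16", function() {
    subs <- generate_cohort(clean_spec(), 8)
    make_paired_dataset(subs, "t1like", "t2like", c(0.75, 0, 0.25), seed = 2)
  })
}
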