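# Shared fixtures, generated in code and cached for the whole run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# the full calibrated study design (2,700 x 320); generated once
bench_set <- function() cached("bench", synthetic_benchmark(1))

# a small, quickly separable design for classifier contracts
tiny_set <- function(n_classes = 3L, seeds_per_class = 12L, seed = 5L) {
  cached(sprintf("tiny_%d_%d_%d", n_classes, seeds_per_class, seed), {
    v <- make_varieties(n_classes, rng_seed = seed, class_sep = 2)
    gen_spectrum_set(v, seeds_per_class,
                     noise_model(additive_sd = 0.004, baseline_shift_sd = 0.01,
                                 slope_sd = 0.01, scatter_sd = 0.02,
                                 wiggle_sd = 0.01, shift_sd = 0.3,
                                 session_sd = 0.02, seed = seed))
  })
}

# wavelength grid reused across tests
short_grid <- function(n = 12L) wavelength_grid(n, 400, 400 + 2 * (n - 1))

expect_setequal_rows <- function(a, b) {
  expect_equal(dim(a), dim(b))
  expect_true(all(a[do.call(order, as.data.frame(a)), ] ==
                  b[do.call(order, as.data.frame(b)), ]))
}
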