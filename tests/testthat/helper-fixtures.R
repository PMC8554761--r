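# Shared fixtures, computed once per test run and cached.

with_seed <- withr::with_seed

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# Moderate-size GC-mix pipeline run shared by pipeline and mechanism
# tests (deliberately below acceptance scale to keep the suite fast; the
# acceptance tests run the full-scale recoveries).
gcmix_run <- function() fixture("gcmix_run", function() {
  run_pipeline(pipeline_config("GC-mix", n_frames = 1.2e5, dt_save = 0.6,
                               seed = 7))
})

# Single-state custom preset emitting frames of one macrostate.
pinned_preset <- function(bases, state) {
  build_preset("custom", overrides = list(
    sequence = bases,
    pi = setNames(1, state),
    flux = data.frame(i = character(0), j = character(0), f = numeric(0))))
}

# Small feature series from a two-state telegraph process: state 0/1
# switching with per-step probability p, embedded in `dim` dimensions.
telegraph_features <- function(n, p, dim = 2L, noise = 0.05, seed = 1L) {
  set.seed(seed)
  flips <- runif(n) < p
  s <- as.integer(cumsum(flips) %% 2L)
  f <- outer(s, seq_len(dim) / dim) + matrix(rnorm(n * dim, sd = noise),
                                             n, dim)
  attr(f, "dt_save") <- 1
  f
}
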