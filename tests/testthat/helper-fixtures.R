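# shared fixtures: a reduced-resolution rig for fast unit tests (0.5 mm/px,
# same optics otherwise) and a lazy cache so expensive reconstructions are
# built once per test file

test_rig <- function(...) {
  make_default_rig(image_size_px = c(158L, 132L), ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# noiseless half-pipe reconstruction on the test rig
halfpipe_recon <- function() {
  cached("halfpipe_recon", {
    simulate_and_reconstruct(test_rig(), half_pipe_surface(21),
                             noise_sd = 0, seed = 1)
  })
}
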