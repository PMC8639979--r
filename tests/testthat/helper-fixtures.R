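# Shared fixtures. Expensive objects are built lazily once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A clean, noise-free two-class spec on a 6x6 grid: class 0 fires the top row,
# class 1 the bottom row.
noise_free_spec <- function(p_on_stroke = 1, p_on_background = 0, seed = 5L) {
  glyph_spec(
    n_classes = 2L, image_shape = c(6L, 6L),
    stroke_masks = list(cbind(1L, 1:6), cbind(6L, 1:6)),
    p_on_stroke = p_on_stroke, p_on_background = p_on_background,
    intensity_off = c(0L, 0L), seed = seed
  )
}

# Short default-conditions training run used by several module tests:
# the package's reference glyph task, 30 epochs.
small_run <- function() {
  cached("small_run", function() {
    spec <- glyph_spec(seed = 11L)
    tr_set <- make_glyph_dataset(spec, 1000L, "train")
    te_set <- make_glyph_dataset(spec, 300L, "test")
    net <- init_network(c(196L, 50L, 50L, 5L), seed = 2L)
    list(spec = spec,
         trace = train(net, tr_set, te_set, lr = 0.5, max_epoch = 30L, seed = 3L))
  })
}

# A frozen-weights (lr = 0) run over the same task.
frozen_run <- function() {
  cached("frozen_run", function() {
    spec <- glyph_spec(seed = 11L)
    tr_set <- make_glyph_dataset(spec, 300L, "train")
    te_set <- make_glyph_dataset(spec, 100L, "test")
    net <- init_network(c(196L, 20L, 20L, 5L), seed = 2L)
    train(net, tr_set, te_set, lr = 0, max_epoch = 12L, seed = 3L)
  })
}

# The full reference recovery run at the package's study conditions
# (14x14 / 5 classes / 2,000 train / 500 test / 300 epochs). Built once;
# consumed by the acceptance tests.
recovery_run <- function() {
  cached("recovery_run", function() {
    out <- file.path(tempdir(), "annlens-recovery")
    suppressMessages(suppressWarnings(
      run_all(run_config(seed = 1L), out, keep_trace = FALSE)))
  })
}
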