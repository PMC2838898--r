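# Expensive shared fixtures, built once per test run on first use: the
# default 20-phantom suite, the per-image pipeline stages, the trained
# classifier, and the full segmentations.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, force(expr), envir = .fixture_cache)
  .fixture_cache[[name]]
}

default_suite <- function() memo("suite", make_fixture_suite(42L, 20L))

default_stages <- function() memo("stages", {
  cfg <- pipeline_config()
  lapply(default_suite(), function(ph) retiseg:::pipeline_stages(ph$image, cfg))
})

default_model <- function() memo("model", {
  suppressWarnings(train_vessel_classifier(default_suite(), pipeline_config()))
})

default_segmentations <- function() memo("segmentations", {
  model <- default_model()
  cfg <- pipeline_config()
  lapply(default_suite(), function(ph) segment_vessels(ph$image, model, cfg))
})

# a small deterministic phantom for cheap single-image tests
small_phantom <- function() memo("small_phantom",
                                 generate_phantom(phantom_spec(seed = 11L)))
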