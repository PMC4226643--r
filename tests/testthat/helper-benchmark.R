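# The desk-scale benchmark fixture: 10 species x 30 images at the default
# moderate separation, rendered and pushed end-to-end (segmentation from
# the raw images) through the feature extractor. Memoized so the several
# tests that need it pay the rendering/extraction cost once.
.benchmark_cache <- new.env(parent = emptyenv())

benchmark_feature_table <- function() {
  if (is.null(.benchmark_cache$ft)) {
    ds <- generate_dataset(benchmark_specs(10), 30, seed = 1)
    .benchmark_cache$ft <- synthetic_feature_table(ds)
  }
  .benchmark_cache$ft
}
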