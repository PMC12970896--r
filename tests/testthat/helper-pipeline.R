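# The full-scale synthetic study (150 recordings, ~4650 windows) is expensive
# to build, so the pipeline-level tests share one lazily computed copy.
.pipeline_cache <- new.env(parent = emptyenv())

pipeline_fixture <- function() {
  if (is.null(.pipeline_cache$feats)) {
    ds <- generate_dataset(n_per_state = 50, master_seed = 1)
    .pipeline_cache$dataset <- ds
    .pipeline_cache$feats <- extract_features(ds)
    .pipeline_cache$plan <- build_fold_plan(ds, n_folds = 10, seed = 1)
  }
  list(dataset = .pipeline_cache$dataset,
       feats = .pipeline_cache$feats,
       plan = .pipeline_cache$plan)
}
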