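# One default-condition synthetic dataset and pipeline run shared across
# test files (built lazily, once per session).
.shared_cache <- new.env(parent = emptyenv())

shared_sim <- function() {
  if (is.null(.shared_cache$sim)) {
    .shared_cache$sim <- simulate_splicing_dataset(
      seed = 101, out_dir = file.path(tempdir(), "shared_sim"))
  }
  .shared_cache$sim
}

shared_build <- function() {
  if (is.null(.shared_cache$build)) {
    sim <- shared_sim()
    .shared_cache$build <- run_splice_pipeline(
      sim$paths$gtf, sim$paths$manifest, sim$paths$samples,
      blacklist = sim$paths$blacklist)
  }
  .shared_cache$build
}
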