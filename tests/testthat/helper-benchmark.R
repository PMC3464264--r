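# The end-to-end synthetic benchmark (3 actions x 6 subjects x 3 clips,
# 60x60x60 volumes, synthetic-small profile, leave-one-subject-out, with
# test-time +-10% rescaling) is expensive, so it is computed once per test
# session and shared by the tests that interrogate it.
benchmark_env <- new.env(parent = emptyenv())

benchmark_run <- function() {
  if (is.null(benchmark_env$result)) {
    ds <- generate_dataset(
      6, 3, c("translating_bar", "expanding_blob", "bouncing_dot"), seed = 11)
    benchmark_env$result <- run_protocol(
      ds, pipeline_config("synthetic-small"), classifier = "svm",
      scale_factors = c(1.1, 0.9), seed = 11)
  }
  benchmark_env$result
}
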