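# write the default-scale corpus once per test run (separate from the
# in-memory benchmark cache so either can be used independently)
default_corpus_dir <- function() {
  if (is.null(.corpus_cache$dir)) {
    dir <- file.path(tempdir(), "pmirscan-default-corpus")
    sim <- simulate_corpus(sim_config(seed = 101L), dir)
    .corpus_cache$dir <- dir
    .corpus_cache$pipeline_config <- sim$config
  }
  list(dir = .corpus_cache$dir, config = .corpus_cache$pipeline_config)
}
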