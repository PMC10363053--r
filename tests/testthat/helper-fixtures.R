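# shared fixtures and independent oracles for the test suite

rand_dna <- function(n, len) {
  if (length(len) == 1L) len <- rep(len, n)
  vapply(len, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

rc <- function(x) pmirscan::revcomp(x)

# exhaustive end-to-end matcher: does `read` occur in any sequence of `seqs`
# (either strand) with at most max_mm substitutions?
host_match_oracle <- function(read, seqs, max_mm) {
  L <- nchar(read)
  for (variant in c(read, rc(read))) {
    v <- strsplit(variant, "")[[1]]
    for (s in seqs) {
      n <- nchar(s)
      if (n < L) next
      ch <- strsplit(s, "")[[1]]
      for (start in seq_len(n - L + 1L)) {
        if (sum(v != ch[start:(start + L - 1L)]) <= max_mm) return(TRUE)
      }
    }
  }
  FALSE
}

# exhaustive sliding-window target scorer (independent of the C++ scan)
target_scan_oracle <- function(mirna, tx, schema = pmirscan::target_schema()) {
  L <- nchar(mirna)
  n <- nchar(tx)
  if (n < L) {
    return(data.frame(position = integer(), expectation = numeric()))
  }
  pos <- 0:(n - L)
  ex <- vapply(pos, function(p) {
    pmirscan::expectation_score(mirna, substr(tx, p + 1L, p + L), schema)
  }, numeric(1))
  keep <- ex <= schema$expectation_cutoff
  data.frame(position = pos[keep], expectation = ex[keep])
}

# exhaustive hypergeometric upper tail P(X >= k) by direct enumeration
hyper_tail_oracle <- function(k, K, N, n) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# four tiny classification databases with known content
toy_dbs <- function(plant = c(pmir1 = "ACGTGCATCGATTGCAAGTCA"),
                    human_mir = c(hsa1 = "TTGACCGGATCGTAGCTAGCT"),
                    other = c(oth1 = "GGCATGCTAGCTTAGGCCTAA"),
                    refseq = c(NM1 = paste0(strrep("CT", 30),
                                            "GATTACAGATTACAGATTACA",
                                            strrep("GA", 30)))) {
  list(sequence_db("plant_mirbase", plant),
       sequence_db("human_mirbase", human_mir),
       sequence_db("other_mirbase", other),
       sequence_db("human_refseq_mrna", refseq))
}

# one shared default-scale corpus + benchmark, built once per test run
.corpus_cache <- new.env(parent = emptyenv())

default_benchmark <- function() {
  if (is.null(.corpus_cache$bench)) {
    .corpus_cache$bench <- run_synthetic_benchmark(sim_config(seed = 101L))
  }
  .corpus_cache$bench
}
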