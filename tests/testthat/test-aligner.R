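test_that("Smith-Waterman handles the worked alignment cases", {
  s <- scoring_scheme()
  perfect <- smith_waterman("ACGT", "ACGT", s)
  expect_equal(perfect$raw_score, 8L)
  expect_equal(perfect$identity, 1.0)

  # best local alignment of ACGTT/ACGAT is the 3-nt prefix (score 6), not
  # the full-length alignment with one mismatch (score 5)
  a <- smith_waterman("ACGTT", "ACGAT", s)
  expect_equal(a$raw_score, 6L)

  # no positive-scoring cell -> empty alignment
  z <- smith_waterman("AAAA", "TTTT", s)
  expect_equal(z$raw_score, 0L)
  expect_equal(diff(z$query_span), 0L)
  expect_equal(z$identity, 0)

  expect_error(smith_waterman("", "ACGT", s), "non-empty")
  expect_error(smith_waterman("ACGU", "ACGT", s), "outside A/C/G/T")
})

test_that("Smith-Waterman agrees with an independent aligner on random pairs", {
  skip_if_not_installed("Biostrings")
  s <- scoring_scheme()
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  set.seed(31)
  for (i in 1:50) {
    q <- rand_dna(1, sample(8:30, 1))
    subj <- rand_dna(1, sample(8:40, 1))
    mine <- smith_waterman(q, subj, s)$raw_score
    if (mine == 0) next
    ref <- Biostrings::score(Biostrings::pairwiseAlignment(
      q, subj, type = "local", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2))
    expect_equal(mine, ref)
  }
})

test_that("identity is 1 exactly when there are no mismatches and no gaps", {
  s <- scoring_scheme()
  set.seed(17)
  for (i in 1:40) {
    q <- rand_dna(1, sample(10:25, 1))
    subj <- rand_dna(1, sample(10:40, 1))
    a <- smith_waterman(q, subj, s)
    if (a$raw_score == 0) next
    expect_equal(a$identity == 1,
                 a$matches == a$length && a$gaps == 0L)
  }
})

test_that("alignment score is symmetric under joint reverse complement", {
  s <- scoring_scheme()
  set.seed(23)
  for (i in 1:30) {
    q <- rand_dna(1, sample(10:25, 1))
    subj <- rand_dna(1, sample(10:40, 1))
    expect_equal(smith_waterman(q, subj, s)$raw_score,
                 smith_waterman(rc(q), rc(subj), s)$raw_score)
  }
})

test_that("bit score follows the Karlin-Altschul closed form", {
  s <- scoring_scheme()  # lambda 0.625, K 0.41
  expect_equal(bitscore(0, s), -log(0.41) / log(2), tolerance = 1e-12)
  expect_equal(bitscore(42, s), (0.625 * 42 - log(0.41)) / log(2),
               tolerance = 1e-12)
  expect_equal(bitscore(42, s), 39.157, tolerance = 1e-4)
  # monotone in the raw score
  ss <- bitscore(0:50, s)
  expect_true(all(diff(ss) > 0))
})

test_that("E-value formula: scale, limits, linearity", {
  expect_equal(evalue(10, 20, 1000), 20000 * 2^-10)
  expect_equal(evalue(10, 20, 1000), 19.53125)
  expect_lt(evalue(1e6, 20, 1000), 1e-300)  # huge bit score -> E -> 0
  expect_equal(evalue(10, 20, 2000), 2 * evalue(10, 20, 1000))
  expect_error(evalue(10, 0, 1000), "positive")
})

test_that("seeded search finds exact containments and respects the seed requirement", {
  s <- scoring_scheme()
  set.seed(5)
  q <- rand_dna(1, 21)
  db <- c(acc1 = paste0("TTAAGG", q, "CCGGAA"), acc2 = rand_dna(1, 40))
  idx <- seq_index(db, 11)
  hit <- seeded_search(q, idx, s)
  expect_equal(hit$raw_score, 21L * 2L)
  expect_equal(hit$identity, 1.0)
  expect_equal(hit$subject_id, "acc1")

  # reverse-complement containment is found on the minus strand
  hit_rc <- seeded_search(rc(q), idx, s)
  expect_equal(hit_rc$raw_score, 42L)
  expect_equal(hit_rc$strand, "-")

  # no shared 11-mer -> no hit at all
  expect_null(seeded_search(strrep("A", 21),
                            seq_index(c(x = strrep("C", 50)), 11), s))

  expect_error(seq_index(c(a = "ACGTACGTACGT"), word_size = 3), ">= 4")
})

test_that("seeded search equals full Smith-Waterman when a seed lies on the optimum", {
  s <- scoring_scheme()
  set.seed(71)
  for (i in 1:100) {
    q <- rand_dna(1, sample(12:30, 1))
    core_len <- sample(11:nchar(q), 1)
    start <- sample(nchar(q) - core_len + 1L, 1)
    core <- substr(q, start, start + core_len - 1L)
    subj <- paste0(rand_dna(1, sample(0:8, 1)), core,
                   rand_dna(1, sample(0:8, 1)))
    idx <- seq_index(c(s1 = subj), 11)
    hit <- seeded_search(q, idx, s)
    expect_equal(hit$raw_score, smith_waterman(q, subj, s)$raw_score)
  }
})

test_that("blast-style tabular output carries 1-based coordinates", {
  s <- scoring_scheme()
  q <- "ACGTACGTACGTACGTACGTA"
  idx <- seq_index(c(subj = paste0("GGGGG", q, "GGGGG")), 11)
  hits <- pmirscan:::index_hits(q, idx, s, best_only = TRUE)
  tab <- as_blast_tab(hits)
  expect_equal(tab$qstart, 1L)
  expect_equal(tab$qend, nchar(q))
  expect_equal(tab$sstart, 6L)
  expect_equal(tab$pident, 100)
})
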