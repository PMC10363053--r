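test_that("expectation score worked cases", {
  # 21-nt miRNA with known bases at the probed positions
  mirna <- "ACGTACGTACGTACGTACGTA"
  perfect_site <- rc(mirna)
  expect_equal(expectation_score(mirna, perfect_site), 0.0)

  # G:U wobble at miRNA position 15 (outside the 2-13 seed): 0.5
  # miRNA position 15 ("G") pairs with site position L - 15 + 1 = 7;
  # turning the site base from C into T makes a G:U pair
  stopifnot(substr(mirna, 15, 15) == "G")
  site_gu <- rc(mirna)
  substr(site_gu, 7, 7) <- "T"
  expect_equal(expectation_score(mirna, site_gu), 0.5)

  # plain mismatch at miRNA position 5 (inside the seed): 1.0 * 2 = 2.0
  site_mm <- rc(mirna)
  pos5_site <- nchar(mirna) - 5 + 1
  stopifnot(substr(mirna, 5, 5) == "A")   # pairs "T"; "C" is a plain mismatch
  substr(site_mm, pos5_site, pos5_site) <- "C"
  expect_equal(expectation_score(mirna, site_mm), 2.0)

  expect_error(expectation_score(mirna, "ACGT"), "same length")
})

test_that("expectation score is monotone in the number of mismatches", {
  set.seed(89)
  mirna <- rand_dna(1, 21)
  site <- rc(mirna)
  prev <- expectation_score(mirna, site)
  mutable <- sample(21, 10)
  for (p in mutable) {
    substr(site, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                         substr(site, p, p)), 1)
    cur <- expectation_score(mirna, site)
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("target prediction equals exhaustive window scoring", {
  set.seed(97)
  schema <- target_schema()
  mirna <- rand_dna(1, 21)
  # transcripts with a planted perfect site plus random background
  tx <- c(t1 = paste0(rand_dna(1, 150), rc(mirna), rand_dna(1, 150)),
          t2 = rand_dna(1, 300))
  pred <- predict_targets(mirna, tx, schema)
  expect_true(nrow(pred) >= 1L)
  top <- pred[1, ]
  expect_equal(top$expectation, 0.0)
  expect_equal(top$transcript_id, "t1")
  expect_equal(top$position, 150L)

  for (id in names(tx)) {
    oracle <- target_scan_oracle(mirna, tx[[id]], schema)
    got <- pred[pred$transcript_id == id, c("position", "expectation")]
    rownames(got) <- NULL
    oracle <- oracle[order(oracle$position), ]
    got <- got[order(got$position), ]
    rownames(oracle) <- rownames(got) <- NULL
    expect_equal(got, oracle)
  }
})

test_that("degenerate and multi-site target cases", {
  # all-A miRNA on an all-A transcript: every position is a doubled mismatch
  expect_equal(nrow(predict_targets(strrep("A", 21),
                                    c(t = strrep("A", 100)))), 0L)
  # two disjoint perfect sites are both reported
  set.seed(101)
  mirna <- rand_dna(1, 21)
  tx <- c(t = paste0(rand_dna(1, 50), rc(mirna), rand_dna(1, 50), rc(mirna),
                     rand_dna(1, 50)))
  pred <- predict_targets(mirna, tx)
  expect_equal(sum(pred$expectation == 0), 2L)
  expect_equal(pred$position[pred$expectation == 0], c(50L, 121L))
})

test_that("hypergeometric enrichment matches exact enumeration", {
  universe <- sprintf("g%02d", 1:10)
  res <- hypergeom_enrich(universe[1:5], list(T1 = universe[1:5]), universe)
  expect_equal(res$p_value, 1 / 252, tolerance = 1e-12)
  expect_equal(res$k, 5L)
  expect_equal(res$neg_log10_adjusted_p, -log10(res$adjusted_p))

  # k = 0 -> p = 1
  res0 <- hypergeom_enrich(universe[1:5], list(T1 = universe[6:10]), universe)
  expect_equal(res0$p_value, 1.0)

  # random configurations with N <= 25 against the enumeration oracle
  set.seed(103)
  for (i in 1:30) {
    N <- sample(5:25, 1)
    uni <- sprintf("u%03d", seq_len(N))
    K <- sample(N, 1)
    n <- sample(N, 1)
    term <- sample(uni, K)
    query <- sample(uni, n)
    k <- length(intersect(term, query))
    p <- hypergeom_enrich(query, list(T = term), uni)$p_value
    expect_equal(p, hyper_tail_oracle(k, K, N, n), tolerance = 1e-12)
  }

  expect_error(hypergeom_enrich(c("g01", "nope"), list(T1 = "g01"), universe),
               "nope")
})

test_that("BH adjustment and sorting follow the step-up procedure", {
  universe <- sprintf("g%02d", 1:20)
  # engineer three terms with increasing overlap to the query
  query <- universe[1:10]
  terms <- list(A = universe[1:8], B = universe[c(1:4, 11:14)],
                C = universe[11:18])
  res <- hypergeom_enrich(query, terms, universe)
  expect_equal(res$adjusted_p, sort(res$adjusted_p))
  expect_true(all(res$adjusted_p >= res$p_value))
  expect_equal(res$adjusted_p, unname(p.adjust(res$p_value, "BH")),
               tolerance = 1e-12)
  # the textbook example: (0.01, 0.02, 0.03) with m = 3 all adjust to 0.03
  expect_equal(unname(p.adjust(c(0.01, 0.02, 0.03), "BH")),
               c(0.03, 0.03, 0.03))
})

test_that("GMT files round-trip", {
  sets <- list(T1 = c("g1", "g2", "g3"), T2 = c("g4"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f, descriptions = c(T1 = "first", T2 = "second"))
  back <- read_gmt(f)
  expect_equal(back$sets, sets)
  expect_equal(unname(back$names["T1"]), "first")
})
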