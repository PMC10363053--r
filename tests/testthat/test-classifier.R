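mk_hit <- function(bits, full = FALSE, acc = "acc", identity = 1) {
  list(best_accession = acc, best_bitscore = bits, best_identity = identity,
       full_length_identity = full)
}

test_that("discard-rule truth table", {
  # plant strictly on top, human hit below and not full-length -> validated
  expect_equal(classify(list(
    plant_mirbase = mk_hit(40.1), human_mirbase = NULL, other_mirbase = NULL,
    human_refseq_mrna = mk_hit(35.0, full = FALSE, identity = 0.9))),
    "validated_pmiRNA")

  # 100% full-length identity with a human sequence dominates everything
  expect_equal(classify(list(
    plant_mirbase = mk_hit(42.0), human_mirbase = NULL, other_mirbase = NULL,
    human_refseq_mrna = mk_hit(40.0, full = TRUE))),
    "discarded_human_identity")

  # another database on top -> not the highest bit score for plant
  expect_equal(classify(list(
    plant_mirbase = mk_hit(38.0), human_mirbase = NULL,
    other_mirbase = mk_hit(40.0), human_refseq_mrna = NULL)),
    "discarded_not_top_plant")

  # tie with a human hit (not full-length identity) -> strict maximum fails
  expect_equal(classify(list(
    plant_mirbase = mk_hit(40.0), human_mirbase = mk_hit(40.0, identity = 0.95),
    other_mirbase = NULL, human_refseq_mrna = NULL)),
    "discarded_not_top_plant")
})

test_that("classification is a total function over hit patterns", {
  none <- list(plant_mirbase = NULL, human_mirbase = NULL,
               other_mirbase = NULL, human_refseq_mrna = NULL)
  expect_equal(classify(none), "no_hit")

  only_other <- none
  only_other$other_mirbase <- mk_hit(30)
  expect_equal(classify(only_other), "discarded_not_top_plant")

  only_plant <- none
  only_plant$plant_mirbase <- mk_hit(30)
  expect_equal(classify(only_plant), "validated_pmiRNA")

  # full-length human identity wins even without any plant hit
  human_only <- none
  human_only$human_mirbase <- mk_hit(42, full = TRUE)
  expect_equal(classify(human_only), "discarded_human_identity")

  expect_error(classify(list(plant_mirbase = NULL)), "named list")
})

test_that("search_all_dbs reports the best hit per database", {
  set.seed(61)
  plant_seq <- rand_dna(1, 21)
  both_seq <- rand_dna(1, 21)
  dbs <- toy_dbs(
    plant = c(pmir1 = plant_seq, pmir2 = both_seq),
    refseq = c(NM1 = paste0(rand_dna(1, 40), both_seq, rand_dna(1, 40)))
  )
  hits <- search_all_dbs(c(plant_seq, both_seq, strrep("AT", 11)), dbs)

  h1 <- hits[hits$sequence == plant_seq, ]
  expect_equal(h1$db_name, "plant_mirbase")
  expect_equal(h1$identity, 1)
  expect_true(h1$full_length_identity)

  h2 <- hits[hits$sequence == both_seq, ]
  expect_setequal(h2$db_name, c("plant_mirbase", "human_refseq_mrna"))
  expect_equal(diff(h2$bitscore), 0)
  expect_true(all(h2$full_length_identity))

  # a sequence sharing no 11-mer seed with any database has no hits at all
  expect_equal(nrow(hits[hits$sequence == strrep("AT", 11), ]), 0L)

  expect_error(search_all_dbs("ACGT", toy_dbs()[1:3]), "four databases")
})

test_that("classify_sequences applies the verdicts end to end", {
  set.seed(67)
  validated_seq <- rand_dna(1, 21)
  human_seq <- rand_dna(1, 21)
  dbs <- toy_dbs(
    plant = c(pmir1 = validated_seq),
    refseq = c(NM1 = paste0(rand_dna(1, 30), human_seq, rand_dna(1, 30)))
  )
  rec <- classify_sequences(c(validated_seq, human_seq, strrep("AT", 11)),
                            dbs)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$verdict[rec$sequence == validated_seq],
               "validated_pmiRNA")
  expect_equal(rec$best_plant_match[rec$sequence == validated_seq], "pmir1")
  expect_equal(rec$verdict[rec$sequence == human_seq],
               "discarded_human_identity")
  expect_equal(rec$verdict[rec$sequence == strrep("AT", 11)], "no_hit")
})

test_that("KDE matches the closed-form normal density and integrates to 1", {
  set.seed(73)
  x <- rnorm(1000)
  d <- kde(x)
  at0 <- d$density[which.min(abs(d$x))]
  expect_equal(at0, dnorm(0), tolerance = 0.05 / dnorm(0))
  integral <- sum(diff(d$x) * (head(d$density, -1) + d$density[-1]) / 2)
  expect_equal(integral, 1, tolerance = 0.01)

  expect_error(kde(c(1)), "at least 2")
  expect_error(kde(rep(3.5, 10)), "degenerate")
})

test_that("overlap coefficient behaves on identical, disjoint and swapped inputs", {
  set.seed(79)
  x <- rnorm(500)
  y <- rnorm(500, mean = 1000)
  da <- kde(x, from = -5, to = 1005, n = 2048)
  db <- kde(y, from = -5, to = 1005, n = 2048)
  expect_equal(overlap_coefficient(da, da), 1, tolerance = 0.01)
  expect_lt(overlap_coefficient(da, db), 0.01)
  expect_equal(overlap_coefficient(da, db), overlap_coefficient(db, da))
  expect_error(overlap_coefficient(da, kde(y, from = 0, to = 1, n = 2048)),
               "common grid")
  expect_error(overlap_coefficient(da, kde(y, from = -5, to = 1005, n = 512)),
               "common grid")
})
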