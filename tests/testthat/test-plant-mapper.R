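toy_plant <- function(seed = 13, mirna = NULL) {
  set.seed(seed)
  mirna <- mirna %||% rand_dna(1, 21)
  g <- rand_dna(1, 3000)
  pos <- 1001L
  substr(g, pos, pos + nchar(mirna) - 1L) <- mirna
  feats <- data.frame(seqid = "chr1", source = "s", feature_type = "miRNA",
                      start = pos, end = pos + nchar(mirna) - 1L, score = ".",
                      strand = "+", phase = ".", attributes = "ID=m1",
                      stringsAsFactors = FALSE)
  list(pg = plant_genome("sp", c(chr1 = g), feats), mirna = mirna, pos = pos)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("full-identity genome matching counts reads per species", {
  tp <- toy_plant()
  res <- map_to_plant_genomes(tp$mirna, list(tp$pg))
  expect_equal(res[[1]]$aligned_read_count, 1L)
  expect_equal(res[[1]]$alignments$sstart, tp$pos - 1L)  # 0-based

  # one mismatch fails the default min_identity = 1 requirement
  mut <- tp$mirna
  substr(mut, 11, 11) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mut, 11, 11))[1]
  res_mut <- map_to_plant_genomes(mut, list(tp$pg))
  expect_equal(res_mut[[1]]$aligned_read_count, 0L)
  # ... but qualifies when thresholds are relaxed (with a seed short enough
  # to fit between mismatches, as a mutation-tolerant run would use)
  res_rel <- map_to_plant_genomes(mut, list(tp$pg), min_identity = 0.9,
                                  min_coverage = 0.9, word_size = 8)
  expect_equal(res_rel[[1]]$aligned_read_count, 1L)

  # a read matching two species counts once in each
  tp2 <- toy_plant(seed = 14, mirna = tp$mirna)
  res2 <- map_to_plant_genomes(tp$mirna, list(tp$pg, tp2$pg))
  expect_equal(vapply(res2, `[[`, numeric(1), "aligned_read_count"), c(1, 1))
})

test_that("per-species counts are invariant to read and record order", {
  set.seed(41)
  mirnas <- rand_dna(5, 21)
  g <- rand_dna(1, 5000)
  for (i in seq_along(mirnas)) {
    substr(g, 500 * i, 500 * i + 20) <- mirnas[i]
  }
  pg <- plant_genome("sp", c(chr1 = g),
                     data.frame(seqid = character(), source = character(),
                                feature_type = character(), start = integer(),
                                end = integer(), score = character(),
                                strand = character(), phase = character(),
                                attributes = character()))
  r1 <- map_to_plant_genomes(mirnas, list(pg))[[1]]
  r2 <- map_to_plant_genomes(rev(mirnas), list(pg))[[1]]
  expect_equal(r1$aligned_read_count, r2$aligned_read_count)
  expect_equal(r1$alignments[order(r1$alignments$sequence), ]$sstart,
               r2$alignments[order(r2$alignments$sequence), ]$sstart)
})

test_that("genome-size normalization follows the reads-per-Mb formula", {
  expect_equal(normalize_by_genome_size(1000, 500e6), 2.0)
  expect_equal(normalize_by_genome_size(0, 123456), 0.0)
  expect_equal(normalize_by_genome_size(350, 100e6), 3.5)
  expect_error(normalize_by_genome_size(10, 0), "positive")
  # equal counts, different genome sizes: inversely proportional
  expect_equal(normalize_by_genome_size(100, 2e6) /
                 normalize_by_genome_size(100, 4e6), 2)
})

test_that("annotation intersection keeps only well-overlapped whitelisted features", {
  feats <- data.frame(seqid = "chr1", source = "s", feature_type = "miRNA",
                      start = 90L, end = 160L, score = ".", strand = "+",
                      phase = ".", attributes = "ID=m1",
                      stringsAsFactors = FALSE)
  aln <- data.frame(sequence = "X", seqid = "chr1", strand = "+",
                    sstart = 99L, send = 120L, identity = 1, coverage = 1,
                    score = 42L, bitscore = 39.2, stringsAsFactors = FALSE)
  expect_equal(nrow(intersect_mirna_annotations(aln, feats)), 1L)

  # non-whitelisted features never reach this step (dropped at GFF3 read),
  # so an empty feature table drops everything
  expect_equal(nrow(intersect_mirna_annotations(aln, feats[0, ])), 0L)

  # 10 nt of a 21-nt alignment is below the 0.9 overlap requirement
  aln2 <- aln
  aln2$sstart <- 150L  # overlaps [151,160] = 10 nt of 21
  aln2$send <- 171L
  expect_equal(nrow(intersect_mirna_annotations(aln2, feats, 0.9)), 0L)
  expect_equal(nrow(intersect_mirna_annotations(aln2, feats, 0.4)), 1L)

  # wrong seqid never overlaps
  aln3 <- aln
  aln3$seqid <- "chr2"
  expect_equal(nrow(intersect_mirna_annotations(aln3, feats)), 0L)
})

test_that("spiked reads inside features are kept; reads outside are dropped", {
  set.seed(55)
  g <- rand_dna(1, 4000)
  inside <- rand_dna(1, 21)
  substr(g, 1001, 1021) <- inside
  outside <- substr(g, 3001, 3021)
  feats <- data.frame(seqid = "chr1", source = "s", feature_type = "miRNA",
                      start = 1001L, end = 1021L, score = ".", strand = "+",
                      phase = ".", attributes = "ID=m1",
                      stringsAsFactors = FALSE)
  pg <- plant_genome("sp", c(chr1 = g), feats)
  res <- map_to_plant_genomes(c(inside, outside), list(pg))[[1]]
  expect_equal(res$aligned_read_count, 2L)
  kept <- intersect_mirna_annotations(res$alignments, feats)
  expect_equal(unique(kept$sequence), inside)
})
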