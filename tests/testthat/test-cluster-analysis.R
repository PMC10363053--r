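test_that("clustering merges identical columns first and is permutation-stable", {
  set.seed(107)
  m <- matrix(rlnorm(30), nrow = 5,
              dimnames = list(sprintf("s%d", 1:5), sprintf("e%d", 1:6)))
  m[, 2] <- m[, 1]  # identical experiments
  sc <- hierarchical_cluster(m)
  hc <- sc$experiment_hclust
  expect_equal(hc$height[1], 0)
  expect_setequal(hc$labels[-hc$merge[1, ]], c("e1", "e2"))

  # permuting rows leaves experiment merge heights unchanged
  sc2 <- hierarchical_cluster(m[sample(5), ])
  expect_equal(sort(sc2$experiment_hclust$height), sort(hc$height))
})

test_that("block-diagonal matrices split into their blocks", {
  m <- matrix(0, 6, 6, dimnames = list(sprintf("s%d", 1:6),
                                       sprintf("e%d", 1:6)))
  m[1:3, 1:3] <- 5
  m[4:6, 4:6] <- 7
  sc <- hierarchical_cluster(m)
  g <- cut_groups(sc, 2, 2)
  expect_setequal(g$experiment_groups[[1]],
                  setdiff(sprintf("e%d", 1:6), g$experiment_groups[[2]]))
  blocks <- lapply(g$experiment_groups, sort)
  expect_true(identical(blocks[[1]], c("e1", "e2", "e3")) ||
                identical(blocks[[1]], c("e4", "e5", "e6")))

  # degenerate cuts
  g1 <- cut_groups(sc, 1, 1)
  expect_equal(length(g1$experiment_groups), 1L)
  expect_equal(length(g1$experiment_groups[[1]]), 6L)
  g6 <- cut_groups(sc, 6, 6)
  expect_equal(lengths(g6$experiment_groups), setNames(rep(1L, 6),
                                                       names(g6$experiment_groups)))
  expect_error(cut_groups(sc, 7, 2), "between 1 and")
  expect_error(cut_groups(sc, 0, 2), "between 1 and")
})

test_that("planted noiseless blocks are recovered exactly (ARI 1)", {
  skip_if_not_installed("mclust")
  sim <- simulate_block_matrix(n_blocks = 3, experiments_per_block = 4,
                               sequences_per_block = 8, noise = 0,
                               seed = 11)
  sc <- hierarchical_cluster(sim$matrix)
  g <- cut_groups(sc, 3, 3)
  memb <- rep(NA_integer_, ncol(sim$matrix))
  names(memb) <- colnames(sim$matrix)
  for (i in seq_along(g$experiment_groups)) {
    memb[g$experiment_groups[[i]]] <- i
  }
  ari <- mclust::adjustedRandIndex(memb[colnames(sim$matrix)],
                                   sim$experiment_blocks)
  expect_equal(ari, 1.0)
})

test_that("presence/absence mode clusters on shared detection patterns", {
  m <- matrix(0, 4, 4, dimnames = list(sprintf("s%d", 1:4),
                                       sprintf("e%d", 1:4)))
  m[1:2, 1:2] <- c(1, 9, 4, 2)  # different magnitudes, same presence
  m[3:4, 3:4] <- c(5, 5, 5, 5)
  sc <- hierarchical_cluster(m, distance = "binary", transform = "presence")
  g <- cut_groups(sc, 2, 2)
  expect_setequal(lapply(g$experiment_groups, sort),
                  list(c("e1", "e2"), c("e3", "e4")))
})

test_that("project distribution rows sum to 100 at two-decimal precision", {
  groups <- list(EG1 = sprintf("x%d", 1:7), EG2 = "x8", EG3 = c("x9", "x10"))
  e2p <- setNames(c(rep("pA", 2), rep("pB", 5), "pC", "pC", "pC"),
                  sprintf("x%d", 1:10))
  pd <- project_distribution(groups, e2p)
  # 2:5 ratio -> 28.57 / 71.43
  expect_equal(pd$pA[1], 28.57)
  expect_equal(pd$pB[1], 71.43)
  # homogeneous and singleton groups
  expect_equal(pd$pC[2], 100.00)
  expect_equal(pd$pA[2], 0.00)
  expect_equal(pd$pC[3], 100.00)
  sums <- rowSums(pd[, c("pA", "pB", "pC")])
  expect_true(all(abs(sums - 100) <= 0.02))

  expect_error(project_distribution(list(EG1 = character()), e2p), "empty")
  expect_error(project_distribution(list(EG1 = "zz"), e2p), "without a project")
})

test_that("consensus search finds planted cores and nothing in random sets", {
  set.seed(113)
  core <- "ACGTACG"
  seqs <- paste0(rand_dna(12, 7), core, rand_dna(12, 7))
  hits <- consensus_search(seqs, 7, 7, min_fraction = 1.0)
  expect_true(core %in% hits$kmer)
  expect_equal(hits$fraction[hits$kmer == core], 1.0)

  # invariance to order and duplication
  hits2 <- consensus_search(c(rev(seqs), seqs), 7, 7, min_fraction = 1.0)
  expect_equal(hits2, hits)

  # 50 independent random 21-mers share no 10-mer
  rnd <- rand_dna(50, 21)
  expect_equal(nrow(consensus_search(rnd, 10, 12, min_fraction = 0.9)), 0L)

  # single sequence: every k-mer at fraction 1
  one <- consensus_search("ACGTACGTAA", 9, 9, min_fraction = 1.0)
  expect_setequal(one$kmer, c("ACGTACGTA", "CGTACGTAA"))
  expect_true(all(one$fraction == 1.0))

  expect_warning(consensus_search(c("ACGTACGTAA", "ACG"), 5, 5), "excluded")
  expect_error(consensus_search("ACGTAC", 1, 5), "kmin")
})

test_that("single-axis matrices produce trivial dendrograms with a warning", {
  m <- matrix(1:4, nrow = 1, dimnames = list("s1", sprintf("e%d", 1:4)))
  expect_warning(sc <- hierarchical_cluster(m), "single sequence")
  g <- cut_groups(sc, 2, 1)
  expect_equal(length(g$sequence_groups), 1L)
  expect_equal(g$sequence_groups[[1]], "s1")
})
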