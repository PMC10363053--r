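small_cfg <- function(seed = 5, ...) {
  args <- modifyList(
    list(seed = seed, host_genome_len = 20000L, host_tx_count = 5L,
         host_tx_len = 600L, extrachromosomal_len = 2000L,
         plant_genome_len = 30000L, mirnas_per_species = 8L,
         reads_per_experiment = 500L, n_target_transcripts = 8L,
         target_transcript_len = 400L),
    list(...))
  do.call(sim_config, args)
}

test_that("simulated references satisfy their construction invariants", {
  refs <- simulate_references(small_cfg())

  # every plant miRNA occurs verbatim inside an annotated feature of its genome
  for (i in seq_len(nrow(refs$mirnas))) {
    row <- refs$mirnas[i, ]
    pg <- refs$plants[[match(row$species,
                             vapply(refs$plants, `[[`, character(1),
                                    "species_name"))]]
    g <- pg$genome[[1]]
    pos <- regexpr(row$sequence, g, fixed = TRUE)
    expect_gt(pos, 0)
    inside <- any(pg$features$start <= pos &
                    pg$features$end >= pos + nchar(row$sequence) - 1L &
                    pg$features$feature_type %in%
                      c("miRNA", "miRNA_primary_transcript", "pre-miRNA"))
    expect_true(inside)
  }

  # the decoy source is an exact substring of a human mRNA record and of
  # every plant genome's annotated ambiguous region
  decoy <- refs$decoy$sequence
  refseq <- refs$dbs$human_refseq_mrna$sequences
  expect_true(any(grepl(decoy, refseq, fixed = TRUE)))
  for (pg in refs$plants) {
    expect_true(grepl(decoy, pg$genome[[1]], fixed = TRUE))
  }

  # human paralogs are >= 95% similar to their plant miRNA but not identical
  par <- refs$mirnas[refs$mirnas$human_paralog, ]
  hdb <- refs$dbs$human_mirbase$sequences
  for (i in seq_len(nrow(par))) {
    p <- hdb[[paste0("hsa-par-", par$mirna_id[i])]]
    d <- sum(strsplit(p, "")[[1]] != strsplit(par$sequence[i], "")[[1]])
    expect_equal(d, 1L)
  }

  # a planted perfect target site exists for each positive control
  for (i in seq_len(nrow(refs$positive_controls))) {
    pc <- refs$positive_controls[i, ]
    tx <- refs$transcripts[[pc$transcript_id]]
    expect_equal(substr(tx, pc$position + 1L, pc$position + 21L),
                 rc(pc$sequence))
  }
})

test_that("equal seeds give byte-identical corpora; different seeds differ", {
  cfg <- small_cfg(seed = 9)
  d1 <- file.path(withr::local_tempdir(), "c1")
  d2 <- file.path(withr::local_tempdir(), "c2")
  simulate_corpus(cfg, d1)
  simulate_corpus(cfg, d2)
  files <- list.files(d1, recursive = TRUE)
  files <- setdiff(files, "config.yaml")  # embeds absolute paths
  expect_gt(length(files), 10)
  for (f in files) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = f)
  }
  d3 <- file.path(withr::local_tempdir(), "c3")
  simulate_corpus(small_cfg(seed = 10), d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "reads", "exp01.fastq"))),
    unname(tools::md5sum(file.path(d3, "reads", "exp01.fastq")))))
})

test_that("read classes follow the configured fractions and manifest covers all reads", {
  cfg <- small_cfg(seed = 21, reads_per_experiment = 1000L)
  refs <- simulate_references(cfg)
  sim <- simulate_reads(cfg, refs)
  expect_equal(nrow(sim$reads), 5000L)
  expect_equal(sort(sim$manifest$read_id), sort(sim$reads$read_id))
  # integral fractions x reads -> exact class counts per experiment
  tab <- table(sim$manifest$experiment_id, sim$manifest$class)
  expect_true(all(tab[, "host"] == 700))
  expect_true(all(tab[, "plant_mirna"] == 100))
  expect_true(all(tab[, "human_rrna_decoy"] == 100))
  expect_true(all(tab[, "random"] == 100))
  expect_equal(unname(sim$library_sizes), rep(1000, 5))

  # spiked miRNAs follow the project block plan
  plan <- refs$block_plan
  e2p <- cfg$experiment_to_project
  spiked <- sim$manifest[sim$manifest$class == "plant_mirna", ]
  for (e in unique(spiked$experiment_id)) {
    allowed <- plan[[e2p[[e]]]]
    expect_true(all(spiked$mirna_id[spiked$experiment_id == e] %in% allowed))
  }

  # read lengths respect the ingestion window
  expect_true(all(nchar(sim$reads$sequence) >= cfg$min_read_len))
  expect_true(all(nchar(sim$reads$sequence) <= cfg$max_read_len))
})

test_that("degenerate configurations behave", {
  cfg0 <- small_cfg(seed = 2, reads_per_experiment = 0L)
  refs <- simulate_references(cfg0)
  sim <- simulate_reads(cfg0, refs)
  expect_equal(nrow(sim$reads), 0L)
  expect_equal(nrow(sim$manifest), 0L)
  expect_equal(unname(sim$library_sizes), rep(0, 5))

  cfg_host <- small_cfg(seed = 3, reads_per_experiment = 200L,
                        class_fractions = c(host = 1, plant_mirna = 0,
                                            human_rrna_decoy = 0, random = 0))
  sim2 <- simulate_reads(cfg_host, simulate_references(cfg_host))
  expect_true(all(sim2$manifest$class == "host"))

  expect_error(sim_config(class_fractions = c(host = 0.5, plant_mirna = 0.2,
                                              human_rrna_decoy = 0.2,
                                              random = 0.2)), "sum to 1")
  expect_error(sim_config(mirna_len = 17), "trimming")
})

test_that("block matrices carry the planted structure", {
  sim <- simulate_block_matrix(n_blocks = 2, experiments_per_block = 3,
                               sequences_per_block = 4, noise = 0, seed = 7)
  expect_equal(dim(sim$matrix), c(8L, 6L))
  expect_true(all(sim$matrix[1:4, 1:3] > 0))
  expect_true(all(sim$matrix[5:8, 1:3] == 0))
  # determinism
  sim2 <- simulate_block_matrix(n_blocks = 2, experiments_per_block = 3,
                                sequences_per_block = 4, noise = 0, seed = 7)
  expect_identical(sim$matrix, sim2$matrix)
})
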