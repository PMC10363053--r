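READ_CLASSES <- c("host", "plant_mirna", "human_rrna_decoy", "random")

rand_seq <- function(n, len) {
  if (length(len) == 1L) len <- rep(len, n)
  vapply(len, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

# Fixed internal rRNA-like decoy source: a synthetic GC-rich sequence built
# once from its own frozen generator seed, independent of any simulation
# config. Not derived from any real genome.
rrna_like_sequence <- function() {
  with_seed(424242L, {
    paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE,
                 prob = c(0.18, 0.32, 0.32, 0.18)), collapse = "")
  })
}

substitute_bases <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

#' Simulation configuration
#'
#' Defines the synthetic study: host references, plant genomes with embedded
#' annotated miRNAs, the four classification databases (including rRNA-like
#' decoys shared between the read pool and the human mRNA database, and
#' near-identical human paralogs of some plant miRNAs), target transcripts
#' with a planted perfect site, and multi-project experiments whose spiked
#' pmiRNA profiles follow a project block plan. Desk-scale defaults: a 200 kb
#' host genome, 3 plant genomes of 50 kb with 20 miRNAs each, 5 experiments
#' over 3 projects, 20 000 reads per experiment.
#'
#' @param seed master integer seed; every stage derives its own substream
#'   from it, so equal seeds give byte-identical corpora.
#' @param host_genome_len,host_tx_count,host_tx_len,extrachromosomal_len
#'   host reference sizes (bp).
#' @param n_plant_species,plant_genome_len,mirnas_per_species,mirna_len plant
#'   reference sizes.
#' @param n_experiments,n_projects,reads_per_experiment study design.
#' @param experiment_to_project optional named character vector; default
#'   splits experiments into contiguous near-equal project blocks.
#' @param class_fractions named fractions over
#'   host / plant_mirna / human_rrna_decoy / random (sum to 1).
#' @param mutation_rate per-base substitution probability applied to degraded
#'   plant-read copies.
#' @param degraded_fraction fraction of plant reads that are degraded copies.
#' @param trim_probs probabilities of trimming 0/1/2 nt from the 3' end of a
#'   spiked read (isomiR-like length heterogeneity).
#' @param paralog_fraction fraction of plant miRNAs given a >=95\%-similar
#'   human paralog (exercises the competitive rule).
#' @param n_extra_plant_db,n_human_mirnas,n_other_mirnas database padding.
#' @param n_target_transcripts,target_transcript_len,n_terms target/enrichment
#'   universe sizes.
#' @param min_read_len,max_read_len read length window.
#' @param block_plan optional named list project -> miRNA ids to spike;
#'   default assigns each plant species to one project round-robin.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       host_genome_len = 200000L, host_tx_count = 20L,
                       host_tx_len = 1200L, extrachromosomal_len = 16000L,
                       n_plant_species = 3L, plant_genome_len = 50000L,
                       mirnas_per_species = 20L, mirna_len = 21L,
                       n_experiments = 5L, n_projects = 3L,
                       reads_per_experiment = 20000L,
                       experiment_to_project = NULL,
                       class_fractions = c(host = 0.70, plant_mirna = 0.10,
                                           human_rrna_decoy = 0.10,
                                           random = 0.10),
                       mutation_rate = 0.02, degraded_fraction = 0.15,
                       trim_probs = c(0.60, 0.25, 0.15),
                       paralog_fraction = 1 / 3,
                       n_extra_plant_db = 10L, n_human_mirnas = 30L,
                       n_other_mirnas = 30L,
                       n_target_transcripts = 30L,
                       target_transcript_len = 1000L, n_terms = 12L,
                       min_read_len = 16L, max_read_len = 35L,
                       block_plan = NULL) {
  if (!setequal(names(class_fractions), READ_CLASSES)) {
    stop("class_fractions must be named over ",
         paste(READ_CLASSES, collapse = ", "))
  }
  class_fractions <- class_fractions[READ_CLASSES]
  if (abs(sum(class_fractions) - 1) > 1e-9) {
    stop("class_fractions must sum to 1")
  }
  if (any(class_fractions < 0)) stop("class_fractions must be non-negative")
  if (mirna_len >= plant_genome_len) stop("miRNA longer than plant genome")
  if (mirna_len < min_read_len + 2L) {
    stop("mirna_len must allow 2 nt of 3' trimming above min_read_len")
  }
  if (n_projects > n_experiments) stop("more projects than experiments")
  if (abs(sum(trim_probs) - 1) > 1e-9) stop("trim_probs must sum to 1")
  experiments <- sprintf("exp%02d", seq_len(n_experiments))
  projects <- sprintf("proj%d", seq_len(n_projects))
  if (is.null(experiment_to_project)) {
    experiment_to_project <- stats::setNames(
      projects[sort(rep_len(seq_len(n_projects), n_experiments))],
      experiments)
  }
  structure(list(
    seed = as.integer(seed), host_genome_len = host_genome_len,
    host_tx_count = host_tx_count, host_tx_len = host_tx_len,
    extrachromosomal_len = extrachromosomal_len,
    n_plant_species = n_plant_species, plant_genome_len = plant_genome_len,
    mirnas_per_species = mirnas_per_species, mirna_len = mirna_len,
    n_experiments = n_experiments, n_projects = n_projects,
    reads_per_experiment = reads_per_experiment,
    experiments = experiments, projects = projects,
    experiment_to_project = experiment_to_project,
    class_fractions = class_fractions, mutation_rate = mutation_rate,
    degraded_fraction = degraded_fraction, trim_probs = trim_probs,
    paralog_fraction = paralog_fraction,
    n_extra_plant_db = n_extra_plant_db, n_human_mirnas = n_human_mirnas,
    n_other_mirnas = n_other_mirnas,
    n_target_transcripts = n_target_transcripts,
    target_transcript_len = target_transcript_len, n_terms = n_terms,
    min_read_len = min_read_len, max_read_len = max_read_len,
    block_plan = block_plan
  ), class = "sim_config")
}

#' Simulate the complete reference universe
#'
#' Generates host references, plant genomes with every miRNA embedded
#' verbatim inside an annotated feature, the four classification databases,
#' target transcripts, a transcript-to-gene map and a GMT term map. The
#' rRNA-like decoy source sequence is embedded both in a human mRNA record
#' and inside an annotated region of every plant genome, so decoy reads reach
#' the classifier and must be rejected there; selected plant miRNAs receive
#' near-identical human paralogs.
#'
#' @param config a [sim_config()].
#' @return list with `host`, `plants` (list of [plant_genome()]), `dbs`
#'   (list of four [sequence_db()]), `transcripts`, `tx2gene`, `terms`,
#'   `mirnas` (catalog data.frame), `decoy`, `positive_controls`,
#'   `block_plan`.
#' @export
simulate_references <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(stage_seed(cfg$seed, "references"), {
    host <- list(
      genome = stats::setNames(rand_seq(1, cfg$host_genome_len), "host_chr1"),
      transcriptome = stats::setNames(
        rand_seq(cfg$host_tx_count, cfg$host_tx_len),
        sprintf("host_tx%03d", seq_len(cfg$host_tx_count))),
      extrachromosomal = stats::setNames(
        rand_seq(1, cfg$extrachromosomal_len), "host_mt")
    )

    # unique miRNA catalog
    n_mir <- cfg$n_plant_species * cfg$mirnas_per_species
    repeat {
      mir_seq <- rand_seq(n_mir, cfg$mirna_len)
      if (!anyDuplicated(mir_seq)) break
    }
    mirnas <- data.frame(
      mirna_id = sprintf("sp%d-miR-%04d",
                         rep(seq_len(cfg$n_plant_species),
                             each = cfg$mirnas_per_species),
                         seq_len(n_mir)),
      species = sprintf("species%d", rep(seq_len(cfg$n_plant_species),
                                         each = cfg$mirnas_per_species)),
      sequence = mir_seq,
      stringsAsFactors = FALSE
    )
    mirnas$human_paralog <- seq_len(n_mir) %% 3L == 1L &
      stats::runif(n_mir) < 3 * cfg$paralog_fraction
    mirnas$other_paralog <- seq_len(n_mir) %% 3L == 2L

    decoy_seq <- rrna_like_sequence()

    plants <- lapply(seq_len(cfg$n_plant_species), function(s) {
      sp <- sprintf("species%d", s)
      chr <- sprintf("sp%d_chr1", s)
      g <- rand_seq(1, cfg$plant_genome_len)
      rows <- mirnas[mirnas$species == sp, , drop = FALSE]
      n_slots <- nrow(rows) + 1L  # + 1 for the embedded decoy region
      spacing <- cfg$plant_genome_len %/% (n_slots + 1L)
      if (spacing < nchar(decoy_seq) + 100L) {
        stop("plant genome too small for the configured miRNA count")
      }
      feats <- NULL
      for (i in seq_len(nrow(rows))) {
        pos <- i * spacing + sample.int(50L, 1L)  # 1-based start
        substr(g, pos, pos + cfg$mirna_len - 1L) <- rows$sequence[i]
        feats <- rbind(feats, data.frame(
          seqid = chr, source = "synthetic", feature_type = "miRNA",
          start = pos, end = pos + cfg$mirna_len - 1L, score = ".",
          strand = ifelse(i %% 2L == 0L, "-", "+"), phase = ".",
          attributes = paste0("ID=", rows$mirna_id[i], ";Name=",
                              rows$mirna_id[i]),
          stringsAsFactors = FALSE
        ))
        if (i %% 4L == 0L) {  # enclosing precursor annotation for some
          feats <- rbind(feats, data.frame(
            seqid = chr, source = "synthetic",
            feature_type = "miRNA_primary_transcript",
            start = max(1L, pos - 15L), end = pos + cfg$mirna_len + 14L,
            score = ".", strand = ifelse(i %% 2L == 0L, "-", "+"),
            phase = ".",
            attributes = paste0("ID=", rows$mirna_id[i], "-precursor"),
            stringsAsFactors = FALSE
          ))
        }
      }
      dpos <- n_slots * spacing
      substr(g, dpos, dpos + nchar(decoy_seq) - 1L) <- decoy_seq
      feats <- rbind(feats, data.frame(
        seqid = chr, source = "synthetic",
        feature_type = "miRNA_primary_transcript",
        start = dpos, end = dpos + nchar(decoy_seq) - 1L, score = ".",
        strand = "+", phase = ".",
        attributes = paste0("ID=", sp, "-ambiguous-rrna-like-region"),
        stringsAsFactors = FALSE
      ))
      # non-whitelisted annotation, dropped at GFF3 ingestion
      feats <- rbind(feats, data.frame(
        seqid = chr, source = "synthetic", feature_type = "gene",
        start = 11L, end = 210L, score = ".", strand = "+", phase = ".",
        attributes = paste0("ID=", sp, "-gene-1"), stringsAsFactors = FALSE
      ))
      plant_genome(sp, stats::setNames(g, chr), feats)
    })

    # classification databases
    plant_db <- c(stats::setNames(mirnas$sequence, mirnas$mirna_id),
                  stats::setNames(rand_seq(cfg$n_extra_plant_db,
                                           cfg$mirna_len),
                                  sprintf("spX-miR-x%03d",
                                          seq_len(cfg$n_extra_plant_db))))
    # paralog substitution near the 5' end: leaves a long exact 3' stretch so
    # trimmed read variants still share a seed-length word with the paralog
    par_pos <- max(2L, cfg$mirna_len - 15L)
    human_paralogs <- vapply(which(mirnas$human_paralog), function(i) {
      substitute_bases(mirnas$sequence[i], par_pos)
    }, character(1))
    names(human_paralogs) <- paste0("hsa-par-",
                                    mirnas$mirna_id[mirnas$human_paralog])
    human_db <- c(stats::setNames(rand_seq(cfg$n_human_mirnas, cfg$mirna_len),
                                  sprintf("hsa-miR-r%03d",
                                          seq_len(cfg$n_human_mirnas))),
                  human_paralogs)
    other_paralogs <- vapply(which(mirnas$other_paralog), function(i) {
      substitute_bases(mirnas$sequence[i], c(max(2L, par_pos - 2L), par_pos))
    }, character(1))
    names(other_paralogs) <- paste0("oth-par-",
                                    mirnas$mirna_id[mirnas$other_paralog])
    other_db <- c(stats::setNames(rand_seq(cfg$n_other_mirnas, cfg$mirna_len),
                                  sprintf("oth-miR-r%03d",
                                          seq_len(cfg$n_other_mirnas))),
                  other_paralogs)
    refseq_db <- stats::setNames(
      host$transcriptome[seq_len(min(10L, cfg$host_tx_count))],
      sprintf("NM_HOST%03d", seq_len(min(10L, cfg$host_tx_count))))
    refseq_db <- c(refseq_db, stats::setNames(
      paste0(rand_seq(1, 200), decoy_seq, rand_seq(1, 200)),
      "NR_SYNTH_RRNA"))
    if (length(human_paralogs)) {
      embedded <- vapply(human_paralogs, function(p) {
        paste0(rand_seq(1, 50), p, rand_seq(1, 50))
      }, character(1))
      names(embedded) <- sprintf("NM_PAR%03d", seq_along(embedded))
      refseq_db <- c(refseq_db, embedded)
    }
    dbs <- list(
      plant_mirbase = sequence_db("plant_mirbase", plant_db),
      human_mirbase = sequence_db("human_mirbase", human_db),
      other_mirbase = sequence_db("other_mirbase", other_db),
      human_refseq_mrna = sequence_db("human_refseq_mrna", refseq_db)
    )

    # target transcripts (separate universe from the host filter references)
    tx <- rand_seq(cfg$n_target_transcripts, cfg$target_transcript_len)
    names(tx) <- sprintf("tx%03d", seq_len(cfg$n_target_transcripts))
    pc_mirs <- mirnas[!duplicated(mirnas$species), , drop = FALSE]
    pc_mirs <- pc_mirs[seq_len(min(nrow(pc_mirs), length(tx))), ,
                       drop = FALSE]
    positive_controls <- NULL
    for (i in seq_len(nrow(pc_mirs))) {
      site <- revcomp(pc_mirs$sequence[i])
      pos <- 100L + (i - 1L) * 50L  # 1-based
      substr(tx[i], pos, pos + nchar(site) - 1L) <- site
      positive_controls <- rbind(positive_controls, data.frame(
        mirna_id = pc_mirs$mirna_id[i], sequence = pc_mirs$sequence[i],
        transcript_id = names(tx)[i], position = pos - 1L,  # 0-based
        stringsAsFactors = FALSE
      ))
    }
    tx2gene <- data.frame(
      transcript_id = names(tx),
      gene_id = sprintf("GENE%03d", seq_along(tx)),
      stringsAsFactors = FALSE
    )
    genes <- tx2gene$gene_id
    pos_genes <- tx2gene$gene_id[match(positive_controls$transcript_id,
                                       tx2gene$transcript_id)]
    sets <- list(TERM_POS = unique(c(pos_genes,
                                     sample(genes, min(3L, length(genes))))))
    for (t in seq_len(max(0L, cfg$n_terms - 1L))) {
      sets[[sprintf("TERM%03d", t)]] <-
        sample(genes, sample(5:min(15L, length(genes)), 1L))
    }
    term_names <- stats::setNames(
      c("planted positive-control gene set",
        sprintf("random gene set %d", seq_len(length(sets) - 1L))),
      names(sets))

    list(host = host, plants = plants, dbs = dbs, transcripts = tx,
         tx2gene = tx2gene, terms = list(sets = sets, names = term_names),
         mirnas = mirnas, decoy = list(sequence = decoy_seq),
         positive_controls = positive_controls,
         block_plan = resolve_block_plan(cfg, mirnas))
  })
}

resolve_block_plan <- function(cfg, mirnas) {
  if (!is.null(cfg$block_plan)) return(cfg$block_plan)
  plan <- lapply(seq_len(cfg$n_projects), function(p) {
    sp <- sprintf("species%d",
                  which((seq_len(cfg$n_plant_species) - 1L) %%
                          cfg$n_projects + 1L == p))
    ids <- mirnas$mirna_id[mirnas$species %in% sp]
    if (length(ids) == 0L) ids <- mirnas$mirna_id
    ids
  })
  stats::setNames(plan, cfg$projects)
}

#' Simulate reads for every experiment
#'
#' Draws reads per the configured class fractions: host reads are exact
#' substrings of the host references (either strand), plant reads are spiked
#' copies of the project's block of miRNAs (with isomiR-like 3' trimming and
#' occasional degraded copies carrying substitutions), decoy reads are exact
#' substrings of the rRNA-like source, and random reads are uniform
#' sequences. Every read is labelled in the ground-truth manifest.
#'
#' @param config a [sim_config()].
#' @param refs result of [simulate_references()].
#' @return list with `reads` (data.frame `read_id`, `sequence`, `quality`,
#'   `experiment_id`), `manifest` (adds `class`, `species`, `mirna_id`,
#'   `mutations`, `trim`), and `library_sizes` (named integer).
#' @export
simulate_reads <- function(config, refs) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  plan <- refs$block_plan
  mir_lookup <- stats::setNames(refs$mirnas$sequence, refs$mirnas$mirna_id)
  mir_species <- stats::setNames(refs$mirnas$species, refs$mirnas$mirna_id)
  host_seqs <- c(refs$host$genome, refs$host$transcriptome,
                 refs$host$extrachromosomal)
  decoy <- refs$decoy$sequence

  per_exp <- lapply(cfg$experiments, function(e) {
    with_seed(stage_seed(cfg$seed, paste0("reads_", e)), {
      n <- cfg$reads_per_experiment
      counts <- apportion(n, cfg$class_fractions)
      names(counts) <- READ_CLASSES
      project <- cfg$experiment_to_project[[e]]
      block <- plan[[project]]

      seqs <- character(0)
      cls <- character(0)
      mid <- character(0)
      mmut <- integer(0)
      mtrim <- integer(0)

      if (counts[["host"]] > 0L) {
        k <- counts[["host"]]
        si <- sample(seq_along(host_seqs), k, replace = TRUE,
                     prob = nchar(host_seqs))
        len <- sample(cfg$min_read_len:cfg$max_read_len, k, replace = TRUE)
        len <- pmin(len, nchar(host_seqs)[si])
        start <- vapply(seq_len(k), function(i) {
          sample.int(nchar(host_seqs)[si[i]] - len[i] + 1L, 1L)
        }, integer(1))
        s <- substring(host_seqs[si], start, start + len - 1L)
        flip <- stats::runif(k) < 0.5
        s[flip] <- revcomp(s[flip])
        seqs <- c(seqs, unname(s))
        cls <- c(cls, rep("host", k))
        mid <- c(mid, rep(NA_character_, k))
        mmut <- c(mmut, rep(0L, k))
        mtrim <- c(mtrim, rep(0L, k))
      }
      if (counts[["plant_mirna"]] > 0L) {
        k <- counts[["plant_mirna"]]
        ids <- sample(block, k, replace = TRUE)
        trims <- sample(0:2, k, replace = TRUE, prob = cfg$trim_probs)
        s <- substr(mir_lookup[ids], 1L, cfg$mirna_len - trims)
        degraded <- stats::runif(k) < cfg$degraded_fraction
        muts <- integer(k)
        for (i in which(degraded)) {
          pos <- which(stats::runif(nchar(s[i])) < cfg$mutation_rate)
          if (length(pos)) {
            s[i] <- substitute_bases(s[i], pos)
            muts[i] <- length(pos)
          }
        }
        seqs <- c(seqs, unname(s))
        cls <- c(cls, rep("plant_mirna", k))
        mid <- c(mid, ids)
        mmut <- c(mmut, muts)
        mtrim <- c(mtrim, trims)
      }
      if (counts[["human_rrna_decoy"]] > 0L) {
        k <- counts[["human_rrna_decoy"]]
        len <- sample(18:24, k, replace = TRUE)
        start <- vapply(len, function(L) {
          sample.int(nchar(decoy) - L + 1L, 1L)
        }, integer(1))
        s <- substring(decoy, start, start + len - 1L)
        seqs <- c(seqs, unname(s))
        cls <- c(cls, rep("human_rrna_decoy", k))
        mid <- c(mid, rep(NA_character_, k))
        mmut <- c(mmut, rep(0L, k))
        mtrim <- c(mtrim, rep(0L, k))
      }
      if (counts[["random"]] > 0L) {
        k <- counts[["random"]]
        s <- rand_seq(k, sample(cfg$min_read_len:cfg$max_read_len, k,
                                replace = TRUE))
        seqs <- c(seqs, s)
        cls <- c(cls, rep("random", k))
        mid <- c(mid, rep(NA_character_, k))
        mmut <- c(mmut, rep(0L, k))
        mtrim <- c(mtrim, rep(0L, k))
      }

      ids <- sprintf("%s_r%06d", e, seq_along(seqs))
      list(
        reads = data.frame(read_id = ids, sequence = seqs,
                           quality = strrep("I", nchar(seqs)),
                           experiment_id = rep(e, length(ids)),
                           stringsAsFactors = FALSE),
        manifest = data.frame(
          read_id = ids, experiment_id = rep(e, length(ids)), class = cls,
          species = ifelse(is.na(mid), NA_character_,
                           unname(mir_species[mid])),
          mirna_id = mid, mutations = mmut, trim = mtrim,
          stringsAsFactors = FALSE)
      )
    })
  })
  reads <- do.call(rbind, lapply(per_exp, `[[`, "reads"))
  manifest <- do.call(rbind, lapply(per_exp, `[[`, "manifest"))
  if (is.null(reads)) {
    reads <- data.frame(read_id = character(), sequence = character(),
                        quality = character(), experiment_id = character(),
                        stringsAsFactors = FALSE)
    manifest <- data.frame(read_id = character(), experiment_id = character(),
                           class = character(), species = character(),
                           mirna_id = character(), mutations = integer(),
                           trim = integer(), stringsAsFactors = FALSE)
  }
  library_sizes <- stats::setNames(
    vapply(cfg$experiments, function(e) {
      sum(manifest$experiment_id == e)
    }, numeric(1)),
    cfg$experiments)
  list(reads = reads, manifest = manifest, library_sizes = library_sizes)
}

#' Simulate a planted-block abundance matrix
#'
#' Generates a sequences x experiments matrix with block structure: each
#' experiment block expresses its own block of sequences (log-normal
#' abundance), plus uniform contamination noise -- with probability `noise`
#' any cell is replaced by a random abundance draw. Used for clustering
#' recovery checks with known labels.
#'
#' @param n_blocks number of planted groups.
#' @param experiments_per_block,sequences_per_block block sizes.
#' @param noise per-cell probability of replacement by a random draw.
#' @param seed RNG seed.
#' @return list with `matrix`, `experiment_blocks` (integer labels) and
#'   `sequence_blocks`.
#' @export
simulate_block_matrix <- function(n_blocks = 3L, experiments_per_block = 4L,
                                  sequences_per_block = 10L, noise = 0.1,
                                  seed = 1L) {
  with_seed(seed, {
    ne <- n_blocks * experiments_per_block
    ns <- n_blocks * sequences_per_block
    eb <- rep(seq_len(n_blocks), each = experiments_per_block)
    sb <- rep(seq_len(n_blocks), each = sequences_per_block)
    m <- matrix(0, nrow = ns, ncol = ne,
                dimnames = list(sprintf("seq%03d", seq_len(ns)),
                                sprintf("exp%02d", seq_len(ne))))
    for (b in seq_len(n_blocks)) {
      rows <- which(sb == b)
      cols <- which(eb == b)
      m[rows, cols] <- stats::rlnorm(length(rows) * length(cols),
                                     meanlog = 1, sdlog = 0.5)
    }
    flip <- matrix(stats::runif(ns * ne) < noise, nrow = ns)
    m[flip] <- stats::rlnorm(sum(flip), meanlog = 1, sdlog = 0.5)
    list(matrix = m, experiment_blocks = eb, sequence_blocks = sb)
  })
}

#' Write a simulated corpus to disk
#'
#' Persists everything the pipeline reads: per-experiment FASTQ, host and
#' plant FASTA, GFF3 annotations, the four database FASTAs, target
#' transcripts, transcript-to-gene TSV, GMT terms, experiment manifest,
#' ground-truth manifest, library sizes, and a ready-to-run pipeline
#' `config.yaml`.
#'
#' @param refs [simulate_references()] result.
#' @param reads [simulate_reads()] result.
#' @param config the [sim_config()] used.
#' @param dir output directory (created).
#' @return invisibly, the pipeline config list (with absolute paths).
#' @export
write_corpus <- function(refs, reads, config, dir) {
  for (d in c("", "reads", "host", "plants", "dbs", "targets")) {
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  fastq_paths <- character(0)
  for (e in config$experiments) {
    p <- file.path(dir, "reads", paste0(e, ".fastq"))
    write_fastq(reads$reads[reads$reads$experiment_id == e, , drop = FALSE],
                p)
    fastq_paths <- c(fastq_paths, p)
  }
  write_fasta(refs$host$genome, file.path(dir, "host", "genome.fa"))
  write_fasta(refs$host$transcriptome,
              file.path(dir, "host", "transcriptome.fa"))
  write_fasta(refs$host$extrachromosomal,
              file.path(dir, "host", "extrachromosomal.fa"))
  plant_entries <- lapply(refs$plants, function(p) {
    fa <- file.path(dir, "plants", paste0(p$species_name, ".fa"))
    gff <- file.path(dir, "plants", paste0(p$species_name, ".gff3"))
    write_fasta(p$genome, fa)
    write_gff3(p$features, gff)
    list(species = p$species_name, fasta = fa, gff3 = gff)
  })
  db_paths <- lapply(refs$dbs, function(d) {
    p <- file.path(dir, "dbs", paste0(d$db_name, ".fa"))
    write_fasta(d$sequences, p)
    p
  })
  write_fasta(refs$transcripts, file.path(dir, "targets", "transcripts.fa"))
  write_tsv(refs$tx2gene, file.path(dir, "targets", "tx2gene.tsv"))
  write_gmt(refs$terms$sets, file.path(dir, "targets", "terms.gmt"),
            refs$terms$names)
  write_tsv(data.frame(experiment_id = names(config$experiment_to_project),
                       project_id = unname(config$experiment_to_project),
                       stringsAsFactors = FALSE),
            file.path(dir, "manifest.tsv"))
  write_tsv(reads$manifest, file.path(dir, "ground_truth.tsv"))
  write_tsv(data.frame(experiment_id = names(reads$library_sizes),
                       library_size = unname(reads$library_sizes),
                       stringsAsFactors = FALSE),
            file.path(dir, "library_sizes.tsv"))

  pcfg <- list(
    inputs = list(
      fastq = as.list(fastq_paths),
      manifest = file.path(dir, "manifest.tsv"),
      host = list(genome = file.path(dir, "host", "genome.fa"),
                  transcriptome = file.path(dir, "host", "transcriptome.fa"),
                  extrachromosomal = file.path(dir, "host",
                                               "extrachromosomal.fa")),
      plants = plant_entries,
      dbs = db_paths,
      transcripts = file.path(dir, "targets", "transcripts.fa"),
      tx2gene = file.path(dir, "targets", "tx2gene.tsv"),
      terms = file.path(dir, "targets", "terms.gmt")
    ),
    params = default_params()
  )
  yaml::write_yaml(pcfg, file.path(dir, "config.yaml"))
  invisible(pcfg)
}

#' Simulate and persist a complete corpus
#'
#' @param config a [sim_config()].
#' @param dir output directory.
#' @return invisibly, a list with `refs`, `reads` and the pipeline `config`.
#' @export
simulate_corpus <- function(config, dir) {
  refs <- simulate_references(config)
  reads <- simulate_reads(config, refs)
  pcfg <- write_corpus(refs, reads, config, dir)
  invisible(list(refs = refs, reads = reads, config = pcfg))
}
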