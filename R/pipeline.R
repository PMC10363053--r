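#' Default pipeline parameters
#'
#' One flat list of every tunable, echoed (resolved) with each run for
#' reproducibility.
#'
#' @return named list of parameter defaults.
#' @export
default_params <- function() {
  list(
    min_read_len = 16L, max_read_len = 35L, drop_n = TRUE,
    max_mismatches = 1L,
    match = 2L, mismatch = -3L, gap_open = 5L, gap_extend = 2L,
    lambda = 0.625, K = 0.41,
    word_size_db = 11L, word_size_genome = 16L,
    min_identity = 1.0, min_coverage = 1.0, min_overlap_frac = 0.9,
    feature_types = c("miRNA", "miRNA_primary_transcript", "pre-miRNA"),
    mismatch_penalty = 1.0, gu_wobble_penalty = 0.5, gap_penalty = 2.0,
    seed_start = 2L, seed_end = 13L, seed_multiplier = 2.0,
    expectation_cutoff = 5.0,
    cluster_distance = "euclidean", cluster_linkage = "average",
    cluster_transform = "log1p",
    n_experiment_groups = 5L, n_sequence_groups = 4L,
    consensus_kmin = 10L, consensus_kmax = 12L,
    consensus_min_fraction = 0.9
  )
}

#' Load a pipeline configuration from YAML
#'
#' Missing parameters are filled from [default_params()].
#'
#' @param path YAML file with `inputs` and optional `params` sections.
#' @return config list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$inputs)) stop("config must have an 'inputs' section")
  params <- default_params()
  for (nm in names(cfg$params)) params[[nm]] <- cfg$params[[nm]]
  cfg$params <- params
  cfg
}

config_scheme <- function(p) {
  scoring_scheme(p$match, p$mismatch, p$gap_open, p$gap_extend, p$lambda, p$K)
}

config_schema <- function(p) {
  target_schema(p$mismatch_penalty, p$gu_wobble_penalty, p$gap_penalty,
                p$seed_start, p$seed_end, p$seed_multiplier,
                p$expectation_cutoff)
}

read_fasta_or_empty <- function(path) {
  if (is.null(path) || !nzchar(path) || !file.exists(path)) {
    return(character(0))
  }
  read_fasta(path)
}

stage_path <- function(out_dir, name) file.path(out_dir, name)

require_stage_output <- function(out_dir, name, producer) {
  p <- stage_path(out_dir, name)
  if (!file.exists(p)) {
    stop("missing upstream output '", name, "': run stage '", producer,
         "' first")
  }
  p
}

#' Pipeline stage: ingest and collapse reads
#'
#' Reads every FASTQ, applies the ingestion filters, collapses to unique
#' sequences and records per-experiment library sizes (the RPM denominator:
#' post-ingestion, pre-host-filter).
#'
#' @param config pipeline config list (see [read_pipeline_config()]).
#' @param out_dir run directory.
#' @return invisibly, the ingest counts.
#' @export
stage_ingest <- function(config, out_dir) {
  p <- config$params
  reads <- lapply(unlist(config$inputs$fastq), function(f) {
    read_fastq(f, min_len = p$min_read_len, max_len = p$max_read_len,
               drop_n = p$drop_n)
  })
  collapsed <- collapse_reads(reads)
  lib <- vapply(reads, nrow, numeric(1))
  names(lib) <- vapply(reads, function(r) {
    if (nrow(r)) r$experiment_id[1] else NA_character_
  }, character(1))
  # experiments whose FASTQ was empty keep their file-derived name
  empty <- is.na(names(lib))
  names(lib)[empty] <- sub("\\.(fastq|fq)$", "",
                           basename(unlist(config$inputs$fastq)))[empty]
  write_tsv(collapsed_to_df(collapsed), stage_path(out_dir, "collapsed.tsv"))
  write_tsv(data.frame(experiment_id = names(lib), library_size = unname(lib),
                       stringsAsFactors = FALSE),
            stage_path(out_dir, "library_sizes.tsv"))
  invisible(list(n_reads = sum(lib), n_unique = length(collapsed$sequence)))
}

#' Pipeline stage: host subtraction
#'
#' @inheritParams stage_ingest
#' @return invisibly, the host filter report.
#' @export
stage_host_filter <- function(config, out_dir) {
  p <- config$params
  collapsed <- df_to_collapsed(
    read_tsv(require_stage_output(out_dir, "collapsed.tsv", "ingest")))
  host <- host_reference_set(
    genome = read_fasta_or_empty(config$inputs$host$genome),
    transcriptome = read_fasta_or_empty(config$inputs$host$transcriptome),
    extrachromosomal =
      read_fasta_or_empty(config$inputs$host$extrachromosomal))
  res <- filter_host(collapsed, host, p$max_mismatches)
  write_tsv(collapsed_to_df(res$retained), stage_path(out_dir, "retained.tsv"))
  write_tsv(res$removed, stage_path(out_dir, "removal_log.tsv"))
  write_json_file(res$report, stage_path(out_dir, "host_report.json"))
  invisible(res$report)
}

#' Pipeline stage: plant genome mapping and annotation intersection
#'
#' @inheritParams stage_ingest
#' @return invisibly, the per-species summary data.frame.
#' @export
stage_map_plants <- function(config, out_dir) {
  p <- config$params
  retained <- df_to_collapsed(
    read_tsv(require_stage_output(out_dir, "retained.tsv", "filter-host")))
  genomes <- lapply(config$inputs$plants, function(pl) {
    plant_genome(pl$species, read_fasta(pl$fasta),
                 read_gff3(pl$gff3, types = p$feature_types))
  })
  results <- map_to_plant_genomes(retained, genomes, config_scheme(p),
                                  p$min_identity, p$min_coverage,
                                  p$word_size_genome)
  summary_df <- species_summary(results)
  write_tsv(summary_df, stage_path(out_dir, "species_summary.tsv"))
  all_aln <- do.call(rbind, lapply(seq_along(results), function(i) {
    a <- results[[i]]$alignments
    if (nrow(a)) a$species <- results[[i]]$species_name else
      a$species <- character(0)
    a
  }))
  write_tsv(all_aln, stage_path(out_dir, "alignments.tsv"))
  inter <- do.call(rbind, lapply(seq_along(results), function(i) {
    a <- intersect_mirna_annotations(results[[i]]$alignments,
                                     genomes[[i]]$features,
                                     p$min_overlap_frac)
    if (nrow(a)) a$species <- results[[i]]$species_name else
      a$species <- character(0)
    a
  }))
  write_tsv(inter, stage_path(out_dir, "intersected.tsv"))
  invisible(summary_df)
}

#' Pipeline stage: four-database competitive classification
#'
#' Classifies every sequence surviving the annotation intersection and stores
#' the KDE overlap diagnostic (plant vs human-mRNA bit-score densities before
#' and after filtering).
#'
#' @inheritParams stage_ingest
#' @return invisibly, the classification data.frame.
#' @export
stage_classify <- function(config, out_dir) {
  p <- config$params
  inter <- read_tsv(require_stage_output(out_dir, "intersected.tsv",
                                         "map-plants"))
  seqs <- unique(inter$sequence)
  dbs <- lapply(DB_NAMES, function(nm) {
    sequence_db(nm, read_fasta(config$inputs$dbs[[nm]]))
  })
  if (length(seqs)) {
    records <- classify_sequences(seqs, dbs, config_scheme(p), p$word_size_db)
  } else {
    records <- classify_sequences(character(0), dbs, config_scheme(p),
                                  p$word_size_db)
  }
  write_tsv(records, stage_path(out_dir, "classification.tsv"))
  validated <- records[records$verdict == "validated_pmiRNA", , drop = FALSE]
  diag <- list(overlap_prefilter = bitscore_overlap(records),
               overlap_postfilter = bitscore_overlap(validated))
  write_json_file(diag, stage_path(out_dir, "kde_diagnostics.json"))
  invisible(records)
}

#' Pipeline stage: RPM quantification
#'
#' @inheritParams stage_ingest
#' @return invisibly, the `expression_matrix` (or NULL when nothing was
#'   validated).
#' @export
stage_quantify <- function(config, out_dir) {
  records <- read_tsv(require_stage_output(out_dir, "classification.tsv",
                                           "classify"))
  retained <- df_to_collapsed(
    read_tsv(require_stage_output(out_dir, "retained.tsv", "filter-host")))
  lib_df <- read_tsv(require_stage_output(out_dir, "library_sizes.tsv",
                                          "ingest"))
  lib <- stats::setNames(lib_df$library_size, lib_df$experiment_id)
  n_validated <- sum(records$verdict == "validated_pmiRNA")
  if (n_validated == 0L || any(lib <= 0)) {
    write_tsv(data.frame(sequence = character(), stringsAsFactors = FALSE),
              stage_path(out_dir, "rpm_matrix.tsv"))
    write_json_file(list(n_sequences = 0), stage_path(out_dir,
                                                      "rpm_summary.json"))
    return(invisible(NULL))
  }
  em <- build_matrix(records, retained, lib)
  write_tsv(cbind(data.frame(sequence = rownames(em$rpm),
                             stringsAsFactors = FALSE),
                  as.data.frame(em$rpm, optional = TRUE)),
            stage_path(out_dir, "rpm_matrix.tsv"))
  s <- summarize_rpm(em)
  write_json_file(list(n_sequences = s$n_sequences, mean = s$mean,
                       median = s$median, min = s$min, max = s$max),
                  stage_path(out_dir, "rpm_summary.json"))
  invisible(em)
}

#' Pipeline stage: plant-style target prediction
#'
#' @inheritParams stage_ingest
#' @return invisibly, the targets data.frame (NULL when no transcript FASTA
#'   is configured).
#' @export
stage_targets <- function(config, out_dir) {
  if (is.null(config$inputs$transcripts)) return(invisible(NULL))
  p <- config$params
  records <- read_tsv(require_stage_output(out_dir, "classification.tsv",
                                           "classify"))
  validated <- unique(records$sequence[records$verdict == "validated_pmiRNA"])
  tx <- read_fasta(config$inputs$transcripts)
  schema <- config_schema(p)
  out <- do.call(rbind, lapply(validated, predict_targets, transcripts = tx,
                               schema = schema))
  if (is.null(out)) {
    out <- data.frame(mirna_sequence = character(),
                      transcript_id = character(), position = integer(),
                      expectation = numeric(), stringsAsFactors = FALSE)
  }
  write_tsv(out, stage_path(out_dir, "targets.tsv"))
  invisible(out)
}

#' Pipeline stage: over-representation enrichment
#'
#' @inheritParams stage_ingest
#' @return invisibly, the enrichment data.frame (NULL when inputs are not
#'   configured).
#' @export
stage_enrich <- function(config, out_dir) {
  if (is.null(config$inputs$tx2gene) || is.null(config$inputs$terms)) {
    return(invisible(NULL))
  }
  targets <- read_tsv(require_stage_output(out_dir, "targets.tsv", "targets"))
  tx2gene <- read_tsv(config$inputs$tx2gene)
  gmt <- read_gmt(config$inputs$terms)
  universe <- unique(tx2gene$gene_id)
  query <- unique(tx2gene$gene_id[match(unique(targets$transcript_id),
                                        tx2gene$transcript_id)])
  query <- query[!is.na(query)]
  if (length(query) == 0L) {
    res <- data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_value = numeric(),
                      adjusted_p = numeric(),
                      neg_log10_adjusted_p = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    res <- hypergeom_enrich(query, gmt$sets, universe, gmt$names)
  }
  write_tsv(res, stage_path(out_dir, "enrichment.tsv"))
  invisible(res)
}

#' Pipeline stage: clustering, project distribution and consensus search
#'
#' @inheritParams stage_ingest
#' @return invisibly, the `cluster_grouping` (NULL when the matrix is too
#'   small to cluster both axes).
#' @export
stage_cluster <- function(config, out_dir) {
  p <- config$params
  mat_df <- read_tsv(require_stage_output(out_dir, "rpm_matrix.tsv",
                                          "quantify"))
  records <- read_tsv(require_stage_output(out_dir, "classification.tsv",
                                           "classify"))
  validated <- unique(records$sequence[records$verdict == "validated_pmiRNA"])
  if (length(validated)) {
    cons <- consensus_search(validated, p$consensus_kmin,
                             min(p$consensus_kmax, min(nchar(validated))),
                             p$consensus_min_fraction)
  } else {
    cons <- data.frame(kmer = character(), k = integer(),
                       fraction = numeric(), stringsAsFactors = FALSE)
  }
  write_tsv(cons, stage_path(out_dir, "consensus.tsv"))

  if (nrow(mat_df) < 2L || ncol(mat_df) < 3L) return(invisible(NULL))
  mat <- as.matrix(mat_df[, -1, drop = FALSE])
  rownames(mat) <- mat_df$sequence
  scaffold <- hierarchical_cluster(mat, distance = p$cluster_distance,
                                   linkage = p$cluster_linkage,
                                   transform = p$cluster_transform)
  grouping <- cut_groups(scaffold,
                         min(p$n_experiment_groups, ncol(mat)),
                         min(p$n_sequence_groups, nrow(mat)))
  groups_df <- function(groups, item_col) {
    do.call(rbind, lapply(names(groups), function(g) {
      stats::setNames(data.frame(g, groups[[g]], stringsAsFactors = FALSE),
                      c("group", item_col))
    }))
  }
  write_tsv(groups_df(grouping$experiment_groups, "experiment_id"),
            stage_path(out_dir, "experiment_groups.tsv"))
  write_tsv(groups_df(grouping$sequence_groups, "sequence"),
            stage_path(out_dir, "sequence_groups.tsv"))
  linkage_df <- function(hc) {
    if (is.null(hc)) return(data.frame())
    data.frame(merge1 = hc$merge[, 1], merge2 = hc$merge[, 2],
               height = hc$height)
  }
  write_tsv(linkage_df(scaffold$experiment_hclust),
            stage_path(out_dir, "linkage_experiments.tsv"))
  write_tsv(linkage_df(scaffold$sequence_hclust),
            stage_path(out_dir, "linkage_sequences.tsv"))
  if (!is.null(config$inputs$manifest)) {
    e2p <- read_exp_manifest(config$inputs$manifest)
    write_tsv(project_distribution(grouping$experiment_groups, e2p),
              stage_path(out_dir, "project_distribution.tsv"))
  }
  invisible(grouping)
}

#' Pipeline stage: aggregate the run report
#'
#' Collects per-stage counts into one mutually consistent report
#' (`report.json`). Stage timings are logged to the console only, so repeated
#' runs of the same configuration produce byte-identical outputs.
#'
#' @inheritParams stage_ingest
#' @return the report list (class `run_report`).
#' @export
stage_report <- function(config, out_dir) {
  lib <- read_tsv(require_stage_output(out_dir, "library_sizes.tsv",
                                       "ingest"))
  host <- jsonlite::read_json(require_stage_output(out_dir,
                                                   "host_report.json",
                                                   "filter-host"))
  species <- read_tsv(require_stage_output(out_dir, "species_summary.tsv",
                                           "map-plants"))
  inter <- read_tsv(require_stage_output(out_dir, "intersected.tsv",
                                         "map-plants"))
  records <- read_tsv(require_stage_output(out_dir, "classification.tsv",
                                           "classify"))
  rpm_summary <- jsonlite::read_json(
    require_stage_output(out_dir, "rpm_summary.json", "quantify"))
  kdiag <- jsonlite::read_json(stage_path(out_dir, "kde_diagnostics.json"))
  verdicts <- if (nrow(records)) table(records$verdict) else table(character())
  report <- list(
    library_sizes = stats::setNames(as.list(lib$library_size),
                                    lib$experiment_id),
    n_reads_ingested = sum(lib$library_size),
    host_filter = host,
    species_summary = stats::setNames(as.list(species$aligned_reads),
                                      species$species),
    n_sequences_annotated = length(unique(inter$sequence)),
    n_sequences_classified = nrow(records),
    verdict_counts = as.list(verdicts),
    n_validated = sum(records$verdict == "validated_pmiRNA"),
    rpm_summary = rpm_summary,
    kde_diagnostics = kdiag
  )
  write_json_file(report, stage_path(out_dir, "report.json"))
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("pmirscan run report\n")
  cat("  reads ingested:      ", x$n_reads_ingested, "\n")
  cat("  host-removed reads:  ",
      x$host_filter$n_input - x$host_filter$n_retained, "\n")
  cat("  sequences classified:", x$n_sequences_classified, "\n")
  cat("  validated pmiRNAs:   ", x$n_validated, "\n")
  if (!is.null(x$rpm_summary$mean)) {
    cat(sprintf("  RPM mean/median:      %.4g / %.4g\n", x$rpm_summary$mean,
                x$rpm_summary$median))
  }
  invisible(x)
}

PIPELINE_STAGES <- c("ingest", "filter-host", "map-plants", "classify",
                     "quantify", "targets", "enrich", "cluster", "report")

stage_fun <- function(stage) {
  switch(stage,
         "ingest" = stage_ingest,
         "filter-host" = stage_host_filter,
         "map-plants" = stage_map_plants,
         "classify" = stage_classify,
         "quantify" = stage_quantify,
         "targets" = stage_targets,
         "enrich" = stage_enrich,
         "cluster" = stage_cluster,
         "report" = stage_report,
         stop("unknown stage: ", stage))
}

#' Run the complete detection pipeline
#'
#' Executes ingest, host subtraction, plant mapping, annotation intersection,
#' classification, quantification, target prediction, enrichment, clustering
#' and consensus search, persisting every intermediate under `out_dir`. The
#' resolved configuration is echoed to `config_resolved.yaml`. A stage
#' failure halts the run, names the stage, and leaves a `FAILED` marker next
#' to the partial outputs. Reruns with identical config and inputs are
#' byte-identical.
#'
#' @param config config list (from [read_pipeline_config()] or
#'   [simulate_corpus()]).
#' @param out_dir output directory (created).
#' @param quiet suppress per-stage progress messages.
#' @return the run report (class `run_report`), invisibly.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(config$params)) config$params <- default_params()
  yaml::write_yaml(config, file.path(out_dir, "config_resolved.yaml"))
  report <- NULL
  for (stage in PIPELINE_STAGES) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(stage_fun(stage)(config, out_dir), error = function(e) {
      writeLines(paste0("failed at stage: ", stage),
                 file.path(out_dir, "FAILED"))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    if (!quiet) {
      message(sprintf("[pmirscan] stage %-12s done in %.1fs", stage,
                      proc.time()[["elapsed"]] - t0))
    }
    if (stage == "report") report <- res
  }
  invisible(report)
}
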