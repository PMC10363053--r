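#' Plant genome with miRNA annotations
#'
#' @param species_name species label.
#' @param genome named character vector of chromosome/scaffold sequences.
#' @param features data.frame of annotated features (as from [read_gff3()]),
#'   1-based inclusive coordinates.
#' @return object of class `plant_genome` with `genome_size_bp` precomputed.
#' @export
plant_genome <- function(species_name, genome, features) {
  if (length(genome) == 0L || sum(nchar(genome)) == 0L) {
    stop("empty genome for species ", species_name)
  }
  if (nrow(features) > 0L && !all(features$seqid %in% names(genome))) {
    stop("features reference unknown seqids for species ", species_name)
  }
  structure(list(species_name = species_name, genome = toupper(genome),
                 features = features,
                 genome_size_bp = sum(nchar(genome))),
            class = "plant_genome")
}

#' Normalize an aligned-read count by genome size
#'
#' Reads per megabase: `count / (genome_size_bp / 1e6)`. Used to check that
#' per-species alignment counts are not merely proportional to genome size.
#'
#' @param aligned_read_count non-negative count.
#' @param genome_size_bp positive genome size in bp.
#' @return numeric reads per Mb.
#' @export
normalize_by_genome_size <- function(aligned_read_count, genome_size_bp) {
  if (any(genome_size_bp <= 0)) stop("genome_size_bp must be positive")
  aligned_read_count / (genome_size_bp / 1e6)
}

#' Map reads to plant genomes
#'
#' Per species, counts the distinct read sequences with at least one
#' qualifying alignment (a read may count in several species; multi-mapping
#' within one species counts once), and keeps all qualifying alignments for
#' the annotation-intersection step. Defaults require the full read at 100\%
#' identity: mature miRNAs are genome-encoded verbatim.
#'
#' @param reads a `collapsed_reads` object or character vector of sequences.
#' @param genomes list of [plant_genome()] objects.
#' @param scheme a [scoring_scheme()].
#' @param min_identity minimum alignment identity (default 1.0).
#' @param min_coverage minimum fraction of the read aligned (default 1.0).
#' @param word_size seed length for genome search (default 16).
#' @return list of per-species results: `species_name`, `aligned_read_count`,
#'   `genome_size_bp`, `normalized_count`, `alignments` (data.frame with
#'   0-based half-open subject spans).
#' @export
map_to_plant_genomes <- function(reads, genomes, scheme = scoring_scheme(),
                                 min_identity = 1.0, min_coverage = 1.0,
                                 word_size = 16L) {
  seqs <- if (inherits(reads, "collapsed_reads")) reads$sequence else reads
  lapply(genomes, function(g) {
    stopifnot(inherits(g, "plant_genome"))
    idx <- seq_index(g$genome, word_size)
    hits <- if (length(seqs)) {
      index_hits(seqs, idx, scheme, best_only = FALSE)
    } else {
      index_hits(character(), idx, scheme)
    }
    qual <- hits[hits$identity >= min_identity &
                   hits$coverage >= min_coverage, , drop = FALSE]
    alignments <- data.frame(
      sequence = qual$query_seq, seqid = qual$subject_id,
      strand = qual$strand, sstart = qual$sstart, send = qual$send,
      identity = qual$identity, coverage = qual$coverage,
      score = qual$score, bitscore = qual$bitscore,
      stringsAsFactors = FALSE
    )
    n_aligned <- length(unique(alignments$sequence))
    list(species_name = g$species_name,
         aligned_read_count = n_aligned,
         genome_size_bp = g$genome_size_bp,
         normalized_count = normalize_by_genome_size(n_aligned,
                                                     g$genome_size_bp),
         alignments = alignments)
  })
}

#' Keep alignments overlapping annotated miRNA features
#'
#' An alignment survives when its subject interval overlaps a whitelisted
#' feature on the same seqid by at least `min_overlap_frac` of the aligned
#' length. Overlap is strand-agnostic: a mature miRNA may derive from either
#' arm of the precursor.
#'
#' @param alignments alignment data.frame from [map_to_plant_genomes()]
#'   (0-based half-open `sstart`/`send`).
#' @param features feature data.frame (1-based inclusive `start`/`end`),
#'   already restricted to whitelisted types by [read_gff3()].
#' @param min_overlap_frac minimum overlap as a fraction of the aligned
#'   subject length (default 0.9).
#' @return the filtered alignment data.frame.
#' @export
intersect_mirna_annotations <- function(alignments, features,
                                        min_overlap_frac = 0.9) {
  if (nrow(alignments) == 0L || nrow(features) == 0L) {
    return(alignments[integer(), , drop = FALSE])
  }
  aln_gr <- GenomicRanges::GRanges(
    seqnames = alignments$seqid,
    ranges = IRanges::IRanges(start = alignments$sstart + 1L,
                              end = alignments$send)
  )
  feat_gr <- GenomicRanges::GRanges(
    seqnames = features$seqid,
    ranges = IRanges::IRanges(start = features$start, end = features$end)
  )
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(aln_gr, feat_gr, ignore.strand = TRUE))
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  ov_width <- pmin(alignments$send[qh], features$end[sh]) -
    pmax(alignments$sstart[qh] + 1L, features$start[sh]) + 1L
  aln_len <- alignments$send[qh] - alignments$sstart[qh]
  keep <- unique(qh[ov_width >= min_overlap_frac * aln_len])
  alignments[sort(keep), , drop = FALSE]
}

#' Per-species mapping summary table
#'
#' @param results list from [map_to_plant_genomes()].
#' @return data.frame with species, aligned_reads, genome_size_bp and
#'   reads_per_Mb columns (the bar-plot analogue of the mapping figures).
#' @export
species_summary <- function(results) {
  data.frame(
    species = vapply(results, `[[`, character(1), "species_name"),
    aligned_reads = vapply(results, `[[`, numeric(1), "aligned_read_count"),
    genome_size_bp = vapply(results, `[[`, numeric(1), "genome_size_bp"),
    reads_per_Mb = vapply(results, `[[`, numeric(1), "normalized_count"),
    stringsAsFactors = FALSE
  )
}
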