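#' Read a 4-line FASTQ file of small RNA reads
#'
#' Sequences are uppercased and U is converted to T at ingestion. Reads
#' containing N and reads outside the configured length window are dropped
#' (they cannot be classified unambiguously at 100\% identity); the numbers
#' removed are recorded in attributes.
#'
#' @param path FASTQ file (uncompressed, 4 lines per record).
#' @param experiment_id experiment label attached to every read; defaults to
#'   the file name without extension.
#' @param min_len,max_len inclusive read-length window kept after ingestion.
#' @param drop_n drop reads containing N (default TRUE).
#' @return data.frame with columns `read_id`, `sequence`, `quality`,
#'   `experiment_id`; attributes `n_raw`, `n_dropped_length`, `n_dropped_n`.
#' @export
read_fastq <- function(path, experiment_id = NULL, min_len = 16L,
                       max_len = 35L, drop_n = TRUE) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  experiment_id <- experiment_id %||% sub("\\.(fastq|fq)$", "", basename(path))
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop("malformed FASTQ (", path, "): truncated record starting at line ",
         4L * (n %/% 4L) + 1L)
  }
  if (n == 0L) {
    out <- data.frame(read_id = character(), sequence = character(),
                      quality = character(), experiment_id = character(),
                      stringsAsFactors = FALSE)
    attr(out, "n_raw") <- 0L
    attr(out, "n_dropped_length") <- 0L
    attr(out, "n_dropped_n") <- 0L
    return(out)
  }
  idx <- seq(1L, n, by = 4L)
  hdr <- lines[idx]
  seqs <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  qual <- lines[idx + 3L]

  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr)) {
    stop("malformed FASTQ (", path, "): expected '@' header at line ",
         idx[bad_hdr[1L]])
  }
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus)) {
    stop("malformed FASTQ (", path, "): expected '+' separator at line ",
         idx[bad_plus[1L]] + 2L)
  }
  bad_len <- which(nchar(seqs) != nchar(qual))
  if (length(bad_len)) {
    stop("malformed FASTQ (", path, "): sequence/quality length mismatch ",
         "at line ", idx[bad_len[1L]] + 3L)
  }

  seqs <- chartr("u", "t", seqs)
  seqs <- toupper(seqs)
  seqs <- chartr("U", "T", seqs)

  len <- nchar(seqs)
  keep_len <- len >= min_len & len <= max_len
  has_n <- grepl("[^ACGT]", seqs)
  keep <- keep_len & (!drop_n | !has_n)

  out <- data.frame(
    read_id = sub("^@", "", sub("\\s.*$", "", hdr))[keep],
    sequence = seqs[keep],
    quality = qual[keep],
    experiment_id = rep(experiment_id, sum(keep)),
    stringsAsFactors = FALSE
  )
  attr(out, "n_raw") <- length(seqs)
  attr(out, "n_dropped_length") <- sum(!keep_len)
  attr(out, "n_dropped_n") <- sum(keep_len & drop_n & has_n)
  out
}

#' Write reads to a 4-line FASTQ file
#'
#' @param reads data.frame with `read_id`, `sequence`, `quality` columns.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$quality
  if (is.null(qual)) qual <- strrep("I", nchar(reads$sequence))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence, "+",
                           qual))
  if (nrow(reads) == 0L) lines <- character()
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a named character vector of sequences to FASTA
#'
#' @param x named character vector.
#' @param path output path.
#' @export
write_fasta <- function(x, path) {
  set <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read miRNA features from a GFF3 file
#'
#' Returns only features whose type is in `types`; coordinates stay 1-based
#' inclusive as in the file (conversion to 0-based half-open happens at the
#' interval-arithmetic boundary, not here).
#'
#' @param path GFF3 file (9 tab-separated columns; `#` comment lines).
#' @param types feature-type whitelist.
#' @return data.frame with `seqid`, `source`, `feature_type`, `start`, `end`,
#'   `score`, `strand`, `phase`, `attributes`.
#' @export
read_gff3 <- function(path,
                      types = c("miRNA", "miRNA_primary_transcript",
                                "pre-miRNA")) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  empty <- data.frame(
    seqid = character(), source = character(), feature_type = character(),
    start = integer(), end = integer(), score = character(),
    strand = character(), phase = character(), attributes = character(),
    stringsAsFactors = FALSE
  )
  if (!any(keep)) return(empty)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    stop("malformed GFF3 (", path, "): expected 9 columns at line ",
         which(keep)[which(nf != 9L)[1L]])
  }
  m <- do.call(rbind, fields)
  df <- data.frame(
    seqid = m[, 1L], source = m[, 2L], feature_type = m[, 3L],
    start = as.integer(m[, 4L]), end = as.integer(m[, 5L]), score = m[, 6L],
    strand = m[, 7L], phase = m[, 8L], attributes = m[, 9L],
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(df$start) | is.na(df$end) | df$start < 1L |
                 df$end < df$start)
  if (length(bad)) {
    stop("invalid GFF3 record (", path, ") at line ", which(keep)[bad[1L]],
         ": end < start or non-positive coordinate")
  }
  df <- df[df$feature_type %in% types, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write features to a GFF3 file
#'
#' @param features data.frame as returned by [read_gff3()].
#' @param path output path.
#' @export
write_gff3 <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features)) {
    writeLines(paste(features$seqid, features$source, features$feature_type,
                     features$start, features$end, features$score,
                     features$strand, features$phase, features$attributes,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Collapse reads to unique sequences with per-experiment counts
#'
#' The collapsed set is the unit of all downstream processing: each unique
#' sequence appears once, with a count per experiment and a total. Output is
#' ordered lexicographically by sequence, so it is deterministic.
#'
#' @param reads data.frame with `sequence` and `experiment_id` columns (e.g.
#'   from [read_fastq()]), or a list of such data.frames.
#' @return object of class `collapsed_reads`: list with `sequence` (character,
#'   sorted), `counts` (integer matrix, sequences x experiments) and `total`
#'   (integer vector).
#' @export
collapse_reads <- function(reads) {
  if (is.data.frame(reads)) reads <- list(reads)
  reads <- do.call(rbind, lapply(reads, function(d) {
    d[, c("sequence", "experiment_id"), drop = FALSE]
  }))
  if (is.null(reads) || nrow(reads) == 0L) {
    return(new_collapsed(character(), matrix(integer(), 0L, 0L)))
  }
  experiments <- sort(unique(reads$experiment_id))
  seqs <- sort(unique(reads$sequence))
  counts <- table(factor(reads$sequence, levels = seqs),
                  factor(reads$experiment_id, levels = experiments))
  counts <- matrix(as.integer(counts), nrow = length(seqs),
                   dimnames = list(NULL, experiments))
  new_collapsed(seqs, counts)
}

new_collapsed <- function(sequence, counts) {
  structure(list(sequence = sequence, counts = counts,
                 total = as.integer(rowSums(counts))),
            class = "collapsed_reads")
}

#' @export
print.collapsed_reads <- function(x, ...) {
  cat("collapsed_reads:", length(x$sequence), "unique sequences,",
      sum(x$total), "reads,", ncol(x$counts), "experiments\n")
  invisible(x)
}

#' Subset a collapsed read set by sequence
#'
#' @param x `collapsed_reads` object.
#' @param keep logical vector or character vector of sequences to keep.
#' @return `collapsed_reads` with the selected sequences.
#' @export
subset_collapsed <- function(x, keep) {
  stopifnot(inherits(x, "collapsed_reads"))
  if (is.character(keep)) keep <- x$sequence %in% keep
  new_collapsed(x$sequence[keep], x$counts[keep, , drop = FALSE])
}

collapsed_to_df <- function(x) {
  cbind(data.frame(sequence = x$sequence, total_count = x$total,
                   stringsAsFactors = FALSE),
        as.data.frame(x$counts, optional = TRUE))
}

df_to_collapsed <- function(df) {
  counts <- as.matrix(df[, setdiff(names(df), c("sequence", "total_count")),
                         drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- NULL
  new_collapsed(df$sequence, counts)
}

#' Read an experiment-to-project manifest
#'
#' @param path TSV with header columns `experiment_id` and `project_id`.
#' @return named character vector mapping experiment to project.
#' @export
read_exp_manifest <- function(path) {
  df <- read_tsv(path)
  if (!all(c("experiment_id", "project_id") %in% names(df))) {
    stop("manifest must have columns experiment_id and project_id: ", path)
  }
  stats::setNames(as.character(df$project_id), as.character(df$experiment_id))
}
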