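#' Reads per million
#'
#' @param count non-negative read count.
#' @param library_size positive total reads in the library.
#' @return `1e6 * count / library_size`.
#' @export
rpm <- function(count, library_size) {
  if (any(library_size <= 0)) stop("library_size must be positive")
  if (any(count < 0)) stop("count must be non-negative")
  1e6 * count / library_size
}

#' Expression matrix of validated pmiRNAs
#'
#' Builds the complete (explicit zeros) validated-sequence x experiment RPM
#' matrix. The library size is the per-experiment denominator chosen by the
#' caller; the pipeline uses total reads after ingestion filters and before
#' host filtering.
#'
#' @param records classification data.frame from [classify_sequences()]; only
#'   `verdict == "validated_pmiRNA"` rows enter the matrix.
#' @param collapsed `collapsed_reads` carrying per-experiment counts.
#' @param library_sizes named numeric vector, experiment -> total reads.
#' @return object of class `expression_matrix`: list with `rpm` and `counts`
#'   matrices (rows sorted by sequence, columns in `library_sizes` order) and
#'   `library_sizes`.
#' @export
build_matrix <- function(records, collapsed, library_sizes) {
  stopifnot(inherits(collapsed, "collapsed_reads"))
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  experiments <- names(library_sizes)
  missing_exp <- setdiff(colnames(collapsed$counts), experiments)
  if (length(missing_exp)) {
    stop("experiments missing a library size: ",
         paste(missing_exp, collapse = ", "))
  }
  seqs <- sort(unique(records$sequence[records$verdict == "validated_pmiRNA"]))
  counts <- matrix(0L, nrow = length(seqs), ncol = length(experiments),
                   dimnames = list(seqs, experiments))
  i <- match(seqs, collapsed$sequence)
  found <- !is.na(i)
  if (any(found)) {
    have <- intersect(colnames(collapsed$counts), experiments)
    counts[found, have] <- collapsed$counts[i[found], have, drop = FALSE]
  }
  rpm_mat <- sweep(counts, 2, library_sizes[experiments], function(cnt, ls) {
    rpm(cnt, ls)
  })
  structure(list(rpm = rpm_mat, counts = counts,
                 library_sizes = library_sizes[experiments]),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$rpm), "validated sequences x",
      ncol(x$rpm), "experiments\n")
  invisible(x)
}

#' Summary statistics of per-sequence mean RPM
#'
#' For each sequence the mean RPM is taken over ALL experiments (zeros
#' included -- "across all sequencing experiments"), then the overall mean,
#' median, min and max of those per-sequence means are reported.
#'
#' @param em an [build_matrix()] result.
#' @return list with `per_sequence_mean` (named numeric) and scalars `mean`,
#'   `median`, `min`, `max`, `n_sequences`.
#' @export
summarize_rpm <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (nrow(em$rpm) == 0L) stop("cannot summarize an empty expression matrix")
  means <- rowMeans(em$rpm)
  list(per_sequence_mean = means,
       mean = mean(means),
       median = stats::median(means),
       min = min(means),
       max = max(means),
       n_sequences = length(means))
}
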