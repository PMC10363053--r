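#' Host reference set for read subtraction
#'
#' Builds 8-mer indexes over the three host compartments (genome,
#' transcriptome, extra-chromosomal DNA). Empty compartments are allowed but
#' reported with a message.
#'
#' @param genome,transcriptome,extrachromosomal named character vectors of
#'   A/C/G/T sequences (possibly empty).
#' @param word_size seed length for the end-to-end matcher; with the default
#'   8 the pigeonhole search is exact for reads >= 16 nt at up to 1 mismatch.
#' @return object of class `host_reference_set`.
#' @export
host_reference_set <- function(genome = character(),
                               transcriptome = character(),
                               extrachromosomal = character(),
                               word_size = 8L) {
  comps <- list(genome = genome, transcriptome = transcriptome,
                extrachromosomal = extrachromosomal)
  idx <- lapply(names(comps), function(nm) {
    s <- comps[[nm]]
    if (length(s) == 0L) {
      message("host compartment '", nm, "' is empty")
      return(NULL)
    }
    seq_index(s, word_size)
  })
  names(idx) <- names(comps)
  structure(list(indexes = idx, word_size = as.integer(word_size)),
            class = "host_reference_set")
}

#' Remove host-attributable reads
#'
#' A read is removed when it matches a host compartment end-to-end (full read
#' length, no gaps) on either strand with at most `max_mismatches`
#' substitutions. Removal is attributed to the first matching compartment in
#' the order genome, transcriptome, extrachromosomal. End-to-end rather than
#' local matching is used deliberately: local matching would delete
#' miRNA-sized reads that share short cores with the host by chance.
#'
#' @param collapsed a [collapse_reads()] result.
#' @param host a [host_reference_set()].
#' @param max_mismatches maximum substitutions tolerated (default 1).
#' @return list with `retained` (collapsed_reads), `removed` (data.frame
#'   `sequence`, `compartment`, `mismatches`, `total_count`) and `report`
#'   (read-level counts: `n_input`, `n_removed_genome`,
#'   `n_removed_transcriptome`, `n_removed_extrachromosomal`, `n_retained`).
#' @export
filter_host <- function(collapsed, host, max_mismatches = 1L) {
  stopifnot(inherits(collapsed, "collapsed_reads"))
  if (!inherits(host, "host_reference_set")) {
    stop("host references must be built with host_reference_set()")
  }
  if (max_mismatches < 0L) stop("max_mismatches must be >= 0")

  n <- length(collapsed$sequence)
  compartment <- rep(NA_character_, n)
  mism <- rep(NA_integer_, n)
  pending <- rep(TRUE, n)
  for (nm in c("genome", "transcriptome", "extrachromosomal")) {
    idx <- host$indexes[[nm]]
    if (is.null(idx) || !any(pending)) next
    res <- cpp_search_endtoend(idx$ptr, collapsed$sequence[pending],
                               as.integer(max_mismatches))
    hitpos <- which(pending)[res$matched]
    compartment[hitpos] <- nm
    mism[hitpos] <- res$mismatches[res$matched]
    pending[hitpos] <- FALSE
  }

  removed_i <- !is.na(compartment)
  removed <- data.frame(
    sequence = collapsed$sequence[removed_i],
    compartment = compartment[removed_i],
    mismatches = mism[removed_i],
    total_count = collapsed$total[removed_i],
    stringsAsFactors = FALSE
  )
  retained <- subset_collapsed(collapsed, !removed_i)
  count_of <- function(cmp) {
    sum(collapsed$total[removed_i][removed$compartment == cmp])
  }
  report <- list(
    n_input = sum(collapsed$total),
    n_removed_genome = count_of("genome"),
    n_removed_transcriptome = count_of("transcriptome"),
    n_removed_extrachromosomal = count_of("extrachromosomal"),
    n_retained = sum(retained$total)
  )
  list(retained = retained, removed = removed, report = report)
}
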