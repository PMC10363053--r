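#' Plant-style target scoring schema
#'
#' Expectation-score constants in the miRU / psRNATarget family: mismatch 1,
#' G:U wobble 0.5, gap 2, penalties doubled over miRNA positions 2-13 (the
#' functionally critical region in plant miRNA:target pairing), with sites
#' reported up to expectation 5. All constants are configurable and echoed in
#' pipeline output metadata.
#'
#' @param mismatch_penalty,gu_wobble_penalty,gap_penalty non-negative
#'   penalties per aligned position.
#' @param seed_start,seed_end 1-based miRNA positions (from the 5' end) whose
#'   penalties are multiplied by `seed_multiplier`.
#' @param seed_multiplier multiplier over the seed range.
#' @param expectation_cutoff maximum reported expectation.
#' @return object of class `target_schema`.
#' @export
target_schema <- function(mismatch_penalty = 1.0, gu_wobble_penalty = 0.5,
                          gap_penalty = 2.0, seed_start = 2L, seed_end = 13L,
                          seed_multiplier = 2.0, expectation_cutoff = 5.0) {
  if (any(c(mismatch_penalty, gu_wobble_penalty, gap_penalty) < 0)) {
    stop("penalties must be non-negative")
  }
  if (seed_start < 1L || seed_end < seed_start) stop("invalid seed range")
  structure(list(mismatch_penalty = mismatch_penalty,
                 gu_wobble_penalty = gu_wobble_penalty,
                 gap_penalty = gap_penalty,
                 seed_start = as.integer(seed_start),
                 seed_end = as.integer(seed_end),
                 seed_multiplier = seed_multiplier,
                 expectation_cutoff = expectation_cutoff),
            class = "target_schema")
}

#' Expectation score of a miRNA against a candidate site (gapless)
#'
#' The site is read as the transcript's sense strand; the miRNA pairs with it
#' antiparallel, so miRNA position i (1-based from the 5' end) faces site
#' position `L - i + 1`. Watson-Crick pairs cost 0, G:U wobbles
#' `gu_wobble_penalty`, other mismatches `mismatch_penalty`; penalties at
#' miRNA positions within the seed range are multiplied by
#' `seed_multiplier`. Lower is better; 0 is a perfect complement.
#'
#' @param mirna miRNA sequence (DNA alphabet, 5'->3').
#' @param site_sequence transcript window of the same length (sense strand).
#' @param schema a [target_schema()].
#' @return numeric expectation score.
#' @export
expectation_score <- function(mirna, site_sequence, schema = target_schema()) {
  mirna <- toupper(mirna)
  site_sequence <- toupper(site_sequence)
  L <- nchar(mirna)
  if (nchar(site_sequence) != L) {
    stop("site_sequence must have the same length as the miRNA in gapless mode")
  }
  b <- strsplit(mirna, "")[[1]]
  t <- strsplit(site_sequence, "")[[1]][L:1]  # antiparallel pairing partner
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  wc <- t == comp[b]
  gu <- (b == "G" & t == "T") | (b == "T" & t == "G")
  pen <- ifelse(wc, 0, ifelse(gu, schema$gu_wobble_penalty,
                              schema$mismatch_penalty))
  i <- seq_len(L)
  seed <- i >= schema$seed_start & i <= schema$seed_end
  sum(pen * ifelse(seed, schema$seed_multiplier, 1))
}

#' Predict target sites of a miRNA on transcripts
#'
#' Slides the miRNA over every position of every transcript (complementarity
#' sites may lie anywhere on a plant miRNA target, not only the 3' UTR) and
#' reports all windows with expectation at or below the schema cutoff, sorted
#' by expectation then transcript and position.
#'
#' @param mirna miRNA sequence.
#' @param transcripts named character vector of transcript sequences.
#' @param schema a [target_schema()].
#' @return data.frame with `mirna_sequence`, `transcript_id`, `position`
#'   (0-based site start on the transcript) and `expectation`.
#' @export
predict_targets <- function(mirna, transcripts, schema = target_schema()) {
  mirna <- toupper(mirna)
  out <- lapply(names(transcripts), function(tx_id) {
    df <- cpp_target_scan(mirna, toupper(transcripts[[tx_id]]),
                          schema$mismatch_penalty, schema$gu_wobble_penalty,
                          schema$seed_start, schema$seed_end,
                          schema$seed_multiplier, schema$expectation_cutoff)
    if (nrow(df) == 0L) return(NULL)
    data.frame(mirna_sequence = mirna, transcript_id = tx_id,
               position = df$position, expectation = df$expectation,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(mirna_sequence = character(),
                      transcript_id = character(), position = integer(),
                      expectation = numeric(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$expectation, out$transcript_id, out$position), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation test with BH correction
#'
#' Upper-tail hypergeometric p-value per term, `P(X >= k)` for `k` query
#' genes in a term of size `K` drawn from a universe of size `N` with query
#' size `n`, followed by Benjamini-Hochberg adjustment across the tested
#' terms.
#'
#' @param query_genes character vector of genes of interest (must be a subset
#'   of `universe`).
#' @param term_to_genes named list mapping term id to its gene set.
#' @param universe character vector of all considered genes.
#' @param term_names optional named character vector of readable term names.
#' @return data.frame sorted by adjusted p: `term_id`, `term_name`, `k`, `K`,
#'   `n`, `N`, `p_value`, `adjusted_p`, `neg_log10_adjusted_p`.
#' @export
hypergeom_enrich <- function(query_genes, term_to_genes, universe,
                             term_names = NULL) {
  query_genes <- unique(query_genes)
  universe <- unique(universe)
  offenders <- setdiff(query_genes, universe)
  if (length(offenders)) {
    stop("query genes not in universe: ", paste(offenders, collapse = ", "))
  }
  N <- length(universe)
  n <- length(query_genes)
  res <- lapply(names(term_to_genes), function(tid) {
    genes <- intersect(unique(term_to_genes[[tid]]), universe)
    K <- length(genes)
    k <- length(intersect(genes, query_genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tid,
               term_name = if (is.null(term_names)) tid else
                 unname(term_names[tid]),
               k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$adjusted_p <- stats::p.adjust(res$p_value, method = "BH")
  res$neg_log10_adjusted_p <- -log10(res$adjusted_p)
  res <- res[order(res$adjusted_p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read a GMT gene-set file
#'
#' @param path GMT file: term id, description, then member genes, tab
#'   separated.
#' @return list with `sets` (named list of gene vectors) and `names` (named
#'   character vector of descriptions).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, character(1), 1L)
  desc <- vapply(fields, function(f) if (length(f) >= 2) f[[2]] else "",
                 character(1))
  sets <- lapply(fields, function(f) if (length(f) >= 3) f[-(1:2)] else
    character())
  names(sets) <- ids
  list(sets = sets, names = stats::setNames(desc, ids))
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of gene vectors.
#' @param path output path.
#' @param descriptions optional named character vector of descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(id) {
    d <- if (is.null(descriptions)) id else unname(descriptions[id])
    paste(c(id, d, sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
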