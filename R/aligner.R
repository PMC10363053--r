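#' Alignment scoring scheme with Karlin-Altschul constants
#'
#' Defaults follow the common nucleotide-BLAST parameterization: match +2,
#' mismatch -3, gap open 5, gap extend 2 (a gap of length L costs
#' `gap_open + L * gap_extend`), with lambda = 0.625 and K = 0.41 for the
#' bit-score transform `(lambda * S - ln K) / ln 2`.
#'
#' @param match positive match reward.
#' @param mismatch negative mismatch penalty.
#' @param gap_open,gap_extend non-negative gap costs.
#' @param lambda,K positive Karlin-Altschul constants.
#' @return object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2L, mismatch = -3L, gap_open = 5L,
                           gap_extend = 2L, lambda = 0.625, K = 0.41) {
  if (!(match > 0 && mismatch < 0)) stop("need match > 0 > mismatch")
  if (gap_open < 0 || gap_extend < 0) stop("gap costs must be non-negative")
  if (lambda <= 0 || K <= 0) stop("lambda and K must be positive")
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

#' Bit score of a raw alignment score
#'
#' `bitscore = (lambda * S - ln K) / ln 2`, making scores comparable across
#' scoring schemes.
#'
#' @param raw_score raw alignment score S.
#' @param scheme a [scoring_scheme()].
#' @return numeric bit score.
#' @export
bitscore <- function(raw_score, scheme = scoring_scheme()) {
  (scheme$lambda * raw_score - log(scheme$K)) / log(2)
}

#' E-value from a bit score and search-space size
#'
#' `E = m * n * 2^(-bitscore)` with m the query length and n the database
#' length. Edge (effective-length) corrections are deliberately omitted: the
#' pipeline's decisions are made on bit scores, not E-value cut-offs.
#'
#' @param bits bit score.
#' @param query_len,db_len positive lengths.
#' @return numeric expected number of equal-or-better chance hits.
#' @export
evalue <- function(bits, query_len, db_len) {
  if (any(query_len <= 0) || any(db_len <= 0)) {
    stop("query_len and db_len must be positive")
  }
  query_len * db_len * 2^(-bits)
}

new_local_alignment <- function(query_id, subject_id, raw, qstart, qend,
                                sstart, send, matches, length, gaps, strand,
                                scheme, db_len, query_len) {
  idn <- if (length > 0) matches / length else 0
  bits <- bitscore(raw, scheme)
  structure(list(
    query_id = query_id, subject_id = subject_id, raw_score = raw,
    bitscore = bits, evalue = evalue(bits, query_len, db_len),
    identity = idn, query_span = c(qstart, qend),
    subject_span = c(sstart, send), strand = strand, matches = matches,
    length = length, gaps = gaps
  ), class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf(
    "local_alignment %s vs %s (%s): raw %d, bits %.2f, identity %.3f, q[%d,%d) s[%d,%d)\n",
    x$query_id, x$subject_id, x$strand, x$raw_score, x$bitscore, x$identity,
    x$query_span[1], x$query_span[2], x$subject_span[1], x$subject_span[2]))
  invisible(x)
}

#' Optimal local alignment (Smith-Waterman, affine gaps)
#'
#' Exact dynamic programming over the full matrix; traceback ties prefer the
#' diagonal, then up, then left, so results are deterministic. Spans are
#' 0-based half-open.
#'
#' @param query,subject non-empty A/C/G/T strings.
#' @param scheme a [scoring_scheme()].
#' @param query_id,subject_id labels carried into the result.
#' @return object of class `local_alignment` with `raw_score`, `bitscore`,
#'   `evalue`, `identity`, `query_span`, `subject_span`, `strand`.
#' @export
smith_waterman <- function(query, subject, scheme = scoring_scheme(),
                           query_id = "query", subject_id = "subject") {
  assert_dna(query, "query")
  assert_dna(subject, "subject")
  stopifnot(length(query) == 1, length(subject) == 1)
  a <- cpp_sw(query, subject, scheme$match, scheme$mismatch, scheme$gap_open,
              scheme$gap_extend)
  new_local_alignment(query_id, subject_id, a$score, a$qstart, a$qend,
                      a$sstart, a$send, a$matches, a$length, a$gaps, "+",
                      scheme, nchar(subject), nchar(query))
}

#' Build a k-mer index over subject sequences
#'
#' The index stores exact `word_size`-mer positions over the forward strand
#' of every subject; searches handle the reverse strand by aligning the
#' reverse complement of the query.
#'
#' @param sequences named character vector of A/C/G/T subject sequences.
#' @param word_size exact-seed length (>= 4).
#' @return object of class `seq_index`.
#' @export
seq_index <- function(sequences, word_size = 11L) {
  if (word_size < 4L) stop("word_size must be >= 4")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("subject sequences must be named")
  }
  sequences <- toupper(sequences)
  ptr <- cpp_index_build(unname(sequences), names(sequences),
                         as.integer(word_size))
  structure(list(ptr = ptr, names = names(sequences),
                 word_size = as.integer(word_size),
                 total_bases = sum(nchar(sequences))),
            class = "seq_index")
}

#' @export
print.seq_index <- function(x, ...) {
  cat("seq_index:", length(x$names), "sequences,", x$total_bases,
      "bases, word size", x$word_size, "\n")
  invisible(x)
}

# internal: seeded hits for many queries against an index.
# Returns a data.frame (0-based half-open spans on the forward subject and
# forward query) with identity, coverage, bitscore, evalue columns added.
index_hits <- function(queries, index, scheme = scoring_scheme(),
                       best_only = FALSE) {
  stopifnot(inherits(index, "seq_index"))
  df <- cpp_search_local(index$ptr, queries, scheme$match, scheme$mismatch,
                         scheme$gap_open, scheme$gap_extend, best_only)
  df$query_seq <- queries[df$query]
  df$subject_id <- index$names[df$subject]
  df$identity <- ifelse(df$length > 0, df$matches / df$length, 0)
  df$coverage <- (df$qend - df$qstart) / nchar(df$query_seq)
  df$bitscore <- bitscore(df$score, scheme)
  df$evalue <- evalue(df$bitscore, nchar(df$query_seq), index$total_bases)
  df
}

#' Seed-and-extend search of a query against an indexed database
#'
#' Collects exact word-size seed matches on both strands, extends each
#' candidate region with full Smith-Waterman dynamic programming, and returns
#' the best hit (score, then identity, then subject name, then position).
#' Whenever an exact seed of the index word size lies on the optimal local
#' alignment, the returned score equals the [smith_waterman()] score.
#'
#' @param query non-empty A/C/G/T string.
#' @param index a [seq_index()].
#' @param scheme a [scoring_scheme()].
#' @return a `local_alignment` (with `subject_id` and `strand` set), or
#'   `NULL` when no seed is shared with any subject.
#' @export
seeded_search <- function(query, index, scheme = scoring_scheme()) {
  assert_dna(query, "query")
  df <- index_hits(query, index, scheme, best_only = TRUE)
  if (nrow(df) == 0L) return(NULL)
  h <- df[1L, ]
  new_local_alignment("query", h$subject_id, h$score, h$qstart, h$qend,
                      h$sstart, h$send, h$matches, h$length, h$gaps,
                      h$strand, scheme, index$total_bases, nchar(query))
}

#' Tabular hits in BLAST outfmt-6 column order
#'
#' @param hits hit data.frame from the internal seeded search (as stored in
#'   mapping results).
#' @return data.frame with columns qseqid, sseqid, pident, length, mismatch,
#'   gapopen, qstart, qend, sstart, send, evalue, bitscore (1-based inclusive
#'   coordinates, as BLAST prints them).
#' @export
as_blast_tab <- function(hits) {
  data.frame(
    qseqid = hits$query_seq, sseqid = hits$subject_id,
    pident = round(100 * hits$identity, 3), length = hits$length,
    mismatch = hits$length - hits$matches - hits$gaps, gapopen = hits$gaps,
    qstart = hits$qstart + 1L, qend = hits$qend,
    sstart = ifelse(hits$strand == "+", hits$sstart + 1L, hits$send),
    send = ifelse(hits$strand == "+", hits$send, hits$sstart + 1L),
    evalue = hits$evalue, bitscore = round(hits$bitscore, 2),
    stringsAsFactors = FALSE
  )
}
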