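DB_NAMES <- c("plant_mirbase", "human_mirbase", "other_mirbase",
              "human_refseq_mrna")

#' A named sequence database for competitive classification
#'
#' @param db_name one of `plant_mirbase`, `human_mirbase`, `other_mirbase`,
#'   `human_refseq_mrna`.
#' @param sequences named character vector; names are accessions and must be
#'   unique within the database.
#' @return object of class `sequence_db`.
#' @export
sequence_db <- function(db_name, sequences) {
  db_name <- match.arg(db_name, DB_NAMES)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("database sequences must carry unique accession names")
  }
  structure(list(db_name = db_name, sequences = toupper(sequences)),
            class = "sequence_db")
}

check_db_set <- function(dbs) {
  nms <- vapply(dbs, function(d) {
    if (!inherits(d, "sequence_db")) stop("each database must be a sequence_db")
    d$db_name
  }, character(1))
  if (!setequal(nms, DB_NAMES) || length(dbs) != 4L) {
    stop("exactly the four databases ", paste(DB_NAMES, collapse = ", "),
         " must be supplied")
  }
  stats::setNames(dbs[match(DB_NAMES, nms)], DB_NAMES)
}

#' Best hit per database for each sequence
#'
#' For every query sequence and each of the four databases, reports the best
#' hit by bit score (ties broken by higher identity, then lexicographic
#' accession). A hit is `full_length_identity` when the whole read aligns at
#' 100\% identity with no gaps.
#'
#' @param sequences character vector of query sequences.
#' @param dbs list of the four [sequence_db()] objects.
#' @param scheme a [scoring_scheme()].
#' @param word_size exact-seed length for the database search (default 11).
#' @return data.frame with one row per sequence x database combination that
#'   produced a hit: `sequence`, `db_name`, `accession`, `raw_score`,
#'   `bitscore`, `identity`, `full_length_identity`. Absent hits are absent
#'   rows.
#' @export
search_all_dbs <- function(sequences, dbs, scheme = scoring_scheme(),
                           word_size = 11L) {
  dbs <- check_db_set(dbs)
  out <- lapply(DB_NAMES, function(nm) {
    idx <- seq_index(dbs[[nm]]$sequences, word_size)
    hits <- index_hits(sequences, idx, scheme, best_only = TRUE)
    if (nrow(hits) == 0L) return(NULL)
    data.frame(
      sequence = hits$query_seq, db_name = nm, accession = hits$subject_id,
      raw_score = hits$score, bitscore = hits$bitscore,
      identity = hits$identity,
      full_length_identity = hits$identity == 1 & hits$coverage == 1 &
        hits$gaps == 0L,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(sequence = character(), db_name = character(),
                      accession = character(), raw_score = integer(),
                      bitscore = numeric(), identity = numeric(),
                      full_length_identity = logical(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Classify one sequence from its four database hits
#'
#' Implements the competitive discard rule: (1) any full-length
#' 100\%-identity hit to a human database discards the sequence as human;
#' (2) a sequence with no hit in any database is `no_hit`; (3) the plant
#' bit score must be the strict maximum over all databases -- a missing plant
#' hit, a higher competing hit, or a tie discards the sequence as
#' `discarded_not_top_plant`; (4) otherwise the sequence is a
#' `validated_pmiRNA`.
#'
#' @param hits named list over the four database names; each element is
#'   either `NULL` (no hit) or a list with at least `best_bitscore` and
#'   `full_length_identity` (as produced by [search_all_dbs()] rows).
#' @return verdict string.
#' @export
classify <- function(hits) {
  if (!all(DB_NAMES %in% names(hits))) {
    stop("hits must be a named list over ", paste(DB_NAMES, collapse = ", "))
  }
  human_full <- any(vapply(hits[c("human_mirbase", "human_refseq_mrna")],
                           function(h) {
                             !is.null(h) && isTRUE(h$full_length_identity)
                           }, logical(1)))
  if (human_full) return("discarded_human_identity")
  if (all(vapply(hits[DB_NAMES], is.null, logical(1)))) return("no_hit")
  plant <- hits[["plant_mirbase"]]
  if (is.null(plant)) return("discarded_not_top_plant")
  others <- hits[setdiff(DB_NAMES, "plant_mirbase")]
  other_best <- vapply(others, function(h) {
    if (is.null(h)) -Inf else h$best_bitscore
  }, numeric(1))
  if (any(other_best >= plant$best_bitscore)) {
    return("discarded_not_top_plant")
  }
  "validated_pmiRNA"
}

#' Classify many sequences against the four databases
#'
#' Runs [search_all_dbs()] and applies [classify()] to every sequence,
#' returning one record per sequence (a total function: every sequence gets
#' exactly one verdict).
#'
#' @inheritParams search_all_dbs
#' @return data.frame with per-database best accession/bitscore/identity
#'   columns, `verdict`, and `best_plant_match`.
#' @export
classify_sequences <- function(sequences, dbs, scheme = scoring_scheme(),
                               word_size = 11L) {
  sequences <- unique(sequences)
  hits <- search_all_dbs(sequences, dbs, scheme, word_size)
  rec <- data.frame(sequence = sequences, stringsAsFactors = FALSE)
  for (nm in DB_NAMES) {
    h <- hits[hits$db_name == nm, , drop = FALSE]
    i <- match(rec$sequence, h$sequence)
    rec[[paste0(nm, "_accession")]] <- h$accession[i]
    rec[[paste0(nm, "_bitscore")]] <- h$bitscore[i]
    rec[[paste0(nm, "_identity")]] <- h$identity[i]
    rec[[paste0(nm, "_full_length_identity")]] <- h$full_length_identity[i]
  }
  rec$verdict <- vapply(seq_len(nrow(rec)), function(r) {
    hl <- lapply(DB_NAMES, function(nm) {
      bs <- rec[[paste0(nm, "_bitscore")]][r]
      if (is.na(bs)) return(NULL)
      list(db_name = nm,
           best_accession = rec[[paste0(nm, "_accession")]][r],
           best_bitscore = bs,
           best_identity = rec[[paste0(nm, "_identity")]][r],
           full_length_identity =
             rec[[paste0(nm, "_full_length_identity")]][r])
    })
    names(hl) <- DB_NAMES
    classify(hl)
  }, character(1))
  rec$best_plant_match <- ifelse(rec$verdict == "validated_pmiRNA",
                                 rec$plant_mirbase_accession, NA_character_)
  rec
}

#' Gaussian kernel density estimate of a score distribution
#'
#' Bandwidth defaults to Scott's rule-of-thumb (`stats::bw.nrd`). The curve
#' integrates to 1 (up to the tail mass beyond the grid, below 1\% at the
#' default 3-bandwidth cut). Degenerate inputs (fewer than two finite scores,
#' or zero spread, for which no bandwidth exists) raise an error.
#'
#' @param scores numeric vector of scores.
#' @param bandwidth `"scott"` (default), `"silverman"`, or a positive number.
#' @param from,to optional grid limits (used to put two densities on a common
#'   grid for [overlap_coefficient()]).
#' @param n number of grid points (default 512).
#' @return data.frame with columns `x` and `density`.
#' @export
kde <- function(scores, bandwidth = "scott", from = NULL, to = NULL,
                n = 512L) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 2L) stop("kde needs at least 2 finite scores")
  bw <- if (is.numeric(bandwidth)) {
    bandwidth
  } else if (identical(bandwidth, "scott")) {
    stats::bw.nrd(scores)
  } else if (identical(bandwidth, "silverman")) {
    stats::bw.nrd0(scores)
  } else {
    stop("unknown bandwidth rule: ", bandwidth)
  }
  # heavily tied score sets can have zero IQR with positive spread; fall back
  # to the Gaussian-reference (sd-based) Scott bandwidth there
  if (is.character(bandwidth) && is.finite(bw) && bw <= 0 &&
      stats::sd(scores) > 0) {
    bw <- 1.06 * stats::sd(scores) * length(scores)^(-1 / 5)
  }
  if (!is.finite(bw) || bw <= 0) {
    stop("degenerate score distribution (zero spread): no bandwidth")
  }
  args <- list(x = scores, bw = bw, n = as.integer(n))
  if (!is.null(from)) args$from <- from
  if (!is.null(to)) args$to <- to
  d <- do.call(stats::density, args)
  data.frame(x = d$x, density = d$y)
}

#' Overlap coefficient of two densities on a common grid
#'
#' Trapezoidal integral of the pointwise minimum; 1 means identical
#' distributions, 0 disjoint supports.
#'
#' @param density_a,density_b data.frames from [kde()] on the same grid.
#' @return numeric in `[0, 1]`.
#' @export
overlap_coefficient <- function(density_a, density_b) {
  if (nrow(density_a) != nrow(density_b) ||
      !isTRUE(all.equal(density_a$x, density_b$x))) {
    stop("densities must share a common grid (use kde(from=, to=, n=))")
  }
  x <- density_a$x
  y <- pmin(density_a$density, density_b$density)
  sum(diff(x) * (utils::head(y, -1) + y[-1]) / 2)
}

#' Overlap of plant and human-mRNA bit-score densities
#'
#' Convenience diagnostic for the before/after-filter comparison: computes
#' KDEs of the plant-miRNA and human-mRNA best bit scores over a common grid
#' and returns their overlap coefficient.
#'
#' @param records classification data.frame from [classify_sequences()].
#' @param db_a,db_b database columns to compare.
#' @return numeric overlap coefficient, or `NA` when either score set has
#'   fewer than two values.
#' @export
bitscore_overlap <- function(records, db_a = "plant_mirbase",
                             db_b = "human_refseq_mrna") {
  a <- records[[paste0(db_a, "_bitscore")]]
  b <- records[[paste0(db_b, "_bitscore")]]
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L ||
      stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(NA_real_)
  }
  lo <- min(a, b)
  hi <- max(a, b)
  pad <- 0.1 * (hi - lo) + 1e-9
  da <- kde(a, from = lo - pad, to = hi + pad)
  db <- kde(b, from = lo - pad, to = hi + pad)
  overlap_coefficient(da, db)
}
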