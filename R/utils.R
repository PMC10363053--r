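`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA sequences
#'
#' @param x character vector of A/C/G/T sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  cpp_revcomp(toupper(x))
}

# run code under a temporary RNG state, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# deterministic per-stage substream seed (kept below 2^31 - 1)
stage_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1, is.finite(seed))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 7919 + h * 104729) %% 2147483647)
}

# round half away from zero (printed-table convention)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

assert_dna <- function(x, what = "sequence", allow_empty = FALSE) {
  if (!is.character(x)) stop(what, " must be a character vector")
  if (!allow_empty && any(!nzchar(x))) stop(what, " must be non-empty")
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(what, " contains characters outside A/C/G/T: ",
         paste(utils::head(x[bad], 3), collapse = ", "))
  }
  invisible(x)
}

# largest-remainder apportionment of n into parts proportional to w
apportion <- function(n, w) {
  if (n == 0) return(integer(length(w)))
  raw <- n * w / sum(w)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
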