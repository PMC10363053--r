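#' Hierarchical clustering of the pmiRNA abundance matrix
#'
#' Agglomerative clustering of both axes of the validated-sequence x
#' experiment matrix. The defaults (log(1 + RPM) transform, Euclidean
#' distance, average linkage) suit abundance data; a presence/absence mode
#' (`transform = "presence"`, `distance = "binary"`, i.e. Jaccard) matches
#' clustering on presence alone.
#'
#' @param mat numeric matrix (sequences x experiments) or an
#'   [build_matrix()] result.
#' @param distance `"euclidean"` (default) or `"binary"` (Jaccard).
#' @param linkage agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @param transform `"log1p"` (default), `"presence"` (binarize), or
#'   `"none"`.
#' @return object of class `cluster_scaffold`: `experiment_hclust`,
#'   `sequence_hclust` (NULL with a warning when an axis has a single item),
#'   leaf orders, and the parameters used.
#' @export
hierarchical_cluster <- function(mat, distance = c("euclidean", "binary"),
                                 linkage = "average",
                                 transform = c("log1p", "presence", "none")) {
  if (inherits(mat, "expression_matrix")) mat <- mat$rpm
  distance <- match.arg(distance)
  transform <- match.arg(transform)
  if (nrow(mat) == 0L || ncol(mat) == 0L) stop("matrix must be non-empty")
  x <- switch(transform,
              log1p = log1p(mat),
              presence = (mat > 0) * 1,
              none = mat)
  axis_cluster <- function(m, what) {
    if (nrow(m) < 2L) {
      warning("single ", what, ": trivial dendrogram")
      return(NULL)
    }
    stats::hclust(stats::dist(m, method = distance), method = linkage)
  }
  seq_hc <- axis_cluster(x, "sequence")
  exp_hc <- axis_cluster(t(x), "experiment")
  leaf_order <- function(hc, labels) {
    if (is.null(hc)) labels else hc$labels[hc$order]
  }
  structure(list(
    experiment_hclust = exp_hc,
    sequence_hclust = seq_hc,
    experiment_leaf_order = leaf_order(exp_hc, colnames(mat)),
    sequence_leaf_order = leaf_order(seq_hc, rownames(mat)),
    params = list(distance = distance, linkage = linkage,
                  transform = transform)
  ), class = "cluster_scaffold")
}

#' Cut the dendrograms into experiment and sequence groups
#'
#' The numbers of groups are user inputs (as in a heatmap annotated with
#' fixed numbers of experiment and sequence groups), not auto-detected.
#'
#' @param scaffold a [hierarchical_cluster()] result.
#' @param n_experiment_groups,n_sequence_groups number of groups per axis
#'   (each between 1 and the number of leaves).
#' @return object of class `cluster_grouping` with `experiment_groups` and
#'   `sequence_groups` (named lists of member vectors, ordered by first
#'   appearance along the dendrogram) plus the leaf orders.
#' @export
cut_groups <- function(scaffold, n_experiment_groups, n_sequence_groups) {
  stopifnot(inherits(scaffold, "cluster_scaffold"))
  cut_axis <- function(hc, leaf_order, k, prefix) {
    n <- length(leaf_order)
    if (k < 1L || k > n) {
      stop("number of ", prefix, " groups must be between 1 and ", n)
    }
    if (is.null(hc)) {
      memb <- stats::setNames(rep(1L, n), leaf_order)
    } else {
      memb <- stats::cutree(hc, k = k)
    }
    # order groups by first appearance along the dendrogram
    first <- memb[leaf_order]
    ids <- unique(first)
    groups <- lapply(ids, function(g) names(memb)[memb == g])
    names(groups) <- paste0(prefix, seq_along(groups))
    groups
  }
  structure(list(
    experiment_groups = cut_axis(scaffold$experiment_hclust,
                                 scaffold$experiment_leaf_order,
                                 n_experiment_groups, "EG"),
    sequence_groups = cut_axis(scaffold$sequence_hclust,
                               scaffold$sequence_leaf_order,
                               n_sequence_groups, "SG"),
    experiment_leaf_order = scaffold$experiment_leaf_order,
    sequence_leaf_order = scaffold$sequence_leaf_order
  ), class = "cluster_grouping")
}

#' Project composition of each experiment group
#'
#' For each experiment group, the percentage of members coming from each
#' sequencing project, rounded half-up to two decimals (the precision used
#' in per-project distribution tables); each row sums to 100 up to rounding.
#'
#' @param experiment_groups named list of experiment-id vectors (e.g. from
#'   [cut_groups()]).
#' @param experiment_to_project named character vector experiment -> project.
#' @return data.frame with one row per group (`group`, `n`, then one column
#'   per project).
#' @export
project_distribution <- function(experiment_groups, experiment_to_project) {
  projects <- sort(unique(experiment_to_project))
  rows <- lapply(names(experiment_groups), function(g) {
    members <- experiment_groups[[g]]
    if (length(members) == 0L) stop("empty experiment group: ", g)
    unmapped <- setdiff(members, names(experiment_to_project))
    if (length(unmapped)) {
      stop("experiments without a project mapping: ",
           paste(unmapped, collapse = ", "))
    }
    proj <- experiment_to_project[members]
    pct <- vapply(projects, function(p) {
      round_half_up(100 * sum(proj == p) / length(members), 2)
    }, numeric(1))
    cbind(data.frame(group = g, n = length(members), stringsAsFactors = FALSE),
          as.data.frame(as.list(pct), optional = TRUE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Search for consensus k-mers shared across sequences
#'
#' Tallies every k-mer (k from `kmin` to `kmax`) over the unique input
#' sequences and returns those present in at least `min_fraction` of them,
#' longest first. An empty result means no conserved core exists.
#'
#' @param sequences character vector; duplicates are collapsed before
#'   computing fractions.
#' @param kmin,kmax k-mer length range (`2 <= kmin <= kmax`).
#' @param min_fraction minimum fraction of sequences containing the k-mer.
#' @return data.frame with `kmer`, `k`, `fraction`, sorted by k (descending),
#'   fraction (descending), then k-mer.
#' @export
consensus_search <- function(sequences, kmin, kmax, min_fraction = 0.9) {
  if (kmin < 2L || kmax < kmin) stop("need 2 <= kmin <= kmax")
  sequences <- unique(toupper(sequences))
  short <- nchar(sequences) < kmin
  if (any(short)) {
    warning(sum(short), " sequence(s) shorter than kmin excluded")
    sequences <- sequences[!short]
  }
  if (length(sequences) == 0L) {
    return(data.frame(kmer = character(), k = integer(), fraction = numeric(),
                      stringsAsFactors = FALSE))
  }
  n <- length(sequences)
  out <- lapply(seq(kmax, kmin), function(k) {
    usable <- sequences[nchar(sequences) >= k]
    if (length(usable) == 0L) return(NULL)
    per_seq <- lapply(usable, function(s) {
      unique(substring(s, seq_len(nchar(s) - k + 1L),
                       seq_len(nchar(s) - k + 1L) + k - 1L))
    })
    tab <- table(unlist(per_seq))
    frac <- as.numeric(tab) / n  # fraction over all unique sequences
    keep <- frac >= min_fraction
    if (!any(keep)) return(NULL)
    data.frame(kmer = names(tab)[keep], k = k, fraction = frac[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(kmer = character(), k = integer(), fraction = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- out[order(-out$k, -out$fraction, out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  out
}
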