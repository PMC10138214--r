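#' Hard partition of n items
#'
#' A `cps_partition` stores a hard cluster assignment of `n` items together
#' with the cluster proportions used as optimal-transport marginals. Labels
#' are compacted to the dense range `1..K` (empty labels are dropped); the
#' original labels are preserved in `label_map` so I/O can round-trip user
#' labels.
#'
#' @param labels integer (or factor/character) vector of cluster assignments,
#'   one per item. Missing values are not allowed.
#' @return An object of class `cps_partition` with fields
#'   \describe{
#'     \item{labels}{integer vector in `1..K`}
#'     \item{n}{number of items}
#'     \item{K}{number of clusters}
#'     \item{q}{proportion vector, `q[k] = |C_k|/n`}
#'     \item{sizes}{integer cluster sizes}
#'     \item{label_map}{original label of each compacted cluster}
#'   }
#' @examples
#' p <- partition(c("a", "a", "b", "b", "b"))
#' p$K
#' p$q
#' @export
partition <- function(labels) {
  if (length(labels) == 0L) stop("empty input: a partition needs at least one item")
  if (anyNA(labels)) stop("missing cluster labels are not allowed")
  f <- factor(labels)
  lab <- as.integer(f)
  K <- nlevels(f)
  sizes <- tabulate(lab, nbins = K)
  structure(
    list(
      labels = lab,
      n = length(lab),
      K = K,
      q = sizes / length(lab),
      sizes = sizes,
      label_map = levels(f)
    ),
    class = "cps_partition"
  )
}

#' @export
print.cps_partition <- function(x, ...) {
  cat(sprintf("<cps_partition> n = %d, K = %d\n", x$n, x$K))
  cat("proportions:", paste(sprintf("%.3f", x$q), collapse = " "), "\n")
  invisible(x)
}

is_partition <- function(x) inherits(x, "cps_partition")

#' Cluster proportions of a partition
#'
#' Returns `q`, the length-`K` vector of cluster proportions
#' (`q[k] = |C_k|/n`) that serves as the marginal distribution of the
#' partition in the optimal-transport alignment.
#'
#' @param p a [partition()].
#' @return numeric vector of length `K` summing to 1.
#' @export
cluster_proportions <- function(p) {
  stopifnot(is_partition(p))
  p$q
}

#' Member index sets of each cluster
#'
#' @param p a [partition()].
#' @return list of length `K`; element `k` holds the (1-based) item indices of
#'   cluster `k`.
#' @export
cluster_members <- function(p) {
  stopifnot(is_partition(p))
  split(seq_len(p$n), p$labels)
}

#' Jaccard distance between two item sets
#'
#' `1 - |A intersect B| / |A union B|`, the ground cost between clusters used
#' throughout the alignment and separability computations. Two empty sets are
#' defined to have distance 0 (clusters that vanish together are treated as
#' identical); this degenerate case is reported with a warning.
#'
#' @param a,b integer vectors of item indices (duplicates ignored).
#' @return value in `[0, 1]`; 0 iff the sets are equal, 1 iff disjoint.
#' @export
jaccard_distance <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0L && length(b) == 0L) {
    warning("jaccard_distance of two empty sets; defined as 0")
    return(0)
  }
  inter <- length(intersect(a, b))
  1 - inter / (length(a) + length(b) - inter)
}

#' Contingency table of two partitions
#'
#' Entry `(i, j)` counts the items assigned to cluster `i` of `p1` and
#' cluster `j` of `p2`. Row sums equal the cluster sizes of `p1`, column sums
#' those of `p2`, and the grand total is `n`.
#'
#' @param p1,p2 partitions of the same items.
#' @return integer matrix of dimension `K1 x K2`.
#' @export
contingency <- function(p1, p2) {
  stopifnot(is_partition(p1), is_partition(p2))
  if (p1$n != p2$n) stop("partitions cover different numbers of items")
  tab <- table(factor(p1$labels, levels = seq_len(p1$K)),
               factor(p2$labels, levels = seq_len(p2$K)))
  matrix(as.integer(tab), nrow = p1$K, ncol = p2$K)
}

#' Pairwise Jaccard cost matrix between the clusters of two partitions
#'
#' @param p1,p2 partitions of the same items.
#' @return `K1 x K2` matrix of Jaccard distances between cluster member sets.
#' @keywords internal
jaccard_cost_matrix <- function(p1, p2) {
  ct <- contingency(p1, p2)
  # |union| = |A| + |B| - |intersection|, vectorized over the table
  uni <- outer(p1$sizes, p2$sizes, "+") - ct
  1 - ct / uni
}

#' Read a table of cluster labelings
#'
#' Reads an `n x (m+1)` label table (CSV or TSV, header row naming the
#' partitions, first column conventionally the reference) and returns a list
#' of [partition()] objects, one per column.
#'
#' @param path file path; delimiter inferred from the extension (`.tsv` uses
#'   tab, otherwise comma).
#' @return named list of partitions.
#' @export
read_label_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  if (anyNA(df)) stop("label table contains missing values: ", path)
  lapply(df, partition)
}
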