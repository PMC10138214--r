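#' Average within-cluster variance of a feature matrix
#'
#' Unweighted mean over clusters of the mean, across coordinates, of the
#' per-coordinate sample variance (denominator `n_k - 1`). Singleton
#' clusters contribute 0. This is the quantity the default noise level is
#' calibrated against: the perturbation variance is a fraction (10% by
#' default) of this value. The convention is scale-free across the number of
#' clusters and dimensions; scaling `X` by `c` scales the result by `c^2`.
#'
#' @param X numeric matrix, items in rows.
#' @param p a [partition()] of the rows of `X`.
#' @return nonnegative scalar; 0 (with a warning) when every cluster is a
#'   singleton.
#' @export
avg_within_cluster_variance <- function(X, p) {
  X <- as.matrix(X)
  stopifnot(is_partition(p), nrow(X) == p$n)
  per_cluster <- vapply(seq_len(p$K), function(k) {
    rows <- p$labels == k
    if (sum(rows) < 2L) return(0)
    mean(apply(X[rows, , drop = FALSE], 2L, stats::var))
  }, numeric(1))
  if (all(p$sizes < 2L)) warning("all clusters are singletons; variance is 0")
  mean(per_cluster)
}

#' Add isotropic Gaussian noise to a feature matrix
#'
#' Every entry receives independent `N(0, variance)` noise; the noise is
#' homoscedastic across points and coordinates. With `variance = 0` the
#' input is returned unchanged.
#'
#' @param X numeric matrix.
#' @param variance nonnegative per-coordinate noise variance.
#' @param seed integer seed; the output is reproducible given the seed.
#' @return matrix of the same dimension.
#' @export
perturb <- function(X, variance, seed) {
  X <- as.matrix(X)
  if (variance < 0) stop("noise variance must be nonnegative")
  if (variance == 0) return(X)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  X + matrix(stats::rnorm(length(X), sd = sqrt(variance)), nrow(X), ncol(X))
}

# Seed hygiene: run under a given seed without clobbering the caller's RNG
# stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Built-in clusterer adapters
#'
#' A clusterer is any function `(X, seed) -> integer labels` that is
#' deterministic given the seed. These constructors wrap the standard
#' single-view algorithms:
#' \describe{
#'   \item{`clusterer_kmeans(k)`}{[stats::kmeans()] with `nstart = 10`.}
#'   \item{`clusterer_gmm(k)`}{Gaussian mixture via [mclust::Mclust()].}
#'   \item{`clusterer_leiden(resolution, knn)`}{Leiden community detection on
#'     a shared `knn`-nearest-neighbour graph (Euclidean), mirroring the
#'     graph-based default of single-cell pipelines.}
#' }
#'
#' @param k number of clusters.
#' @return a function `(X, seed)` returning an integer label vector.
#' @name clusterers
NULL

#' @rdname clusterers
#' @export
clusterer_kmeans <- function(k) {
  force(k)
  function(X, seed) {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
    stats::kmeans(as.matrix(X), centers = k, nstart = 10L, iter.max = 50L)$cluster
  }
}

#' @rdname clusterers
#' @export
clusterer_gmm <- function(k) {
  force(k)
  function(X, seed) {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
    fit <- mclust::Mclust(as.matrix(X), G = k, verbose = FALSE)
    if (is.null(fit)) stop("Gaussian mixture fit failed")
    fit$classification
  }
}

#' @rdname clusterers
#' @param resolution Leiden resolution parameter.
#' @param knn number of nearest neighbours for the graph.
#' @export
clusterer_leiden <- function(resolution = 1.0, knn = 15L) {
  force(resolution); force(knn)
  function(X, seed) {
    X <- as.matrix(X)
    n <- nrow(X)
    k <- min(knn, n - 1L)
    d <- as.matrix(stats::dist(X))
    # kNN edge list (symmetrized)
    edges <- do.call(rbind, lapply(seq_len(n), function(i) {
      nb <- order(d[i, ])[2:(k + 1L)]
      cbind(i, nb)
    }))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::simplify(g)
    old <- local_seed(seed)
    on.exit(restore_seed(old))
    comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                   resolution = resolution,
                                   n_iterations = 5L)
    igraph::membership(comm)
  }
}

#' Build the clustering ensemble for one view
#'
#' Implements the per-view ensemble construction: the clusterer applied to
#' the original data yields the *reference partition*; `m` further partitions
#' are obtained by re-clustering noise-perturbed copies of the data, with the
#' noise variance set to `noise_fraction` times the average within-cluster
#' variance of the original data under the reference partition. With
#' `perturb_view = FALSE` (a dominant view whose structure should not be
#' degraded) the clusterer is re-run on the unperturbed data with distinct
#' seeds instead.
#'
#' @param X numeric matrix (items in rows) for this view.
#' @param clusterer a function `(X, seed) -> labels`, e.g. from
#'   [clusterer_kmeans()].
#' @param m number of perturbed partitions.
#' @param noise_fraction fraction of the average within-cluster variance used
#'   as noise variance (default 0.1).
#' @param seed master seed; partition `p` uses `seed + p` so the whole
#'   ensemble is reproducible.
#' @param perturb_view logical; perturb this view's data (default `TRUE`).
#' @param view name used in error messages.
#' @return a `cps_ensemble` (see [align_ensemble()]) whose `raw` slot also
#'   retains the pre-alignment partitions needed by the contribution
#'   analysis; the noise variance used is attached as attribute
#'   `noise_variance`.
#' @export
build_ensemble <- function(X, clusterer, m = 20L, noise_fraction = 0.1,
                           seed = 1L, perturb_view = TRUE, view = "view") {
  X <- as.matrix(X)
  if (m < 1L) stop("m must be at least 1")
  if (noise_fraction < 0) stop("noise_fraction must be nonnegative")
  ref_labels <- run_clusterer(clusterer, X, seed, view)
  ref <- partition(ref_labels)
  sigma2 <- if (perturb_view && noise_fraction > 0)
    noise_fraction * avg_within_cluster_variance(X, ref) else 0
  parts <- vector("list", m)
  for (p in seq_len(m)) {
    Xp <- if (perturb_view) perturb(X, sigma2, seed = seed + 10000L + p) else X
    parts[[p]] <- partition(run_clusterer(clusterer, Xp, seed + p, view))
  }
  ens <- align_ensemble(parts, ref)
  attr(ens, "noise_variance") <- sigma2
  ens
}

run_clusterer <- function(clusterer, X, seed, view) {
  labels <- clusterer(X, seed)
  if (length(labels) != nrow(X))
    stop(sprintf("clusterer for %s returned %d labels for %d items",
                 view, length(labels), nrow(X)))
  if (anyNA(labels) || length(unique(labels)) < 1L)
    stop(sprintf("clusterer for %s returned invalid labels", view))
  labels
}
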