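#' Simulate two-view Gaussian-mixture data
#'
#' Generates paired feature matrices for two views of the same `n` items
#' under the canonical multi-view regimes:
#' \describe{
#'   \item{`complementary`}{view A's cluster means depend only on a label
#'     `xi_A` and view B's only on an independent label `xi_B`; the true
#'     clusters are the `k_a * k_b` product clusters, so neither view alone
#'     can recover them.}
#'   \item{`consensus`}{one shared label drives the means of both views
#'     (`k_a = k_b` clusters); the views are noisy copies of a single
#'     clustering structure.}
#'   \item{`mixed`}{four true clusters on a 2x2 design where one pair is
#'     separable only in view A (identical view-B means) and the other pair
#'     only in view B; complementary and consensus structure coexist.}
#'   \item{`ancillary`}{view A carries `k_a` clusters, view B is a single
#'     Gaussian blob with no cluster signal.}
#' }
#' Cluster means sit on a 1-D lattice in the view's feature space with
#' adjacent means `separation` apart, in units of the within-cluster
#' standard deviation (fixed at 1), so `separation` is directly the signal
#' strength.
#'
#' @param regime one of `"complementary"`, `"consensus"`, `"mixed"`,
#'   `"ancillary"`.
#' @param n number of items (cells).
#' @param k_a,k_b clusters per view (consensus uses `k_a` shared clusters;
#'   mixed is fixed to its 2x2 design).
#' @param separation distance between adjacent cluster means in within-
#'   cluster standard deviations; 0 yields pure noise in both views.
#' @param dims integer vector of length 2: feature dimensions per view.
#' @param seed integer seed; generation is deterministic given the seed.
#' @return object of class `cps_scenario`: list with `view_a`, `view_b`
#'   (numeric matrices), `truth` (overall true labels), `truth_a`,
#'   `truth_b` (per-view mean indices), and the scenario parameters.
#' @examples
#' sc <- simulate_views("complementary", n = 200, k_a = 2, k_b = 2,
#'                      separation = 8, seed = 1)
#' table(sc$truth)
#' @export
simulate_views <- function(regime = c("complementary", "consensus", "mixed",
                                      "ancillary"),
                           n = 1000L, k_a = 2L, k_b = 2L, separation = 6,
                           dims = c(2L, 2L), seed = 1L) {
  regime <- match.arg(regime)
  if (separation < 0) stop("separation must be nonnegative")
  stopifnot(n >= 1L, k_a >= 1L, k_b >= 1L, all(dims >= 1L))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  lattice <- function(idx, d) {
    # mean of cluster idx: (idx - 1) * separation along the first coordinate
    mu <- matrix(0, length(idx), d)
    mu[, 1L] <- (idx - 1L) * separation
    mu
  }
  if (regime == "complementary") {
    xi_a <- sample.int(k_a, n, replace = TRUE)
    xi_b <- sample.int(k_b, n, replace = TRUE)
    truth <- (xi_a - 1L) * k_b + xi_b
  } else if (regime == "consensus") {
    k_b <- k_a
    z <- sample.int(k_a, n, replace = TRUE)
    xi_a <- z; xi_b <- z; truth <- z
  } else if (regime == "mixed") {
    # 4 true clusters: {1,2} split only in view A, {3,4} only in view B
    truth <- sample.int(4L, n, replace = TRUE)
    xi_a <- c(1L, 2L, 3L, 3L)[truth]
    xi_b <- c(1L, 1L, 2L, 3L)[truth]
    k_a <- 3L; k_b <- 3L
  } else { # ancillary
    xi_a <- sample.int(k_a, n, replace = TRUE)
    xi_b <- rep(1L, n)
    truth <- xi_a
  }
  view_a <- lattice(xi_a, dims[1L]) +
    matrix(stats::rnorm(n * dims[1L]), n, dims[1L])
  view_b <- lattice(xi_b, dims[2L]) +
    matrix(stats::rnorm(n * dims[2L]), n, dims[2L])
  structure(
    list(view_a = view_a, view_b = view_b, truth = truth,
         truth_a = xi_a, truth_b = xi_b,
         regime = regime, n = n, k_a = k_a, k_b = k_b,
         separation = separation, dims = dims, seed = seed),
    class = "cps_scenario"
  )
}

#' @export
print.cps_scenario <- function(x, ...) {
  cat(sprintf("<cps_scenario> %s: n = %d, k_a = %d, k_b = %d, separation = %g\n",
              x$regime, x$n, x$k_a, x$k_b, x$separation))
  invisible(x)
}

pair_counts <- function(l1, l2) {
  if (length(l1) != length(l2)) stop("label vectors differ in length")
  ct <- contingency(partition(l1), partition(l2))
  n <- sum(ct)
  list(ct = ct, n = n,
       sum_ij = sum(choose(ct, 2)),
       sum_a = sum(choose(rowSums(ct), 2)),
       sum_b = sum(choose(colSums(ct), 2)),
       total = choose(n, 2))
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two labelings, corrected for chance:
#' `ARI = (RI - E[RI]) / (max RI - E[RI])`, computed from the contingency
#' table. Permutation-invariant; 1 for identical partitions, about 0 for
#' independent ones. Two single-cluster labelings are identical and score 1
#' (reported with a warning since the statistic is degenerate there).
#'
#' @param l1,l2 label vectors of equal length.
#' @return scalar ARI.
#' @export
ari <- function(l1, l2) {
  pc <- pair_counts(l1, l2)
  exp_idx <- pc$sum_a * pc$sum_b / pc$total
  max_idx <- (pc$sum_a + pc$sum_b) / 2
  if (abs(max_idx - exp_idx) < .Machine$double.eps) {
    warning("degenerate labelings (single cluster or all singletons); ARI defined as 1")
    return(1)
  }
  (pc$sum_ij - exp_idx) / (max_idx - exp_idx)
}

#' Normalized mutual information
#'
#' `NMI = I(L1; L2) / normalizer`, with the normalizer configurable as the
#' arithmetic mean (default), maximum, minimum, or geometric mean of the two
#' label entropies. Natural logarithms are used throughout (the ratio is
#' base-invariant). Identical degenerate labelings (zero entropy on both
#' sides) score 1.
#'
#' @param l1,l2 label vectors of equal length.
#' @param normalizer one of `"mean"`, `"max"`, `"min"`, `"sqrt"`.
#' @return value in `[0, 1]`.
#' @export
nmi <- function(l1, l2, normalizer = c("mean", "max", "min", "sqrt")) {
  normalizer <- match.arg(normalizer)
  ct <- contingency(partition(l1), partition(l2))
  n <- sum(ct)
  pij <- ct / n
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  h1 <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  h2 <- -sum(pj_[pj_ > 0] * log(pj_[pj_ > 0]))
  norm <- switch(normalizer,
                 mean = (h1 + h2) / 2,
                 max = max(h1, h2),
                 min = min(h1, h2),
                 sqrt = sqrt(h1 * h2))
  if (norm < .Machine$double.eps) {
    warning("zero-entropy labelings; NMI defined as 1")
    return(1)
  }
  max(0, min(1, mi / norm))
}

#' F-measure between a truth and a predicted labeling
#'
#' Default is the pair-counting definition: precision and recall of the
#' predicted co-clustered pairs against the true co-clustered pairs, and
#' `F = 2PR/(P + R)`. The `"bestmatch"` variant instead averages, over true
#' clusters (weighted by size), the best per-cluster F-score against any
#' predicted cluster.
#'
#' @param truth,pred label vectors of equal length (truth first).
#' @param method `"pair"` (default) or `"bestmatch"`.
#' @return value in `[0, 1]`.
#' @export
f_measure <- function(truth, pred, method = c("pair", "bestmatch")) {
  method <- match.arg(method)
  if (method == "pair") {
    pc <- pair_counts(truth, pred)
    if (pc$sum_a == 0 && pc$sum_b == 0) {
      warning("no co-clustered pairs in either labeling; F defined as 1")
      return(1)
    }
    if (pc$sum_a == 0 || pc$sum_b == 0) return(0)
    prec <- pc$sum_ij / pc$sum_b
    rec <- pc$sum_ij / pc$sum_a
    if (prec + rec == 0) return(0)
    2 * prec * rec / (prec + rec)
  } else {
    ct <- contingency(partition(truth), partition(pred))
    nt <- rowSums(ct)
    np <- colSums(ct)
    f_kj <- 2 * ct / outer(nt, np, "+")
    sum(nt / sum(nt) * apply(f_kj, 1L, max))
  }
}
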