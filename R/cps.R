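#' Matched replicate sets of a reference cluster
#'
#' For reference cluster `k`, scans every partition of the aligned ensemble
#' and collects the member set of the cluster that *matches* `k` (mutual
#' dominant mapping at threshold `zeta`, see [classify_relations()]). The
#' proportion of partitions contributing a matched set is `p_k = m_k / m`.
#'
#' @param k reference cluster index.
#' @param ens a `cps_ensemble` from [align_ensemble()].
#' @param zeta match threshold in `(0.5, 1]`.
#' @return list with `sets` (list of integer index vectors, possibly empty),
#'   `m_k`, and `p_k`.
#' @export
matched_sets <- function(k, ens, zeta = 0.7) {
  stopifnot(inherits(ens, "cps_ensemble"))
  sets <- list()
  for (p in seq_len(ens$m)) {
    i <- classify_relations(ens$alignments[[p]], zeta)$match[k]
    if (!is.na(i)) {
      sets[[length(sets) + 1L]] <- which(ens$raw[[p]]$labels == i)
    }
  }
  list(sets = sets, m_k = length(sets), p_k = length(sets) / ens$m)
}

#' Covering point set of a collection of replicate sets (greedy LIFT)
#'
#' The covering point set at level `alpha` is the smallest point set that
#' contains at least `100 (1 - alpha)%` of the replicate sets as subsets — a
#' set-valued analogue of a confidence region for a cluster. The minimal
#' such set is the union of the `ceiling(m_basis * (1 - alpha))` kept sets
#' for the best choice of sets to discard. Because the number of discarded
#' sets is small at practical coverage levels (about `alpha * m`), the
#' optimum is found by direct enumeration over removal choices whenever
#' `choose(m, drops)` is modest (up to 10000 combinations); for larger
#' ensembles a targeted-removal greedy repeatedly discards the set whose
#' exclusion shrinks the running union the most. In both cases every
#' surviving set is covered by construction.
#'
#' @param sets list of integer index vectors.
#' @param alpha coverage level in `[0, 1)`; `alpha = 0` covers every set.
#' @param m_basis denominator of the coverage constraint; defaults to
#'   `length(sets)`. Setting it to the full ensemble size `m` instead
#'   reproduces the stricter constraint that counts unmatched partitions
#'   against the coverage.
#' @return object of class `cps_cover`: list with `members` (sorted integer
#'   vector), `kept` (indices of surviving sets), `alpha`, `required`.
#' @export
covering_point_set <- function(sets, alpha = 0.1, m_basis = length(sets)) {
  if (alpha < 0 || alpha >= 1) stop("alpha must lie in [0, 1)")
  m <- length(sets)
  required <- as.integer(ceiling(m_basis * (1 - alpha)))
  if (required > m) {
    warning("required coverage exceeds the number of available sets; covering all")
    required <- m
  }
  if (required <= 0L) {
    warning("coverage level requires no set to be covered; returning the empty set")
    return(structure(list(members = integer(), kept = integer(),
                          alpha = alpha, required = 0L),
                     class = "cps_cover"))
  }
  sets <- lapply(sets, function(s) sort(unique(s)))
  keep <- seq_len(m)
  n_drop <- m - required
  if (n_drop > 0L && choose(m, n_drop) <= 10000) {
    combos <- utils::combn(m, required, simplify = FALSE)
    sizes <- vapply(combos, function(idx)
      length(unique(unlist(sets[idx], use.names = FALSE))), integer(1))
    keep <- combos[[which.min(sizes)]]   # ties -> first combo: deterministic
  } else while (length(keep) > required) {
    # a set's removal shrinks the running union by exactly its points of
    # multiplicity 1; targeted removal discards the set whose exclusion
    # shrinks the union the most, leaving the smallest cover
    pts <- unlist(sets[keep], use.names = FALSE)
    mult <- table(pts)
    unique_pts <- as.integer(names(mult)[mult == 1L])
    impact <- vapply(keep, function(i) sum(sets[[i]] %in% unique_pts), integer(1))
    drop <- keep[which.max(impact)]   # ties -> smallest index: deterministic
    keep <- setdiff(keep, drop)
  }
  members <- sort(unique(unlist(sets[keep], use.names = FALSE)))
  structure(list(members = members, kept = keep, alpha = alpha,
                 required = required),
            class = "cps_cover")
}

#' @export
print.cps_cover <- function(x, ...) {
  cat(sprintf("<cps_cover> |S_alpha| = %d covering %d sets (alpha = %g)\n",
              length(x$members), length(x$kept), x$alpha))
  invisible(x)
}

#' Tightness of a reference cluster
#'
#' `R_t(k) = p_k * mean_i |S_i| / |S_alpha|`, where the `S_i` are the
#' replicate sets matched with cluster `k` across the ensemble and `S_alpha`
#' is their covering point set. Tightness is 1 for a perfectly stable
#' cluster (every partition reproduces it exactly) and 0 for a cluster never
#' matched; with `alpha = 0` it is guaranteed to lie in `[0, 1]` because all
#' `S_i` are then subsets of `S_alpha`.
#'
#' @inheritParams matched_sets
#' @param alpha coverage level of the covering point set.
#' @return scalar tightness.
#' @export
tightness <- function(k, ens, alpha = 0.1, zeta = 0.7) {
  ms <- matched_sets(k, ens, zeta)
  tightness_from_sets(ms$sets, ms$p_k, alpha)
}

tightness_from_sets <- function(sets, p_k, alpha) {
  m_k <- length(sets)
  if (m_k == 0L) return(0)
  cover <- covering_point_set(sets, alpha, m_basis = m_k)
  size <- length(cover$members)
  if (size == 0L) {
    warning("empty covering point set with matched replicates; tightness set to 0")
    return(0)
  }
  p_k * mean(vapply(sets, function(s) length(unique(s)), integer(1)) / size)
}

#' Cluster Alignment and Points based (CAP) separability
#'
#' Jaccard distance between the covering point sets of two reference
#' clusters. Values near 0 flag clusters whose replicate sets overlap heavily
#' (confusable clusters, prime merge candidates); 1 means the covering sets
#' are disjoint.
#'
#' @param k1,k2 reference cluster indices.
#' @inheritParams tightness
#' @return value in `[0, 1]`; 0 for a cluster against itself.
#' @export
cap_separability <- function(k1, k2, ens, alpha = 0.1, zeta = 0.7) {
  s <- ensemble_stability(ens, alpha, zeta)
  jaccard_distance(s$cps[[k1]], s$cps[[k2]])
}

#' Per-cluster stability summary of an aligned ensemble
#'
#' One pass over an aligned ensemble producing, for every reference cluster:
#' the match proportion `p_k`, the matched replicate sets, the covering point
#' set, the tightness `R_t(k)`, and the pairwise CAP separability matrix.
#' Clusters never matched (`m_k = 0`) fall back to their own reference
#' members as a degenerate covering set so they still have a defined
#' separability to potential merge partners; their tightness stays 0.
#'
#' @param ens a `cps_ensemble`.
#' @param alpha coverage level.
#' @param zeta match threshold.
#' @return object of class `cps_stability`: list with `R_t` (vector),
#'   `p_k`, `m_k`, `cps` (list of integer vectors), `cps_size`,
#'   `delta` (`K x K` separability matrix), `mean_tightness`.
#' @export
ensemble_stability <- function(ens, alpha = 0.1, zeta = 0.7) {
  stopifnot(inherits(ens, "cps_ensemble"))
  K <- ens$reference$K
  members <- cluster_members(ens$reference)
  # one relation scan per partition, reused across clusters
  match_tab <- vapply(ens$alignments,
                      function(al) classify_relations(al, zeta)$match,
                      integer(K))
  match_tab <- matrix(match_tab, nrow = K)
  R_t <- numeric(K)
  p_k <- numeric(K)
  m_k <- integer(K)
  cps <- vector("list", K)
  for (k in seq_len(K)) {
    sets <- list()
    for (p in seq_len(ens$m)) {
      i <- match_tab[k, p]
      if (!is.na(i)) sets[[length(sets) + 1L]] <- which(ens$raw[[p]]$labels == i)
    }
    m_k[k] <- length(sets)
    p_k[k] <- m_k[k] / ens$m
    if (m_k[k] > 0L) {
      cover <- covering_point_set(sets, alpha, m_basis = m_k[k])
      cps[[k]] <- cover$members
      size <- length(cover$members)
      R_t[k] <- if (size == 0L) 0 else
        p_k[k] * mean(lengths(sets) / size)
    } else {
      cps[[k]] <- members[[k]]   # degenerate covering set for separability
      R_t[k] <- 0
    }
  }
  delta <- matrix(0, K, K)
  if (K >= 2L) for (i in seq_len(K - 1L)) for (j in seq(i + 1L, K)) {
    d <- jaccard_distance(cps[[i]], cps[[j]])
    delta[i, j] <- d
    delta[j, i] <- d
  }
  structure(
    list(R_t = R_t, p_k = p_k, m_k = m_k, cps = cps,
         cps_size = lengths(cps), delta = delta,
         mean_tightness = mean(R_t)),
    class = "cps_stability"
  )
}

#' @export
print.cps_stability <- function(x, ...) {
  cat(sprintf("<cps_stability> K = %d, mean tightness = %.3f\n",
              length(x$R_t), x$mean_tightness))
  print(data.frame(cluster = seq_along(x$R_t), p_k = x$p_k, m_k = x$m_k,
                   cps_size = x$cps_size, R_t = round(x$R_t, 4)))
  invisible(x)
}

#' Export a tightness report as a data frame
#'
#' @param s a `cps_stability` object.
#' @return data frame with one row per reference cluster.
#' @export
tightness_report <- function(s) {
  stopifnot(inherits(s, "cps_stability"))
  data.frame(cluster = seq_along(s$R_t), p_k = s$p_k, m_k = s$m_k,
             cps_size = s$cps_size, R_t = s$R_t)
}
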