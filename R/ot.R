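#' Exact solution of a balanced transportation problem
#'
#' Solves `min <W, cost>` subject to `rowSums(W) = supply`,
#' `colSums(W) = demand`, `W >= 0` with the transportation (network) simplex.
#' The solver returns an exact vertex of the transport polytope, which is what
#' the partition-alignment theory requires: when two partitions are
#' label-permuted copies of each other the optimal coupling is the scaled
#' permutation matrix, not a blurred approximation.
#'
#' Marginals are expected as nonnegative counts (integers); the optimum is
#' then integral and all pivoting arithmetic is exact in double precision.
#' Callers with probability marginals should scale by `n` and divide the plan
#' afterwards.
#'
#' @param cost numeric `r x c` cost matrix (finite).
#' @param supply,demand nonnegative numeric vectors with equal sums.
#' @return list with `plan` (`r x c` matrix) and `cost` (achieved objective).
#' @keywords internal
transport_simplex <- function(cost, supply, demand) {
  r <- length(supply)
  s <- length(demand)
  stopifnot(nrow(cost) == r, ncol(cost) == s)
  if (abs(sum(supply) - sum(demand)) > 1e-9 * max(1, sum(supply)))
    stop("unbalanced transportation problem")
  if (any(supply < 0) || any(demand < 0)) stop("negative marginals")

  # trivial shapes
  if (r == 1L) {
    plan <- matrix(demand, nrow = 1L)
    return(list(plan = plan, cost = sum(plan * cost)))
  }
  if (s == 1L) {
    plan <- matrix(supply, ncol = 1L)
    return(list(plan = plan, cost = sum(plan * cost)))
  }

  x <- matrix(0, r, s)          # current basic solution
  basis <- matrix(FALSE, r, s)  # spanning-tree basis indicator

  # --- northwest-corner initial basic feasible solution -------------------
  a <- supply
  b <- demand
  i <- 1L; j <- 1L
  while (TRUE) {
    amt <- min(a[i], b[j])
    x[i, j] <- amt
    basis[i, j] <- TRUE
    a[i] <- a[i] - amt
    b[j] <- b[j] - amt
    if (i == r && j == s) break
    # on simultaneous exhaustion move along the row unless it is the last
    # column (degenerate zero-allocation cells keep the basis a tree)
    if (a[i] <= 0 && i < r) i <- i + 1L else j <- j + 1L
  }

  n_nodes <- r + s
  max_iter <- 2000L * n_nodes

  for (iter in seq_len(max_iter)) {
    # --- dual variables from the basis tree (u[1] = 0) --------------------
    u <- rep(NA_real_, r)
    v <- rep(NA_real_, s)
    u[1] <- 0
    # BFS over the bipartite tree
    queue <- c(1L)            # node ids: 1..r rows, r+1..r+s cols
    visited_r <- c(TRUE, rep(FALSE, r - 1L))
    visited_c <- rep(FALSE, s)
    while (length(queue)) {
      node <- queue[[1L]]; queue <- queue[-1L]
      if (node <= r) {
        ii <- node
        for (jj in which(basis[ii, ] & !visited_c)) {
          v[jj] <- cost[ii, jj] - u[ii]
          visited_c[jj] <- TRUE
          queue <- c(queue, r + jj)
        }
      } else {
        jj <- node - r
        for (ii in which(basis[, jj] & !visited_r)) {
          u[ii] <- cost[ii, jj] - v[jj]
          visited_r[ii] <- TRUE
          queue <- c(queue, ii)
        }
      }
    }
    if (anyNA(u) || anyNA(v)) stop("internal error: basis is not a spanning tree")

    # --- reduced costs; pick entering cell --------------------------------
    red <- cost - outer(u, v, "+")
    red[basis] <- 0
    tol <- 1e-9 * max(1, max(abs(cost)))
    neg <- which(red < -tol)
    if (!length(neg)) break
    if (iter <= 500L * n_nodes) {
      enter <- neg[which.min(red[neg])]   # Dantzig: most negative
    } else {
      enter <- min(neg)                   # Bland fallback: anti-cycling
    }
    ei <- (enter - 1L) %% r + 1L
    ej <- (enter - 1L) %/% r + 1L

    # --- unique basis path from row ei to column ej -----------------------
    # BFS on the tree; parent pointers reconstruct the alternating path
    parent <- rep(NA_integer_, n_nodes)
    seen <- rep(FALSE, n_nodes)
    seen[ei] <- TRUE
    queue <- c(ei)
    target <- r + ej
    while (length(queue) && !seen[target]) {
      node <- queue[[1L]]; queue <- queue[-1L]
      if (node <= r) {
        nb <- r + which(basis[node, ])
      } else {
        nb <- which(basis[, node - r])
      }
      nb <- nb[!seen[nb]]
      seen[nb] <- TRUE
      parent[nb] <- node
      queue <- c(queue, nb)
    }
    if (!seen[target]) stop("internal error: entering cell closes no cycle")
    path <- target
    while (path[[1L]] != ei) path <- c(parent[path[[1L]]], path)

    # cycle cells: entering (+), then alternating -,+,-,... along the path
    L <- length(path) - 1L
    cyc_i <- integer(L); cyc_j <- integer(L); sign <- integer(L)
    for (t in seq_len(L)) {
      a_node <- path[t]; b_node <- path[t + 1L]
      if (a_node <= r) { cyc_i[t] <- a_node; cyc_j[t] <- b_node - r }
      else             { cyc_i[t] <- b_node; cyc_j[t] <- a_node - r }
      sign[t] <- if (t %% 2L == 1L) -1L else 1L
    }
    dec <- which(sign < 0L)
    amounts <- vapply(dec, function(t) x[cyc_i[t], cyc_j[t]], numeric(1))
    theta <- min(amounts)
    leave <- dec[which.min(amounts)]      # first minimizer: deterministic

    for (t in seq_len(L)) x[cyc_i[t], cyc_j[t]] <- x[cyc_i[t], cyc_j[t]] + sign[t] * theta
    x[ei, ej] <- x[ei, ej] + theta
    basis[cyc_i[leave], cyc_j[leave]] <- FALSE
    basis[ei, ej] <- TRUE
  }

  list(plan = x, cost = sum(x * cost))
}

#' Align one partition with a reference by optimal transport
#'
#' Computes the cluster aligning matrix `W` between the clusters of `p` and
#' those of `ref` by solving the transportation problem with cluster
#' proportions as marginals and pairwise Jaccard distances between cluster
#' member sets as ground costs. The minimized objective is the Wasserstein
#' distance `D` between the two partitions. Row-normalizing `W` by the source
#' proportions gives the cluster mapping matrix `Gamma` (how each source
#' cluster distributes over reference clusters); column-normalizing by the
#' reference proportions gives `Gamma_tilde` (how each reference cluster is
#' composed of source clusters).
#'
#' @param p source [partition()].
#' @param ref reference [partition()] over the same items.
#' @return object of class `cps_alignment`: list with `W` (`K_p x K_ref`
#'   coupling, entries sum to 1), `gamma` (row-stochastic), `gamma_tilde`
#'   (column-stochastic), `D` (transport cost in `[0, 1]`), and the marginals
#'   `q_src`, `q_ref`.
#' @examples
#' ref <- partition(c(1, 1, 2, 2))
#' prm <- partition(c(2, 2, 1, 1))   # same partition, permuted labels
#' al <- solve_ot_alignment(prm, ref)
#' al$D          # 0: the permutation is recovered exactly
#' @export
solve_ot_alignment <- function(p, ref) {
  stopifnot(is_partition(p), is_partition(ref))
  if (p$n != ref$n) stop("partitions cover different numbers of items")
  cost <- jaccard_cost_matrix(p, ref)
  sol <- transport_simplex(cost, p$sizes, ref$sizes)
  W <- sol$plan / p$n
  structure(
    list(
      W = W,
      gamma = W / p$q,                       # rows scaled by q_src
      gamma_tilde = sweep(W, 2L, ref$q, "/"),
      D = sol$cost / p$n,
      q_src = p$q,
      q_ref = ref$q
    ),
    class = "cps_alignment"
  )
}

#' @export
print.cps_alignment <- function(x, ...) {
  cat(sprintf("<cps_alignment> %d x %d clusters, D = %.4f\n",
              nrow(x$W), ncol(x$W), x$D))
  invisible(x)
}

#' Relabel a partition into the reference label space (MAP rule)
#'
#' Each item keeps the posterior row of its source cluster in `Gamma` and is
#' assigned the reference label with maximal posterior mass; for hard source
#' partitions this is `argmax_j gamma[a_h, j]`. Ties are broken toward the
#' smallest reference label.
#'
#' @param p source [partition()].
#' @param align result of [solve_ot_alignment()] for `p` against the target
#'   reference.
#' @return [partition()] whose labels live in the reference label space.
#'   Reference labels that receive no item are dropped by compaction, so the
#'   returned `K` can be smaller than the reference's; `label_map` records the
#'   reference labels retained.
#' @export
map_relabel <- function(p, align) {
  stopifnot(is_partition(p), inherits(align, "cps_alignment"))
  map <- apply(align$gamma, 1L, which.max)  # ties -> smallest index
  partition(map[p$labels])
}

#' Classify topological relations between source and reference clusters
#'
#' Clusters `C_i` (source) and `C_j` (reference) *match* when
#' `gamma[i, j] >= zeta` and `gamma_tilde[i, j] >= zeta`, with the relaxation
#' threshold `zeta` in `(0.5, 1]` — both clusters map dominantly onto each
#' other, so they are the same cluster up to labeling. Because rows of
#' `gamma` and columns of `gamma_tilde` each sum to 1, `zeta > 0.5` makes the
#' match partner unique on both sides. Remaining pairs are classified for
#' diagnostics only: a source cluster spreading over several reference
#' clusters (`gamma_tilde[i, j] >= 1 - zeta` for two or more `j`) is a
#' *split*; the symmetric situation a *merge*; a reference cluster with no
#' match in this partition has *lack of correspondence*. Only the match /
#' no-match distinction feeds the downstream stability computations.
#'
#' @param align a `cps_alignment`.
#' @param zeta relaxation threshold in `(0.5, 1]`.
#' @return list with `match` (integer vector over reference clusters: index
#'   of the matching source cluster or `NA`), and `relations`, a data frame
#'   (`source`, `reference`, `relation`).
#' @export
classify_relations <- function(align, zeta = 0.7) {
  stopifnot(inherits(align, "cps_alignment"))
  if (zeta <= 0.5 || zeta > 1) stop("zeta must lie in (0.5, 1]")
  g <- align$gamma
  gt <- align$gamma_tilde
  k1 <- nrow(g); kr <- ncol(g)
  is_match <- g >= zeta & gt >= zeta
  match_of_ref <- rep(NA_integer_, kr)
  rel <- vector("list", 0L)
  for (j in seq_len(kr)) {
    i <- which(is_match[, j])
    if (length(i)) match_of_ref[j] <- i[[1L]]
  }
  rows <- list()
  for (i in seq_len(k1)) for (j in seq_len(kr)) {
    r <- if (is_match[i, j]) "match"
    else if (sum(gt[i, ] >= 1 - zeta) >= 2 && !any(is_match[i, ])) "split"
    else if (sum(g[, j] >= 1 - zeta) >= 2 && is.na(match_of_ref[j])) "merge"
    else if (is.na(match_of_ref[j])) "lack-of-correspondence"
    else NA_character_
    if (!is.na(r)) rows[[length(rows) + 1L]] <- data.frame(
      source = i, reference = j, relation = r)
  }
  relations <- if (length(rows)) do.call(rbind, rows)
  else data.frame(source = integer(), reference = integer(),
                  relation = character())
  list(match = match_of_ref, relations = relations, zeta = zeta)
}

#' Align an ensemble of partitions to a common reference
#'
#' Runs [solve_ot_alignment()] and [map_relabel()] for each partition against
#' the reference, yielding a collection of clustering results with consistent
#' cluster labels.
#'
#' @param parts list of raw [partition()]s.
#' @param ref reference [partition()].
#' @return object of class `cps_ensemble`: list with `reference`, `raw`
#'   (the input partitions), `aligned` (relabeled partitions), and
#'   `alignments` (one `cps_alignment` per partition).
#' @export
align_ensemble <- function(parts, ref) {
  stopifnot(is_partition(ref), is.list(parts))
  alignments <- vector("list", length(parts))
  aligned <- vector("list", length(parts))
  for (p in seq_along(parts)) {
    if (parts[[p]]$n != ref$n)
      stop(sprintf("partition %d covers %d items but the reference covers %d",
                   p, parts[[p]]$n, ref$n))
    al <- solve_ot_alignment(parts[[p]], ref)
    alignments[[p]] <- al
    aligned[[p]] <- map_relabel(parts[[p]], al)
  }
  structure(
    list(reference = ref, raw = parts, aligned = aligned,
         alignments = alignments, m = length(parts)),
    class = "cps_ensemble"
  )
}

#' @export
print.cps_ensemble <- function(x, ...) {
  cat(sprintf("<cps_ensemble> m = %d partitions aligned to a %d-cluster reference (n = %d)\n",
              x$m, x$reference$K, x$reference$n))
  invisible(x)
}
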