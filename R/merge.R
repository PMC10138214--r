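# Recover the original (uncompacted) label values of a partition.
raw_labels <- function(p) {
  v <- suppressWarnings(as.integer(p$label_map))
  if (anyNA(v)) stop("partition labels are not integer-coded")
  v[p$labels]
}

#' Matching weight matrix between two view ensembles
#'
#' For each of the `m` paired partitions, computes the OT cluster aligning
#' matrix between the view-A and view-B partitions of the pair, scatters it
#' into the full `kappa_A x kappa_B` label grid, and averages over pairs:
#' `W_bar = sum_p W^(p) / m`. `W_bar[i, j]` measures how persistently view-A
#' cluster `i` and view-B cluster `j` claim the same points across the
#' perturbed replicates; it is the edge weight of the bipartite graph used
#' for super-clustering.
#'
#' @param ea,eb aligned `cps_ensemble` objects of the two views.
#' @return `kappa_A x kappa_B` nonnegative matrix whose entries sum to 1.
#' @export
matching_weight_matrix <- function(ea, eb) {
  stopifnot(inherits(ea, "cps_ensemble"), inherits(eb, "cps_ensemble"))
  if (ea$m != eb$m) stop("ensembles have different numbers of partitions")
  ka <- ea$reference$K
  kb <- eb$reference$K
  acc <- matrix(0, ka, kb)
  for (p in seq_len(ea$m)) {
    pa <- ea$aligned[[p]]
    pb <- eb$aligned[[p]]
    al <- solve_ot_alignment(pa, pb)
    ia <- as.integer(pa$label_map)   # which reference labels survive in p
    ib <- as.integer(pb$label_map)
    acc[ia, ib] <- acc[ia, ib] + al$W
  }
  acc / ea$m
}

#' Bipartite Leiden super-clustering of view clusters
#'
#' Builds the bipartite graph whose two node sets are the view-A and view-B
#' reference clusters, with edge weights from the matching weight matrix,
#' and runs Leiden community detection (modularity objective). Each
#' community is a *super-cluster* grouping clusters whose cross-view
#' correspondence is sharp.
#'
#' @param wbar matching weight matrix from [matching_weight_matrix()].
#' @param resolution Leiden resolution parameter.
#' @param seed seed for the Leiden refinement.
#' @return list with `comm_a`, `comm_b` (integer community ids for the
#'   view-A and view-B clusters) and `n_super` (number of super-clusters).
#' @export
bipartite_super_clusters <- function(wbar, resolution = 1.0, seed = 1L) {
  ka <- nrow(wbar); kb <- ncol(wbar)
  if (any(wbar < 0)) stop("matching weights must be nonnegative")
  idx <- which(wbar > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    warning("all matching weights are zero; every cluster is its own super-cluster")
    return(list(comm_a = seq_len(ka), comm_b = ka + seq_len(kb),
                n_super = ka + kb))
  }
  g <- igraph::make_empty_graph(ka + kb, directed = FALSE)
  g <- igraph::add_edges(g, rbind(idx[, 1L], ka + idx[, 2L]))
  igraph::E(g)$weight <- wbar[idx]
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 weights = igraph::E(g)$weight,
                                 resolution = resolution, n_iterations = 5L)
  mem <- as.integer(igraph::membership(comm))
  list(comm_a = mem[seq_len(ka)], comm_b = mem[ka + seq_len(kb)],
       n_super = length(unique(mem)))
}

#' First-stage merge map over product labels
#'
#' Builds the mapping `g0` from occupied product labels to first-stage
#' cluster ids. A product label `(xi_A, xi_B)` whose two view clusters fall
#' in the same super-cluster belongs to a *matched product* (MP) block and
#' keeps its own id (product granularity is preserved where cross-view
#' agreement is sharp); labels whose view clusters fall in different
#' super-clusters `(S_i, S_j)`, `i != j`, belong to an *unmatched product*
#' (UP) block and are merged wholesale into a single id per ordered block.
#'
#' @param pe a `cps_product` (after [clean_rare_labels()]).
#' @param super result of [bipartite_super_clusters()], or `NULL` for the
#'   identity map (first stage skipped).
#' @return integer vector `g0` over codebook codes (dense ids `1..kappa_0`),
#'   with attribute `block` labeling each code `"MP"` or `"UP"`.
#' @export
first_stage_map <- function(pe, super = NULL) {
  stopifnot(inherits(pe, "cps_product"))
  cb <- pe$codebook
  occupied <- sort(unique(c(pe$reference_codes, unlist(pe$pair_codes))))
  key <- rep(NA_character_, nrow(cb))
  block <- rep(NA_character_, nrow(cb))
  for (code in occupied) {
    if (is.null(super)) {
      key[code] <- paste0("MP:", code)
      block[code] <- "MP"
    } else {
      sa <- super$comm_a[cb$xi_a[code]]
      sb <- super$comm_b[cb$xi_b[code]]
      if (sa == sb) {
        key[code] <- paste0("MP:", code)
        block[code] <- "MP"
      } else {
        key[code] <- paste0("UP:", sa, ":", sb)
        block[code] <- "UP"
      }
    }
  }
  g0 <- match(key, sort(unique(key[occupied])))
  attr(g0, "block") <- block
  g0
}

#' Apply the first-stage map and align the combined ensemble
#'
#' Collapses the reference product partition through `g0` into the combined
#' reference partition `C` (`kappa_0` clusters), collapses every paired
#' product partition likewise, and OT-aligns each to `C`, producing the
#' combined ensemble that the second-stage merging operates on.
#'
#' @param pe a `cps_product`.
#' @param g0 map from [first_stage_map()].
#' @return a `cps_ensemble` whose reference is `C`.
#' @export
first_stage_merge <- function(pe, g0) {
  stopifnot(inherits(pe, "cps_product"))
  C <- partition(g0[pe$reference_codes])
  parts <- lapply(pe$pair_codes, function(cc) partition(g0[cc]))
  align_ensemble(parts, C)
}

# ---------------------------------------------------------------------------
# Second-stage merging

stability_of_labels <- function(ref_lab, parts_lab, alpha, zeta) {
  ref_part <- partition(ref_lab)
  ens <- align_ensemble(lapply(parts_lab, partition), ref_part)
  list(ref = ref_part, ens = ens,
       st = ensemble_stability(ens, alpha, zeta))
}

collapse_labels <- function(lab, from, to) {
  lab[lab %in% from] <- to
  lab
}

# shared stop test; kappa1 (if given) is the hard stop, otherwise merging
# continues until every cluster reaches the tightness goal — the point at
# which the threshold-ladder scheme converges at its top threshold
merge_done <- function(K, R_t, kappa1, tightness_goal) {
  if (!is.null(kappa1)) K <= kappa1 else all(R_t >= tightness_goal)
}

#' Greedy CPS merging of the combined clusters
#'
#' Maximizes the summed per-cluster tightness by recursive pairwise merging:
#' at each step the most unstable cluster (lowest tightness, ties toward the
#' smallest id) is merged with its closest cluster under CAP separability
#' (ties toward the larger partner, then the smaller id). After every merge
#' the reference and all combined partitions are collapsed through the merge
#' map and tightness/separability are recomputed from scratch. Merging stops
#' when `kappa1` clusters remain (if given) or, otherwise, when every
#' cluster's tightness reaches `tightness_goal` — the same convergence point
#' at which the accelerated threshold ladder terminates.
#'
#' @param ens combined `cps_ensemble` from [first_stage_merge()].
#' @param alpha,zeta CPS analysis parameters.
#' @param kappa1 target number of final clusters, or `NULL`.
#' @param tightness_goal mean-tightness stop (default 0.8) used when
#'   `kappa1` is `NULL`.
#' @return object of class `cps_merge_tree`: list with `final`
#'   (final [partition()] `F`), `g1` (map from initial combined labels to
#'   final labels), `events` (list of merge events with the triggering
#'   tightness and separability), `stability` (final `cps_stability`),
#'   `trajectory` (data frame of `K` and mean tightness per step).
#' @export
cps_merge <- function(ens, alpha = 0.1, zeta = 0.7, kappa1 = NULL,
                      tightness_goal = 0.8) {
  stopifnot(inherits(ens, "cps_ensemble"))
  if (!is.null(kappa1) && kappa1 > ens$reference$K)
    stop("kappa1 exceeds the number of clusters before merging")
  # work in the compacted label space of the combined reference; aligned
  # partitions carry exactly these ids after MAP relabeling
  ref_lab <- ens$reference$labels
  parts_lab <- lapply(ens$aligned, raw_labels)
  init_lab <- ref_lab
  events <- list()
  traj <- list()
  repeat {
    s <- stability_of_labels(ref_lab, parts_lab, alpha, zeta)
    K <- s$ref$K
    traj[[length(traj) + 1L]] <- data.frame(K = K,
                                            mean_tightness = s$st$mean_tightness)
    if (merge_done(K, s$st$R_t, kappa1, tightness_goal)) break
    if (K == 1L) {
      warning("merging reached a single cluster before the stop condition")
      break
    }
    i <- order(s$st$R_t, seq_len(K))[1L]
    cand <- setdiff(seq_len(K), i)
    j <- cand[order(s$st$delta[i, cand], -s$ref$sizes[cand], cand)][1L]
    li <- as.integer(s$ref$label_map)[i]
    lj <- as.integer(s$ref$label_map)[j]
    target <- min(li, lj)
    events[[length(events) + 1L]] <- list(
      children = c(li, lj), parent = target,
      child_tightness = s$st$R_t[i], separability = s$st$delta[i, j],
      mean_tightness_before = s$st$mean_tightness, K_before = K)
    ref_lab <- collapse_labels(ref_lab, c(li, lj), target)
    parts_lab <- lapply(parts_lab, collapse_labels, from = c(li, lj),
                        to = target)
  }
  finish_merge(init_lab, ref_lab, parts_lab, events, traj, alpha, zeta)
}

#' Accelerated CPS merging with a tightness-threshold ladder
#'
#' Processes an ascending ladder of tightness thresholds (default 0.35,
#' 0.5, 0.65, 0.8). Under each threshold, every cluster whose tightness
#' falls below it is merged with its closest cluster (CAP separability) in a
#' single round without intermediate updates; chained assignments within a
#' round are collapsed together through union-find. Rounds repeat under the
#' same threshold until no cluster falls below it, then the threshold
#' advances. The same stop rules as [cps_merge()] apply; if a cluster-count
#' target remains unmet when the ladder is exhausted, merging continues with
#' the exact greedy scheme.
#'
#' @inheritParams cps_merge
#' @param thresholds strictly increasing tightness thresholds in `(0, 1]`.
#' @return a `cps_merge_tree` (see [cps_merge()]); round events carry the
#'   threshold that triggered them.
#' @export
accelerated_cps_merge <- function(ens, alpha = 0.1, zeta = 0.7,
                                  kappa1 = NULL, tightness_goal = 0.8,
                                  thresholds = c(0.35, 0.5, 0.65, 0.8)) {
  stopifnot(inherits(ens, "cps_ensemble"))
  if (any(diff(thresholds) <= 0) || any(thresholds <= 0) || any(thresholds > 1))
    stop("thresholds must be strictly increasing in (0, 1]")
  if (!is.null(kappa1) && kappa1 > ens$reference$K)
    stop("kappa1 exceeds the number of clusters before merging")
  ref_lab <- ens$reference$labels
  parts_lab <- lapply(ens$aligned, raw_labels)
  init_lab <- ref_lab
  events <- list()
  traj <- list()
  done <- FALSE
  for (thr in thresholds) {
    if (done) break
    repeat {
      s <- stability_of_labels(ref_lab, parts_lab, alpha, zeta)
      K <- s$ref$K
      traj[[length(traj) + 1L]] <- data.frame(K = K,
                                              mean_tightness = s$st$mean_tightness)
      if (merge_done(K, s$st$R_t, kappa1, tightness_goal)) {
        done <- TRUE; break
      }
      below <- which(s$st$R_t < thr)
      if (!length(below) || K == 1L) break
      labels_of <- as.integer(s$ref$label_map)
      # union-find over label values; chained merges collapse together
      parent <- stats::setNames(labels_of, labels_of)
      find <- function(x) {
        while (parent[[as.character(x)]] != x) x <- parent[[as.character(x)]]
        x
      }
      count <- K
      merged_pairs <- list()
      for (i in below) {               # ascending cluster id
        if (!is.null(kappa1) && count <= kappa1) break
        cand <- setdiff(seq_len(K), i)
        j <- cand[order(s$st$delta[i, cand], -s$ref$sizes[cand], cand)][1L]
        ri <- find(labels_of[i]); rj <- find(labels_of[j])
        if (ri == rj) next
        target <- min(ri, rj)
        parent[[as.character(max(ri, rj))]] <- target
        count <- count - 1L
        merged_pairs[[length(merged_pairs) + 1L]] <- list(
          children = c(labels_of[i], labels_of[j]), parent = target,
          child_tightness = s$st$R_t[i], separability = s$st$delta[i, j])
      }
      if (!length(merged_pairs)) break
      root_of <- vapply(labels_of, find, numeric(1))
      new_lab <- root_of[match(ref_lab, labels_of)]
      ref_lab <- as.integer(new_lab)
      parts_lab <- lapply(parts_lab, function(x)
        as.integer(root_of[match(x, labels_of)]))
      events[[length(events) + 1L]] <- list(
        threshold = thr, merges = merged_pairs,
        mean_tightness_before = s$st$mean_tightness, K_before = K)
    }
  }
  if (!done && !is.null(kappa1) && length(unique(ref_lab)) > kappa1) {
    # ladder exhausted above the target count: finish with the exact scheme
    tmp_ref <- partition(ref_lab)
    tmp_ens <- align_ensemble(lapply(parts_lab, partition), tmp_ref)
    res <- cps_merge(tmp_ens, alpha, zeta, kappa1, tightness_goal)
    # translate the inner (re-compacted) label space back to this one
    map_back <- as.integer(tmp_ref$label_map)
    inner_events <- lapply(res$events, function(ev) {
      ev$children <- map_back[ev$children]
      ev$parent <- map_back[ev$parent]
      ev
    })
    events <- c(events, inner_events)
    traj <- c(traj, list(res$trajectory))
    final <- partition(map_back[raw_labels(res$final)])
    init_vals <- sort(unique(init_lab))
    g1 <- final$labels[match(init_vals, init_lab)]
    names(g1) <- init_vals
    return(structure(
      list(final = final, g1 = g1, events = events,
           stability = res$stability, ensemble = res$ensemble,
           trajectory = do.call(rbind, traj)),
      class = "cps_merge_tree"))
  }
  finish_merge(init_lab, ref_lab, parts_lab, events, traj, alpha, zeta)
}

finish_merge <- function(init_lab, ref_lab, parts_lab, events, traj,
                         alpha, zeta) {
  final <- partition(ref_lab)
  s <- stability_of_labels(ref_lab, parts_lab, alpha, zeta)
  # g1: initial combined label -> final compacted label
  init_vals <- sort(unique(init_lab))
  g1 <- final$labels[match(init_vals, init_lab)]
  names(g1) <- init_vals
  structure(
    list(final = final, g1 = g1, events = events,
         stability = s$st, ensemble = s$ens,
         trajectory = do.call(rbind, traj)),
    class = "cps_merge_tree"
  )
}

#' @export
print.cps_merge_tree <- function(x, ...) {
  cat(sprintf("<cps_merge_tree> %d merge event(s); final K = %d, mean tightness = %.3f\n",
              length(x$events), x$final$K, x$stability$mean_tightness))
  invisible(x)
}

#' Newick string of a merge tree
#'
#' Renders the recorded merge events as a Newick tree over the initial
#' combined cluster ids (leaves `c<id>`), for dendrogram viewers. Rounds of
#' the accelerated scheme may produce multifurcating nodes; clusters never
#' merged remain children of the root.
#'
#' @param tree a `cps_merge_tree`.
#' @return single Newick string, semicolon-terminated.
#' @export
merge_tree_newick <- function(tree) {
  stopifnot(inherits(tree, "cps_merge_tree"))
  flat <- list()
  for (ev in tree$events) {
    if (!is.null(ev$merges)) flat <- c(flat, ev$merges) else
      flat[[length(flat) + 1L]] <- ev
  }
  leaves <- sort(unique(c(as.integer(names(tree$g1)),
                          unlist(lapply(flat, `[[`, "children")))))
  sub <- stats::setNames(paste0("c", leaves), leaves)
  for (ev in flat) {
    ch <- as.character(ev$children)
    pa <- as.character(ev$parent)
    pieces <- unique(sub[ch])
    sub[pa] <- paste0("(", paste(pieces, collapse = ","), ")")
    sub <- sub[!names(sub) %in% setdiff(ch, pa)]
  }
  if (length(sub) > 1L) paste0("(", paste(sub, collapse = ","), ");")
  else paste0(sub[[1L]], ";")
}
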