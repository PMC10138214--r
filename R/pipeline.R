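#' Merge two aligned view ensembles into a final clustering
#'
#' Core late-integration stage, operating purely on cluster labels: forms
#' the product ensemble, cleans rare product labels, optionally performs the
#' bipartite first-stage merge (when the number of occupied product clusters
#' exceeds `first_stage_threshold`), and runs the second-stage CPS merging.
#'
#' @param ea,eb aligned `cps_ensemble` objects of the two views (e.g. from
#'   [build_ensemble()] or [align_ensemble()] on user label tables).
#' @param alpha CPS coverage level (default 0.1).
#' @param zeta match relaxation threshold in `(0.5, 1]`.
#' @param kappa1 required number of final clusters, or `NULL` to stop at the
#'   mean tightness goal.
#' @param tightness_goal mean-tightness stop (default 0.8).
#' @param merge_mode `"full"` (exact greedy) or `"accelerated"` (threshold
#'   ladder).
#' @param thresholds tightness ladder for the accelerated scheme.
#' @param first_stage_threshold product-cluster count above which the
#'   bipartite first stage is applied (default 100).
#' @param leiden_resolution resolution of the bipartite Leiden clustering.
#' @param seed seed for the Leiden refinement.
#' @return object of class `cps_merge_result`: list with `final` (the final
#'   [partition()] `F`), `tree` (`cps_merge_tree`), `stability`, `product`
#'   (the cleaned `cps_product`), `g0`, `wbar` (or `NULL` when the first
#'   stage is skipped), `contributions` (a `cps_contribution`), and the
#'   parameters used.
#' @export
merge_views <- function(ea, eb, alpha = 0.1, zeta = 0.7, kappa1 = NULL,
                        tightness_goal = 0.8,
                        merge_mode = c("full", "accelerated"),
                        thresholds = c(0.35, 0.5, 0.65, 0.8),
                        first_stage_threshold = 100L,
                        leiden_resolution = 1.0, seed = 1L) {
  merge_mode <- match.arg(merge_mode)
  pe <- pair_ensembles(ea, eb)
  pe <- clean_rare_labels(pe)
  n_product <- length(unique(c(pe$reference_codes, unlist(pe$pair_codes))))
  use_first_stage <- n_product > first_stage_threshold
  wbar <- NULL
  super <- NULL
  if (use_first_stage) {
    wbar <- matching_weight_matrix(ea, eb)
    super <- bipartite_super_clusters(wbar, resolution = leiden_resolution,
                                      seed = seed)
  }
  g0 <- first_stage_map(pe, super)
  combined <- first_stage_merge(pe, g0)
  tree <- if (merge_mode == "full")
    cps_merge(combined, alpha, zeta, kappa1, tightness_goal)
  else
    accelerated_cps_merge(combined, alpha, zeta, kappa1, tightness_goal,
                          thresholds)
  contrib <- view_contributions(tree$final, list(ea$raw, eb$raw),
                                alpha = alpha, zeta = zeta)
  structure(
    list(final = tree$final, tree = tree, stability = tree$stability,
         product = pe, g0 = g0, wbar = wbar,
         contributions = contrib,
         params = list(alpha = alpha, zeta = zeta, kappa1 = kappa1,
                       tightness_goal = tightness_goal,
                       merge_mode = merge_mode, thresholds = thresholds,
                       first_stage_threshold = first_stage_threshold,
                       first_stage_used = use_first_stage,
                       leiden_resolution = leiden_resolution, seed = seed)),
    class = "cps_merge_result"
  )
}

#' @export
print.cps_merge_result <- function(x, ...) {
  cat(sprintf("<cps_merge_result> final K = %d, mean tightness = %.3f, contribution measure: %s\n",
              x$final$K, x$stability$mean_tightness,
              x$contributions$selected))
  invisible(x)
}

#' Run the full two-view clustering pipeline on feature matrices
#'
#' Convenience wrapper executing every stage: per-view ensemble generation
#' by noise perturbation, OT alignment to the view references, Cartesian
#' product, rare-label cleaning, optional first-stage bipartite merging,
#' second-stage CPS merging, and view-contribution scoring.
#'
#' @param view_a,view_b numeric matrices (items in rows) for the two views.
#' @param clusterer_a,clusterer_b clusterer functions `(X, seed) -> labels`,
#'   e.g. [clusterer_kmeans()].
#' @param m number of perturbed partitions per view.
#' @param noise_fraction noise variance as a fraction of the average
#'   within-cluster variance (default 0.1).
#' @param perturb_a,perturb_b whether to perturb each view's data; set a
#'   dominant view to `FALSE` to re-run its clusterer on clean data instead.
#' @param seed master seed; all stage seeds are derived from it.
#' @inheritParams merge_views
#' @param ... passed on to [merge_views()].
#' @return a `cps_merge_result` with the two view ensembles attached as
#'   `ensembles`.
#' @examples
#' \donttest{
#' sc <- simulate_views("complementary", n = 300, separation = 8, seed = 7)
#' res <- run_pipeline(sc$view_a, sc$view_b,
#'                     clusterer_kmeans(2), clusterer_kmeans(2),
#'                     m = 8, seed = 7)
#' ari(res$final$labels, sc$truth)
#' }
#' @export
run_pipeline <- function(view_a, view_b,
                         clusterer_a = clusterer_kmeans(2L),
                         clusterer_b = clusterer_kmeans(2L),
                         m = 20L, noise_fraction = 0.1,
                         perturb_a = TRUE, perturb_b = TRUE,
                         seed = 1L, ...) {
  if (nrow(as.matrix(view_a)) != nrow(as.matrix(view_b)))
    stop("views cover different numbers of items")
  ea <- build_ensemble(view_a, clusterer_a, m = m,
                       noise_fraction = noise_fraction, seed = seed,
                       perturb_view = perturb_a, view = "view A")
  eb <- build_ensemble(view_b, clusterer_b, m = m,
                       noise_fraction = noise_fraction, seed = seed + 100003L,
                       perturb_view = perturb_b, view = "view B")
  res <- merge_views(ea, eb, seed = seed, ...)
  res$ensembles <- list(a = ea, b = eb)
  res
}

#' Run the pipeline on precomputed label ensembles (labels-only mode)
#'
#' Late-integration entry point requiring no feature data: the caller
#' supplies, for each view, the reference labeling plus `m` replicate
#' labelings obtained by their own clustering pipeline on perturbed or
#' resampled data. Replicates are OT-aligned to the view references here;
#' they must not be pre-aligned.
#'
#' @param labels_a,labels_b for each view, a list whose first element is the
#'   reference label vector and whose remaining elements are the `m`
#'   replicate label vectors (or an `n x (m+1)` data frame / matrix with the
#'   reference in column 1).
#' @inheritParams merge_views
#' @param ... passed on to [merge_views()].
#' @return a `cps_merge_result`.
#' @export
run_pipeline_labels <- function(labels_a, labels_b, ...) {
  as_parts <- function(x) {
    if (is.data.frame(x) || is.matrix(x)) x <- as.list(as.data.frame(x))
    lapply(x, partition)
  }
  pa <- as_parts(labels_a)
  pb <- as_parts(labels_b)
  if (length(pa) < 2L || length(pb) < 2L)
    stop("each view needs a reference labeling plus at least one replicate")
  if (length(pa) != length(pb))
    stop("the two views supply different numbers of labelings")
  ea <- align_ensemble(pa[-1L], pa[[1L]])
  eb <- align_ensemble(pb[-1L], pb[[1L]])
  merge_views(ea, eb, ...)
}
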