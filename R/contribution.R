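#' Tightness-based contribution of each view to the final clusters
#'
#' Treats the final partition `F` as the reference and the *raw* (never
#' aligned to any single-view reference) perturbed partitions of each view
#' as its replicates: if a final cluster is reproduced stably by the
#' replicates of one view but not the other, the former view drove its
#' formation. With `R_t(k, l)` the tightness of final cluster `k` computed
#' from view `l`'s replicates, the contribution is
#' `zeta[k, l] = R_t(k, l) / sum_l' R_t(k, l')`, with the convention
#' `zeta[k, l] = 0.5` when the denominator is 0 (two views).
#'
#' @param final final [partition()] `F`.
#' @param raw_views list (one element per view) of lists of raw
#'   [partition()]s.
#' @param alpha,zeta CPS analysis parameters.
#' @return list with `zeta` (`kappa_1 x n_views` matrix, rows summing to 1),
#'   `R_t` (same shape, the per-view tightness values).
#' @export
tightness_contribution <- function(final, raw_views, alpha = 0.1,
                                   zeta = 0.7) {
  stopifnot(is_partition(final), is.list(raw_views))
  nv <- length(raw_views)
  Rt <- vapply(raw_views, function(parts) {
    ens <- align_ensemble(parts, final)
    ensemble_stability(ens, alpha, zeta)$R_t
  }, numeric(final$K))
  Rt <- matrix(Rt, nrow = final$K, ncol = nv)
  tot <- rowSums(Rt)
  zmat <- Rt / ifelse(tot > 0, tot, 1)
  zmat[tot == 0, ] <- 1 / nv
  list(zeta = zmat, R_t = Rt)
}

#' Matching-weight-based contribution of each view
#'
#' For each view `l` and raw partition `p`, the OT coupling `W_l^(p)`
#' between that partition and the final partition `F` is computed; the
#' cluster aligning vector `V_l^(p) = colSums(W_l^(p)) / kappa_{p,l}`
#' measures how much matching mass each final cluster receives, discounted
#' by how many clusters the partition offers. Averaging over partitions
#' gives the matching weight vector `v[, l]`, and the contribution is
#' `eta[k, l] = v[k, l] / sum_l' v[k, l']` with the 0.5 fallback on a zero
#' denominator. Unlike the tightness-based score this remains informative
#' when no single-view cluster corresponds well with a final cluster (pure
#' interaction effects).
#'
#' @inheritParams tightness_contribution
#' @return list with `eta` (`kappa_1 x n_views` matrix, rows summing to 1)
#'   and `v` (the matching weight vectors).
#' @export
matching_weight_contribution <- function(final, raw_views) {
  stopifnot(is_partition(final), is.list(raw_views))
  nv <- length(raw_views)
  v <- vapply(raw_views, function(parts) {
    acc <- numeric(final$K)
    for (p in parts) {
      al <- solve_ot_alignment(p, final)
      acc <- acc + colSums(al$W) / p$K
    }
    acc / length(parts)
  }, numeric(final$K))
  v <- matrix(v, nrow = final$K, ncol = nv)
  tot <- rowSums(v)
  eta <- v / ifelse(tot > 0, tot, 1)
  eta[tot == 0, ] <- 1 / nv
  list(eta = eta, v = v)
}

#' Full per-cluster view-contribution report
#'
#' Computes both contribution measures and selects the one to report: the
#' tightness-based score is preferred, but when more than 40% of the final
#' clusters have tightness 0 the matching-weight-based score is used
#' instead. Under the default `"fallback"` rule a cluster counts as
#' zero-tightness when its tightness is 0 in *every* view — exactly the
#' clusters on which the tightness-based score degenerates to its 0.5
#' fallback, i.e. clusters that cannot be anchored in any single view.
#' Alternative readings are exposed: `"any"` / `"all"` assess the
#' per-view zero fractions and trigger when either / every view exceeds
#' 40%, `"pooled"` pools all view-cluster pairs.
#'
#' @inheritParams tightness_contribution
#' @param rule how to evaluate the zero-tightness trigger.
#' @return object of class `cps_contribution`: list with `table` (data
#'   frame: cluster, view, `R_t`, `v`, `zeta`, `eta`, `selected` value),
#'   `selected` (`"zeta"` or `"eta"`), `zero_fraction` per view, and the
#'   raw matrices.
#' @export
view_contributions <- function(final, raw_views, alpha = 0.1, zeta = 0.7,
                               rule = c("fallback", "any", "all", "pooled")) {
  rule <- match.arg(rule)
  zc <- tightness_contribution(final, raw_views, alpha, zeta)
  mc <- matching_weight_contribution(final, raw_views)
  zero_frac <- colMeans(zc$R_t == 0)
  triggered <- switch(rule,
    fallback = mean(rowSums(zc$R_t) == 0) > 0.4,
    any = any(zero_frac > 0.4),
    all = all(zero_frac > 0.4),
    pooled = mean(zc$R_t == 0) > 0.4)
  selected <- if (triggered) "eta" else "zeta"
  nv <- length(raw_views)
  tab <- data.frame(
    cluster = rep(seq_len(final$K), times = nv),
    view = rep(seq_len(nv), each = final$K),
    R_t = as.vector(zc$R_t),
    v = as.vector(mc$v),
    zeta = as.vector(zc$zeta),
    eta = as.vector(mc$eta)
  )
  tab$selected <- if (selected == "eta") tab$eta else tab$zeta
  structure(
    list(table = tab, selected = selected, zero_fraction = zero_frac,
         zeta = zc$zeta, eta = mc$eta, R_t = zc$R_t, v = mc$v),
    class = "cps_contribution"
  )
}

#' @export
print.cps_contribution <- function(x, ...) {
  cat(sprintf("<cps_contribution> selected measure: %s (zero-tightness fraction: %s)\n",
              x$selected, paste(sprintf("%.2f", x$zero_fraction), collapse = ", ")))
  print(x$table, digits = 3)
  invisible(x)
}
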