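test_that("matching weight matrices average the per-pair couplings", {
  a_lab <- rep(1:2, each = 4)
  b_lab <- rep(1:2, each = 4)
  ea <- perfect_ensemble(a_lab, 3L)
  eb <- perfect_ensemble(b_lab, 3L)
  wbar <- matching_weight_matrix(ea, eb)
  # identical views: diagonal scaled by the proportions
  expect_equal(wbar, diag(c(0.5, 0.5)))
  expect_equal(sum(wbar), 1, tolerance = 1e-8)
  # two distinct pairs: entrywise mean, verified by direct arithmetic
  b2 <- c(1, 1, 2, 2, 2, 2, 1, 1)
  eb2 <- align_ensemble(list(partition(b_lab), partition(b2)),
                        partition(b_lab))
  ea2 <- perfect_ensemble(a_lab, 2L)
  w1 <- solve_ot_alignment(ea2$aligned[[1]], eb2$aligned[[1]])$W
  w2 <- solve_ot_alignment(ea2$aligned[[2]], eb2$aligned[[2]])$W
  expect_equal(matching_weight_matrix(ea2, eb2), (w1 + w2) / 2)
})

test_that("bipartite Leiden recovers block structure and tolerates noise", {
  wbar <- matrix(0, 4, 4)
  wbar[1:2, 1:2] <- 0.125
  wbar[3:4, 3:4] <- 0.125
  sup <- bipartite_super_clusters(wbar, seed = 1)
  expect_equal(sup$n_super, 2L)
  expect_equal(sup$comm_a[1], sup$comm_a[2])
  expect_equal(sup$comm_a[1], sup$comm_b[1])
  expect_false(sup$comm_a[1] == sup$comm_a[3])
  # epsilon off-block noise does not change the communities
  wb2 <- wbar
  wb2[wb2 == 0] <- 1e-3 / 8
  sup2 <- bipartite_super_clusters(wb2, seed = 1)
  expect_equal(ari(c(sup$comm_a, sup$comm_b), c(sup2$comm_a, sup2$comm_b)), 1)
  expect_warning(sup0 <- bipartite_super_clusters(matrix(0, 2, 2)), "zero")
  expect_equal(sup0$n_super, 4L)
})

test_that("the first-stage map merges UP blocks and keeps MP granularity", {
  # 3x3 views fully crossed; clusters {1,2} vs {3} form two super-clusters
  xi_a <- rep(1:3, each = 9)[1:27]
  xi_b <- rep(rep(1:3, each = 3), 3)
  ea <- perfect_ensemble(xi_a, 2L)
  eb <- perfect_ensemble(xi_b, 2L)
  pe <- pair_ensembles(ea, eb)
  super <- list(comm_a = c(1L, 1L, 2L), comm_b = c(1L, 1L, 2L), n_super = 2L)
  g0 <- first_stage_map(pe, super)
  cb <- pe$codebook
  block <- attr(g0, "block")
  mp <- cb$key[block == "MP"]
  expect_setequal(mp, c("1:1", "1:2", "2:1", "2:2", "3:3"))
  # each ordered UP block collapses to a single id
  up1 <- g0[cb$code[cb$key %in% c("1:3", "2:3")]]
  expect_equal(up1[1], up1[2])
  up2 <- g0[cb$code[cb$key %in% c("3:1", "3:2")]]
  expect_equal(up2[1], up2[2])
  expect_false(up1[1] == up2[1])
  expect_equal(length(unique(g0[cb$code])), 7L)  # 5 MP + 2 UP
  # without super-clustering the map is the identity on occupied labels
  g0_id <- first_stage_map(pe, NULL)
  expect_equal(length(unique(g0_id[cb$code])), nrow(cb))
  # a perfect ensemble collapses to identical combined partitions
  comb <- first_stage_merge(pe, g0)
  for (p in comb$aligned) expect_equal(ari(p$labels, comb$reference$labels), 1)
})

stable_split_fixture <- function() {
  # three well-separated blobs clustered with k = 4: the reference splits one
  # blob; perturbed replicates move the split boundary around
  sc <- simulate_views("consensus", n = 300, k_a = 3, separation = 8, seed = 3)
  list(sc = sc, ens = build_ensemble(sc$view_a, clusterer_kmeans(4),
                                     m = 12, seed = 3))
}

test_that("greedy merging reunites a randomly split cluster in one step", {
  fx <- stable_split_fixture()
  st <- ensemble_stability(fx$ens)
  halves <- order(st$R_t)[1:2]
  tr <- cps_merge(fx$ens, kappa1 = 3)
  expect_setequal(tr$events[[1]]$children, halves)
  expect_equal(ari(tr$final$labels, fx$sc$truth), 1)
  # the same end point is reached under the tightness stop
  tr2 <- cps_merge(fx$ens)
  expect_equal(tr2$final$K, 3L)
  expect_true(all(tr2$stability$R_t >= 0.8))
})

test_that("greedy merge agrees with exhaustive one-step lookahead", {
  fx <- stable_split_fixture()
  ens <- fx$ens
  K <- ens$reference$K
  ref_lab <- ens$reference$labels
  parts_lab <- lapply(ens$aligned, cpsmerge:::raw_labels)
  score <- function(i, j) {
    rl <- ref_lab; rl[rl == j] <- i
    pl <- lapply(parts_lab, function(x) { x[x == j] <- i; x })
    s <- cpsmerge:::stability_of_labels(rl, pl, 0.1, 0.7)
    sum(s$st$R_t)
  }
  pairs <- utils::combn(K, 2)
  sums <- apply(pairs, 2, function(ij) score(ij[1], ij[2]))
  best <- pairs[, which.max(sums)]
  tr <- cps_merge(ens, kappa1 = K - 1L)
  expect_setequal(tr$events[[1]]$children, best)
})

test_that("already-stable partitions are returned unmerged", {
  ens <- perfect_ensemble(rep(1:3, each = 5), 5L)
  tr <- cps_merge(ens)
  expect_length(tr$events, 0L)
  expect_equal(tr$final$K, 3L)
  tra <- accelerated_cps_merge(ens)
  expect_length(tra$events, 0L)
  expect_error(cps_merge(ens, kappa1 = 5), "exceeds")
})

test_that("merge trees replay to the final partition and export as Newick", {
  fx <- stable_split_fixture()
  tr <- cps_merge(fx$ens, kappa1 = 2)
  expect_true(all(diff(tr$trajectory$K) < 0))
  # g1 replays the merge history onto the initial labels
  init <- fx$ens$reference$labels
  expect_equal(ari(as.integer(tr$g1[as.character(init)]), tr$final$labels), 1)
  nwk <- merge_tree_newick(tr)
  tree <- ape::read.tree(text = nwk)
  expect_equal(sort(tree$tip.label), sort(paste0("c", 1:4)))
})

test_that("the accelerated ladder honors the cluster-count stop exactly", {
  fx <- stable_split_fixture()
  tra <- accelerated_cps_merge(fx$ens, kappa1 = 3)
  expect_equal(tra$final$K, 3L)
  expect_equal(ari(tra$final$labels, fx$sc$truth), 1)
  tra2 <- accelerated_cps_merge(fx$ens, kappa1 = 2)
  expect_equal(tra2$final$K, 2L)
  expect_error(accelerated_cps_merge(fx$ens, thresholds = c(0.5, 0.4)),
               "increasing")
})

test_that("the pipeline is deterministic given its seed", {
  sc <- simulate_views("complementary", n = 300, separation = 7, seed = 17)
  r1 <- run_pipeline(sc$view_a, sc$view_b, clusterer_kmeans(2),
                     clusterer_kmeans(2), m = 6, seed = 17)
  r2 <- run_pipeline(sc$view_a, sc$view_b, clusterer_kmeans(2),
                     clusterer_kmeans(2), m = 6, seed = 17)
  expect_identical(r1$final$labels, r2$final$labels)
  expect_identical(r1$stability$R_t, r2$stability$R_t)
})
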