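test_that("matched sets count matching partitions and report p_k", {
  ref_lab <- rep(1:2, each = 6)
  ens <- perfect_ensemble(ref_lab, 5L)
  ms <- matched_sets(1, ens)
  expect_equal(ms$p_k, 1)
  for (s in ms$sets) expect_equal(s, 1:6)
  # partitions that split reference cluster 1 in half provide no match for it
  split_lab <- c(1, 1, 1, 3, 3, 3, 2, 2, 2, 2, 2, 2)
  parts <- c(replicate(7, partition(ref_lab), simplify = FALSE),
             replicate(3, partition(split_lab), simplify = FALSE))
  ens2 <- align_ensemble(parts, partition(ref_lab))
  expect_equal(matched_sets(1, ens2)$p_k, 0.7)
  expect_equal(matched_sets(2, ens2)$p_k, 1)
  # a cluster absent everywhere
  ens3 <- align_ensemble(replicate(3, partition(split_lab), simplify = FALSE),
                         partition(ref_lab))
  expect_equal(matched_sets(1, ens3)$p_k, 0)
})

test_that("LIFT covering point sets satisfy coverage and handle boundaries", {
  # identical sets: CPS equals the common set at any alpha
  sets <- replicate(4, c(2, 4, 6), simplify = FALSE)
  expect_equal(covering_point_set(sets, 0.25)$members, c(2, 4, 6))
  # hand fixture used by the tightness closed form
  cv <- covering_point_set(list(1:3, 1:4), alpha = 0)
  expect_equal(cv$members, 1:4)
  # degenerate basis: nothing needs covering
  expect_warning(cv0 <- covering_point_set(list(1:3), alpha = 0.5,
                                           m_basis = 0L), "no set")
  expect_equal(cv0$members, integer())
  # any positive basis requires at least one covered set
  expect_equal(covering_point_set(list(1:3), alpha = 0.9,
                                  m_basis = 1L)$members, 1:3)
  # requirement above the available sets: cover everything, warn
  expect_warning(cva <- covering_point_set(list(1:2, 3:4), alpha = 0,
                                           m_basis = 5L), "exceeds")
  expect_equal(cva$members, 1:4)
  expect_error(covering_point_set(list(1:3), alpha = 1), "alpha")
})

test_that("greedy LIFT attains the exhaustive minimum on random fixtures", {
  set.seed(77)
  for (rep in 1:40) {
    m <- sample(3:7, 1L)
    sets <- replicate(m, sample(1:12, sample(2:8, 1L)), simplify = FALSE)
    alpha <- sample(c(0, 0.2, 0.4), 1L)
    cv <- covering_point_set(sets, alpha)
    required <- ceiling(m * (1 - alpha))
    expect_equal(length(cv$members), bruteforce_cps_size(sets, required))
    covered <- sum(vapply(sets, function(s)
      all(s %in% cv$members), logical(1)))
    expect_gte(covered, required)
  }
})

test_that("tightness closed forms hold", {
  ref_lab <- rep(1:2, each = 5)
  ens <- perfect_ensemble(ref_lab, 6L)
  expect_equal(tightness(1, ens, alpha = 0), 1)
  expect_equal(tightness(2, ens, alpha = 0), 1)
  # never-matched cluster has tightness 0
  split_lab <- c(1, 1, 3, 3, 3, 2, 2, 2, 2, 2)
  ens0 <- align_ensemble(replicate(3, partition(split_lab), simplify = FALSE),
                         partition(ref_lab))
  expect_equal(tightness(1, ens0), 0)
  # hand fixture: sets {1,2,3} and {1,2,3,4} at alpha = 0
  expect_equal(cpsmerge:::tightness_from_sets(list(1:3, 1:4), p_k = 1,
                                              alpha = 0), 0.875)
  # with alpha = 0 tightness is bounded by 1
  set.seed(13)
  for (rep in 1:10) {
    parts <- replicate(5, random_partition(24, 3L), simplify = FALSE)
    ens_r <- align_ensemble(parts, random_partition(24, 3L))
    st <- ensemble_stability(ens_r, alpha = 0)
    expect_true(all(st$R_t >= 0 & st$R_t <= 1 + 1e-12))
  }
})

test_that("CAP separability is a symmetric Jaccard distance between covering sets", {
  expect_equal(jaccard_distance(1:6, 4:9), 2 / 3)
  ref_lab <- rep(1:2, each = 6)
  ens <- perfect_ensemble(ref_lab, 4L)
  st <- ensemble_stability(ens)
  expect_equal(st$delta[1, 2], 1)   # disjoint stable clusters
  expect_equal(diag(st$delta), c(0, 0))
  expect_equal(st$delta, t(st$delta))
  expect_equal(cap_separability(1, 2, ens), 1)
  expect_equal(cap_separability(1, 1, ens), 0)
})

test_that("stability summaries agree with the per-cluster primitives", {
  set.seed(31)
  sc <- simulate_views("consensus", n = 150, k_a = 3, separation = 6, seed = 31)
  ens <- build_ensemble(sc$view_a, clusterer_kmeans(3), m = 6, seed = 31)
  st <- ensemble_stability(ens)
  for (k in 1:3) {
    expect_equal(st$R_t[k], tightness(k, ens))
    expect_equal(st$p_k[k], matched_sets(k, ens)$p_k)
  }
  rep_df <- tightness_report(st)
  expect_equal(rep_df$R_t, st$R_t)
  expect_equal(st$mean_tightness, mean(st$R_t))
})
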