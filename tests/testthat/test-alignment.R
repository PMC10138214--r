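test_that("identical and permuted partitions align with zero transport cost", {
  ref <- partition(c(1, 1, 2, 2))
  al <- solve_ot_alignment(ref, ref)
  expect_equal(al$W, diag(c(0.5, 0.5)))
  expect_equal(al$D, 0)
  prm <- partition(c(2, 2, 1, 1))
  al2 <- solve_ot_alignment(prm, ref)
  expect_equal(al2$D, 0)
  expect_equal(al2$W, matrix(c(0, 0.5, 0.5, 0), 2))  # permutation, scaled by q
  # 3-cluster permutation with unequal sizes
  lab <- c(1, 1, 1, 2, 2, 3)
  perm <- c(3, 1, 2)
  al3 <- solve_ot_alignment(partition(perm[lab]), partition(lab))
  expect_equal(al3$D, 0)
})

test_that("optimal transport cost equals the exhaustive integer optimum", {
  set.seed(101)
  for (rep in 1:30) {
    n <- sample(6:14, 1L)
    p1 <- random_partition(n, kmax = 4L)
    p2 <- random_partition(n, kmax = 4L)
    cost <- cpsmerge:::jaccard_cost_matrix(p1, p2)
    sol <- cpsmerge:::transport_simplex(cost, p1$sizes, p2$sizes)
    expect_equal(sol$cost,
                 bruteforce_transport_cost(cost, p1$sizes, p2$sizes),
                 tolerance = 1e-9)
  }
})

test_that("coupling marginals and mapping-matrix stochasticity hold", {
  set.seed(5)
  for (rep in 1:25) {
    n <- sample(8:60, 1L)
    p1 <- random_partition(n)
    p2 <- random_partition(n)
    al <- solve_ot_alignment(p1, p2)
    expect_equal(rowSums(al$W), p1$q, tolerance = 1e-8)
    expect_equal(colSums(al$W), p2$q, tolerance = 1e-8)
    expect_true(all(al$W >= -1e-12))
    expect_equal(rowSums(al$gamma), rep(1, p1$K), tolerance = 1e-8)
    expect_equal(colSums(al$gamma_tilde), rep(1, p2$K), tolerance = 1e-8)
    expect_gte(al$D, -1e-12)
    expect_lte(al$D, 1 + 1e-12)
    # gamma and gamma_tilde are exactly recoverable from W and the marginals
    expect_equal(al$gamma, al$W / al$q_src)
    expect_equal(al$gamma_tilde, sweep(al$W, 2, al$q_ref, "/"))
    # symmetry of the partition distance
    expect_equal(al$D, solve_ot_alignment(p2, p1)$D, tolerance = 1e-9)
  }
})

test_that("achieved objective is no worse than random feasible couplings", {
  set.seed(9)
  p1 <- random_partition(40, kmax = 5L)
  p2 <- random_partition(40, kmax = 5L)
  cost <- cpsmerge:::jaccard_cost_matrix(p1, p2)
  al <- solve_ot_alignment(p1, p2)
  for (rep in 1:200) {
    # random feasible coupling by Sinkhorn-style scaling of a random matrix
    M <- matrix(stats::rexp(p1$K * p2$K), p1$K)
    for (it in 1:200) {
      M <- M * (p1$q / rowSums(M))
      M <- sweep(M, 2, p2$q / colSums(M), "*")
    }
    expect_lte(al$D, sum(M * cost) + 1e-6)
  }
})

test_that("MAP relabeling inverts permutations and follows the dominant map", {
  ref <- partition(c(1, 1, 2, 2, 3, 3))
  expect_equal(map_relabel(ref, solve_ot_alignment(ref, ref))$labels,
               ref$labels)
  prm <- partition(c(3, 3, 1, 1, 2, 2))
  expect_equal(map_relabel(prm, solve_ot_alignment(prm, ref))$labels,
               ref$labels)
  # one source cluster split 70/30 over two reference clusters: every item
  # follows the 70% target
  ref2 <- partition(c(rep(1, 7), rep(2, 3)))
  src <- partition(rep(1, 10))
  al <- solve_ot_alignment(src, ref2)
  expect_equal(al$gamma, matrix(c(0.7, 0.3), 1))
  expect_equal(map_relabel(src, al)$labels, rep(1L, 10))
})

test_that("map_relabel is equivariant under reference label permutations", {
  set.seed(23)
  for (rep in 1:10) {
    n <- 30L
    src <- random_partition(n, 4L)
    ref_lab <- sample.int(3L, n, replace = TRUE)
    perm <- sample(3L)
    r1 <- map_relabel(src, solve_ot_alignment(src, partition(ref_lab)))
    r2 <- map_relabel(src, solve_ot_alignment(src, partition(perm[ref_lab])))
    expect_equal(ari(r1$labels, r2$labels), 1)
  }
})

test_that("match relation requires mutual dominance at threshold zeta", {
  ref <- partition(c(1, 1, 2, 2))
  al <- solve_ot_alignment(ref, ref)
  rel <- classify_relations(al, zeta = 0.8)
  expect_equal(rel$match, c(1L, 2L))
  # one-sided dominance (gamma 0.9 but gamma_tilde only 0.6) is not a match
  fake <- structure(list(
    W = matrix(c(0.45, 0.3, 0.05, 0.2), 2),
    gamma = matrix(c(0.9, 0.6, 0.1, 0.4), 2),
    gamma_tilde = matrix(c(0.6, 0.4, 0.2, 0.8), 2),
    D = 0.2, q_src = c(0.5, 0.5), q_ref = c(0.75, 0.25)),
    class = "cps_alignment")
  expect_true(is.na(classify_relations(fake, zeta = 0.7)$match[1]))
  expect_error(classify_relations(al, zeta = 0.5), "0.5")
  # reference cluster absorbed 50/50 by two source clusters: no match
  ref3 <- partition(c(1, 1, 1, 1, 2, 2))
  src3 <- partition(c(1, 1, 2, 2, 3, 3))
  rel3 <- classify_relations(solve_ot_alignment(src3, ref3), zeta = 0.8)
  expect_true(is.na(rel3$match[1]))
  expect_equal(rel3$match[2], 3L)
})

test_that("aligning an ensemble of copies or permutations recovers the reference", {
  ref_lab <- c(1, 1, 1, 2, 2, 3, 3, 3)
  ens <- perfect_ensemble(ref_lab, 4L)
  for (p in ens$aligned) expect_equal(p$labels, partition(ref_lab)$labels)
  perms <- lapply(1:4, function(i) {
    pm <- sample(3L)
    partition(pm[ref_lab])
  })
  set.seed(2)
  ens2 <- align_ensemble(perms, partition(ref_lab))
  for (p in ens2$aligned) expect_equal(ari(p$labels, ref_lab), 1)
})
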