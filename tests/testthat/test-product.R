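test_that("cartesian products label items by their view-label pairs", {
  pa <- partition(c(1, 1, 2, 2, 3, 3))
  pb <- partition(c(1, 2, 3, 4, 1, 2))
  pp <- cartesian_product(pa, pb)
  expect_lte(pp$K, 3 * 4)
  cb <- attr(pp, "codebook")
  expect_equal(nrow(cb), pp$K)
  expect_equal(sum(cb$size), 6)
  # a constant second view is absorbed: product equals the first view
  pb1 <- partition(rep(1, 6))
  expect_equal(ari(cartesian_product(pa, pb1)$labels, pa$labels), 1)
  # fully complementary 2x2 design: the product clusters are the truth
  xi_a <- c(1, 1, 2, 2, 1, 2, 1, 2)
  xi_b <- c(1, 2, 1, 2, 1, 2, 2, 1)
  truth <- (xi_a - 1) * 2 + xi_b
  expect_equal(ari(cartesian_product(partition(xi_a),
                                     partition(xi_b))$labels, truth), 1)
  expect_error(cartesian_product(pa, partition(1:3)), "different numbers")
})

test_that("pairing ensembles keeps m index pairs under a shared codebook", {
  a_lab <- rep(1:2, each = 4)
  b_lab <- rep(1:2, times = 4)
  ea <- perfect_ensemble(a_lab, 3L)
  eb <- perfect_ensemble(b_lab, 3L)
  pe <- pair_ensembles(ea, eb)
  expect_equal(pe$m, 3L)
  expect_length(pe$pair_codes, 3L)  # m pairs, never m^2
  for (cc in pe$pair_codes) expect_equal(cc, pe$reference_codes)
  # product label reconstructible from the two view labels
  cb <- pe$codebook
  expect_equal(cb$xi_a[pe$reference_codes], a_lab)
  expect_equal(cb$xi_b[pe$reference_codes], b_lab)
  expect_error(pair_ensembles(ea, perfect_ensemble(b_lab, 2L)), "different")
})

make_product_fixture <- function() {
  # view A stable everywhere; view B has one deviating replicate
  a_lab <- c(1, 1, 1, 1, 2, 2, 2, 2)
  b_ref <- c(1, 1, 2, 2, 3, 3, 3, 3)
  b_dev <- c(1, 1, 3, 2, 3, 3, 3, 3)   # point 3 flips to label 3 once
  ea <- perfect_ensemble(a_lab, 10L)
  b_parts <- c(list(partition(b_dev)),
               replicate(9, partition(b_ref), simplify = FALSE))
  eb <- align_ensemble(b_parts, partition(b_ref))
  pair_ensembles(ea, eb)
}

test_that("rare product labels are re-labeled by the non-rare majority", {
  pe <- make_product_fixture()
  cb <- pe$codebook
  rare_key <- cb$key[cb$rare]
  expect_equal(rare_key, "1:3")       # occupancy 1 < m = 10
  cleaned <- clean_rare_labels(pe)
  expect_false(any(cleaned$codebook$rare))
  maj <- cleaned$codebook$code[cleaned$codebook$key == "1:2"]
  for (p in 1:10) expect_equal(cleaned$pair_codes[[p]][3], maj)
  # untouched points keep their labels (codes recompact, keys are stable)
  expect_equal(cleaned$codebook$key[cleaned$pair_codes[[2]][-3]],
               pe$codebook$key[pe$pair_codes[[2]][-3]])
  # total item count conserved, label count never increases
  expect_lte(nrow(cleaned$codebook), nrow(pe$codebook))
  for (p in 1:10) expect_length(cleaned$pair_codes[[p]], 8L)
})

test_that("occupancy exactly m is not rare and cleaning is then the identity", {
  a_lab <- rep(1:2, each = 4)
  ea <- perfect_ensemble(a_lab, 4L)
  eb <- perfect_ensemble(c(1, 1, 2, 2, 2, 2, 3, 3), 4L)
  pe <- pair_ensembles(ea, eb)
  # every occupied label appears n_label * m >= m times
  expect_false(any(pe$codebook$rare))
  cleaned <- clean_rare_labels(pe)
  expect_identical(cleaned$pair_codes, pe$pair_codes)
  expect_identical(cleaned$reference_codes, pe$reference_codes)
})

test_that("a rare reference label is re-labeled by the ensemble majority", {
  # reference calls point 5 (2,3) but every replicate calls it (2,2)
  a_lab <- c(1, 1, 1, 1, 2, 2, 2, 2)
  b_ref <- c(1, 1, 2, 2, 3, 2, 2, 2)
  b_rep <- c(1, 1, 2, 2, 2, 2, 2, 2)
  ea <- perfect_ensemble(a_lab, 6L)
  eb <- align_ensemble(replicate(6, partition(b_rep), simplify = FALSE),
                       partition(b_ref))
  pe <- pair_ensembles(ea, eb)
  cb <- pe$codebook
  expect_true(cb$rare[cb$key == "2:3"])   # occupancy 0 in the replicates
  cleaned <- clean_rare_labels(pe)
  target <- cleaned$codebook$code[cleaned$codebook$key == "2:2"]
  expect_equal(cleaned$reference_codes[5], target)
})
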