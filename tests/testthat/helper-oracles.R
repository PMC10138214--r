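# Independent oracles and fixture builders used across the suite.

# Exhaustive minimum-cost integer transportation plan by recursive
# enumeration of all integer matrices with the given margins. Independent of
# the package's simplex solver; tractable for counts summing to ~<= 20.
bruteforce_transport_cost <- function(cost, row_counts, col_counts) {
  r <- length(row_counts)
  s <- length(col_counts)
  best <- Inf
  rem_c <- col_counts
  recurse_row <- function(i, acc) {
    if (acc >= best) return()
    if (i > r) {
      if (all(rem_c == 0)) best <<- acc
      return()
    }
    fill_row <- function(j, left, cost_acc) {
      if (acc + cost_acc >= best) return()
      if (j == s) {
        if (left <= rem_c[s]) {
          rem_c[s] <<- rem_c[s] - left
          recurse_row(i + 1L, acc + cost_acc + left * cost[i, s])
          rem_c[s] <<- rem_c[s] + left
        }
        return()
      }
      for (x in 0:min(left, rem_c[j])) {
        rem_c[j] <<- rem_c[j] - x
        fill_row(j + 1L, left - x, cost_acc + x * cost[i, j])
        rem_c[j] <<- rem_c[j] + x
      }
    }
    fill_row(1L, row_counts[i], 0)
  }
  recurse_row(1L, 0)
  best
}

# Exhaustive covering-point-set size: minimum union cardinality over all
# ways of choosing `required` of the sets.
bruteforce_cps_size <- function(sets, required) {
  if (required <= 0L) return(0L)
  combos <- utils::combn(length(sets), required, simplify = FALSE)
  min(vapply(combos, function(idx)
    length(unique(unlist(sets[idx]))), integer(1)))
}

# ARI by direct enumeration of all item pairs (no contingency shortcut).
pairwise_ari <- function(l1, l2) {
  n <- length(l1)
  same1 <- outer(l1, l1, "==")[upper.tri(diag(n))]
  same2 <- outer(l2, l2, "==")[upper.tri(diag(n))]
  a <- sum(same1 & same2)
  b <- sum(same1 & !same2)
  c_ <- sum(!same1 & same2)
  d <- sum(!same1 & !same2)
  tot <- a + b + c_ + d
  exp_a <- (a + b) * (a + c_) / tot
  max_a <- ((a + b) + (a + c_)) / 2
  if (abs(max_a - exp_a) < .Machine$double.eps) return(1)
  (a - exp_a) / (max_a - exp_a)
}

random_partition <- function(n, kmax = 5L) {
  partition(sample.int(sample(2:kmax, 1L), n, replace = TRUE))
}

# Ensemble with every replicate identical to the reference.
perfect_ensemble <- function(ref_labels, m) {
  ref <- partition(ref_labels)
  align_ensemble(replicate(m, partition(ref_labels), simplify = FALSE), ref)
}
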