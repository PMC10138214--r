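#' Cartesian product of two partitions
#'
#' Each item is labeled by the ordered pair of its cluster labels in the two
#' views; every occupied pair becomes one product cluster. Product clusters
#' carry the cross-view interaction structure: when the views are fully
#' complementary the product clusters *are* the true clusters.
#'
#' @param pa,pb partitions of the same items (each already in its view's
#'   reference label space).
#' @return a [partition()] whose `label_map` holds the `"xiA:xiB"` codes; the
#'   pair decomposition is attached as attribute `codebook`, a data frame
#'   with columns `code`, `xi_a`, `xi_b`, `size`.
#' @export
cartesian_product <- function(pa, pb) {
  stopifnot(is_partition(pa), is_partition(pb))
  if (pa$n != pb$n) stop("partitions cover different numbers of items")
  key <- paste(pa$labels, pb$labels, sep = ":")
  p <- partition(key)
  parts <- do.call(rbind, strsplit(p$label_map, ":", fixed = TRUE))
  attr(p, "codebook") <- data.frame(
    code = seq_len(p$K),
    xi_a = as.integer(parts[, 1L]),
    xi_b = as.integer(parts[, 2L]),
    size = p$sizes
  )
  p
}

#' Pair two aligned view ensembles into a product ensemble
#'
#' Pairs partition `p` of view A with partition `p` of view B for
#' `p = 1..m` — since the perturbed partitions within each view are generated
#' independently, index pairing realizes a random pairing while keeping only
#' `m` of the `m^2` possible products. The reference product partition is the
#' product of the two view references.
#'
#' All product partitions share one global codebook over the occupied
#' `(xi_A, xi_B)` pairs so product labels are comparable across partitions.
#'
#' @param ea,eb `cps_ensemble` objects of the two views (aligned).
#' @return object of class `cps_product`: list with `reference` (product
#'   [partition()]), `pairs` (list of `m` product partitions), `codebook`
#'   (data frame: `code`, `xi_a`, `xi_b`, `occupancy`, `ref_size`, `rare`),
#'   `kappa_a`, `kappa_b`, `m`.
#' @export
pair_ensembles <- function(ea, eb) {
  stopifnot(inherits(ea, "cps_ensemble"), inherits(eb, "cps_ensemble"))
  if (ea$m != eb$m) stop("ensembles have different numbers of partitions")
  if (ea$reference$n != eb$reference$n) stop("views cover different numbers of items")
  m <- ea$m
  n <- ea$reference$n
  key_of <- function(pa, pb) paste(pa$labels, pb$labels, sep = ":")
  ref_key <- key_of(ea$reference, eb$reference)
  pair_keys <- lapply(seq_len(m), function(p)
    key_of(ea$aligned[[p]], eb$aligned[[p]]))
  # global codebook over every occupied pair, in any partition
  all_keys <- sort(unique(c(ref_key, unlist(pair_keys))))
  parts <- do.call(rbind, strsplit(all_keys, ":", fixed = TRUE))
  occupancy <- tabulate(match(unlist(pair_keys), all_keys), length(all_keys))
  codebook <- data.frame(
    code = seq_along(all_keys),
    key = all_keys,
    xi_a = as.integer(parts[, 1L]),
    xi_b = as.integer(parts[, 2L]),
    occupancy = occupancy,
    ref_size = tabulate(match(ref_key, all_keys), length(all_keys)),
    rare = occupancy < m
  )
  structure(
    list(
      reference_codes = match(ref_key, all_keys),
      pair_codes = lapply(pair_keys, function(k) match(k, all_keys)),
      codebook = codebook,
      kappa_a = ea$reference$K,
      kappa_b = eb$reference$K,
      m = m,
      n = n
    ),
    class = "cps_product"
  )
}

#' @export
print.cps_product <- function(x, ...) {
  cat(sprintf("<cps_product> %d x %d view clusters, %d occupied product labels, m = %d\n",
              x$kappa_a, x$kappa_b, nrow(x$codebook), x$m))
  invisible(x)
}

#' Re-label rare product clusters by majority vote
#'
#' A product label is *rare* when it is taken by sample points fewer than `m`
#' times in total across the `m` paired product partitions (less than once
#' per result on average) — such labels arise from randomness rather than
#' real interaction structure. Every point that holds a rare label in any
#' result is re-labeled, in all `m` results and in the reference product
#' partition, by its most frequent label across the `m` results; the vote is
#' restricted to non-rare labels whenever the point holds any, so cleaning
#' cannot reintroduce rarity. Vote ties are broken toward the larger global
#' cluster and then the smaller code.
#'
#' @param pe a `cps_product` from [pair_ensembles()].
#' @return a `cps_product` with rare labels resolved and the codebook's
#'   `occupancy`/`rare` columns recomputed; points whose every label was rare
#'   are reported with a warning.
#' @export
clean_rare_labels <- function(pe) {
  stopifnot(inherits(pe, "cps_product"))
  cb <- pe$codebook
  rare <- cb$rare
  if (!any(rare)) return(pe)
  m <- pe$m
  n <- pe$n
  code_mat <- do.call(cbind, pe$pair_codes)       # n x m matrix of codes
  global_size <- tabulate(as.vector(code_mat), nrow(cb))
  affected <- which(apply(code_mat, 1L, function(cc) any(rare[cc])) |
                      rare[pe$reference_codes])
  forced <- integer(0)
  vote <- function(codes) {
    cand <- codes[!rare[codes]]
    fallback <- length(cand) == 0L
    if (fallback) cand <- codes
    tab <- table(cand)
    ids <- as.integer(names(tab))
    best <- ids[order(-as.integer(tab), -global_size[ids], ids)][1L]
    list(code = best, fallback = fallback)
  }
  for (h in affected) {
    v <- vote(code_mat[h, ])
    if (v$fallback) forced <- c(forced, h)
    code_mat[h, ] <- v$code
    pe$reference_codes[h] <- v$code
  }
  if (length(forced))
    warning(sprintf("%d point(s) held only rare labels; majority taken over rare labels",
                    length(forced)))
  pe$pair_codes <- lapply(seq_len(m), function(p) code_mat[, p])
  occ <- tabulate(unlist(pe$pair_codes), nrow(cb))
  ref_occ <- tabulate(pe$reference_codes, nrow(cb))
  # drop emptied labels and recode densely so codes stay row indices
  live <- which(occ > 0L | ref_occ > 0L)
  recode <- match(seq_len(nrow(cb)), live)
  pe$reference_codes <- recode[pe$reference_codes]
  pe$pair_codes <- lapply(pe$pair_codes, function(cc) recode[cc])
  cb <- cb[live, , drop = FALSE]
  cb$code <- seq_len(nrow(cb))
  cb$occupancy <- occ[live]
  cb$ref_size <- ref_occ[live]
  cb$rare <- cb$occupancy < m
  rownames(cb) <- NULL
  pe$codebook <- cb
  pe
}
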