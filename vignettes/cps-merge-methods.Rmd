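---
title: "Stability-guided merging of product clusters: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability-guided merging of product clusters: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpsmerge)
```

# The problem

Multimodal single-cell experiments measure the same cells in two (or more)
views — RNA and surface protein in CITE-seq, RNA and chromatin accessibility
in multiome assays. Each view supports its own clustering, and two opposing
principles govern how the views should be combined. Under the *consensus*
principle the views are noisy copies of one underlying structure, and
integration should average them. Under the *complementary* principle some
populations are separable only when the views are combined — T-cell subsets
indistinguishable in RNA but split cleanly by surface markers are the
canonical example. `cpsmerge` is a *late-integration* method: it consumes
only cluster labels from each view (any single-view algorithm can produce
them), yet it retains complementary structure by working with the Cartesian
product of the single-view clusterings and merging the product clusters
under a clustering-stability objective.

# The pipeline

## Per-view ensembles and alignment

For each view, the chosen clusterer applied to the original data gives the
*reference partition*. The data are then perturbed `m` times with isotropic
Gaussian noise and re-clustered, giving `m` replicate partitions. The noise
variance is a fraction (default 10%) of the *average within-cluster
variance*: the unweighted mean over clusters of the mean per-coordinate
sample variance (denominator $n_k - 1$, singletons contributing 0). This
convention is scale-free in both the number of clusters and the
dimensionality; users comparing against other stability tools should note
that the variance is per-coordinate, not total. A view known a priori to be
dominant can be left unperturbed (`perturb_view = FALSE`), in which case
the clusterer is re-run with fresh seeds instead.

Cluster labels are arbitrary across runs, so each replicate is aligned to
the reference by optimal transport. With cluster proportions
$q^{(p)}, q^{(r)}$ as marginals and the Jaccard distance between cluster
member sets as ground cost, the coupling $W$ solves

$$D(\mathcal{P}^{(p)},\mathcal{P}^{(r)}) = \min_W \sum_{i,j} w_{ij}\,
d(C_i^{(p)}, C_j^{(r)}), \qquad
\textstyle\sum_j w_{ij} = q_i^{(p)},\; \sum_i w_{ij} = q_j^{(r)},\; w \ge 0.$$

The solver is an exact transportation (network) simplex written for this
package: partition alignment needs a vertex of the transport polytope — a
label-permuted copy of a partition must come back as the exact permutation
with $D = 0$ — which entropic approximations do not deliver. Marginals are
handled as integer counts, so all pivoting arithmetic is exact; the solver
is validated in the test suite against brute-force enumeration of integer
transportation plans. Row-normalizing $W$ gives the mapping matrix
$\Gamma$ (how each replicate cluster distributes over reference clusters),
column-normalizing gives $\tilde\Gamma$; items are relabeled by the MAP
rule over their cluster's $\Gamma$ row, ties toward the smaller reference
label.

Clusters $C_i^{(p)}$ and $C_j^{(r)}$ *match* when
$\gamma_{ij} \ge \zeta$ and $\tilde\gamma_{ij} \ge \zeta$ with the
relaxation threshold $\zeta \in (0.5, 1]$ (default 0.7, the midpoint of the
admissible range; any $\zeta > 0.5$ makes the match partner unique on both
sides). Relations beyond match/no-match (split, merge, lack of
correspondence) are reported for diagnostics only and follow a documented
stand-in taxonomy; nothing downstream consumes them.

## Stability: covering point sets and tightness

For reference cluster $k$, the replicates matched with it form sets
$S_1,\dots,S_{m_k}$, with $p_k = m_k/m$ the match frequency. The *covering
point set* $S_\alpha$ is the smallest point set containing at least
$100(1-\alpha)\%$ of the $S_i$ as subsets — a set-valued confidence region.
The minimal cover is the union of the kept sets for the best removal
choice; since only about $\alpha\, m_k$ sets are removed, `cpsmerge` finds
the optimum by direct enumeration over removal choices whenever
$\binom{m_k}{\text{drops}} \le 10^4$ (always the case at the default
$\alpha = 0.1$ with practical ensemble sizes), and otherwise applies a
targeted-removal greedy that repeatedly discards the set whose exclusion
shrinks the running union the most. The enumeration bound matters: the
greedy alone misses the optimum on roughly 8% of small random instances,
so exactness at the scale where it is affordable is both cheap and
verifiable against an exhaustive oracle.

Cluster tightness is
$R_t(k) = p_k \cdot \frac{1}{m_k}\sum_i |S_i| / |S_\alpha|$: 1 for a
cluster every replicate reproduces exactly, 0 for a cluster never matched;
at $\alpha = 0$ it is guaranteed to lie in $[0,1]$. The coverage
denominator uses the $m_k$ matched sets (coverage
$\lceil m_k(1-\alpha)\rceil$), since only matched replicates exist as sets;
`m_basis` exposes the stricter all-partitions convention. *CAP
separability* $\delta_{\text{cap}}$ between two reference clusters is the
Jaccard distance between their covering point sets; clusters that are never
matched fall back to their own member set as a degenerate cover so they
still have a defined distance to potential merge partners, while their
tightness stays 0. Default $\alpha = 0.1$.

## Product clusters and rare-label cleaning

The two aligned reference partitions define product labels
$(\xi_A, \xi_B)$; replicate pairs $(A^{(p)}, B^{(p)})$, $p = 1..m$, are
index-paired (the replicates are generated independently within each view,
so index pairing realizes a random pairing while keeping $m$ rather than
$m^2$ products). A product label occupied fewer than $m$ times in total
across the $m$ paired partitions — less than once per result on average —
is *rare*: an artifact of randomness rather than interaction structure.
Every point holding a rare label anywhere is re-labeled, in all $m$ results
and in the reference, by its most frequent label across the results. The
vote is restricted to non-rare labels whenever the point holds any (an
unrestricted vote could reintroduce rarity); ties break toward the larger
global cluster, then the smaller code. Labels emptied by cleaning are
dropped and codes recompacted.

## Two-stage merging

The target is the label map $f$ maximizing $\sum_k R_t(k)$ over the final
clusters — an intrinsically combinatorial objective attacked greedily.

When more than `first_stage_threshold` (default 100) product clusters are
occupied, a *first stage* reduces their number: the matching weight matrix
$\bar W = \sum_p W^{(p)}/m$ (mean OT coupling between the paired replicate
partitions of the two views) weights a bipartite graph whose node sets are
the view-A and view-B clusters, and Leiden community detection (modularity
objective, resolution 1 by default, seeded from the master seed) groups
the nodes into super-clusters. Product labels whose two view clusters fall
in the same super-cluster keep product granularity (*matched product*
blocks); labels spanning two super-clusters are collapsed wholesale into
one cluster per ordered block (*unmatched product* blocks). The collapsed
reference is the combined reference $C$; every collapsed replicate product
partition is OT-aligned to $C$.

The *second stage* merges the combined clusters to maximize tightness. The
exact greedy repeatedly takes the most unstable cluster (lowest $R_t$,
ties toward the smaller id) and merges it with its closest cluster under
$\delta_{\text{cap}}$ (ties toward the larger partner, then the smaller
id); after each merge the reference and all replicate partitions are
collapsed through the merge map and all quantities are recomputed from
scratch — there is no linkage shortcut because tightness is not
decomposable. Partner search is global, not restricted to super-cluster
boundaries. Replicates are OT-aligned to $C$ once and collapsed through
the merge map thereafter, with couplings recomputed on the collapsed label
spaces each round. The *accelerated* variant processes an ascending
threshold ladder (default 0.35, 0.5, 0.65, 0.8): under each threshold,
every cluster below it is merged with its nearest cluster in one round,
chained assignments being collapsed together through union-find, until no
cluster falls below the threshold.

Two stop rules exist. A cluster-count target $\kappa_1$ is a hard stop and
takes precedence when both are configured (matching how fixed cluster
numbers are used in benchmark comparisons). Otherwise merging stops when
*every* cluster's tightness reaches the goal (default 0.8). The
every-cluster reading deserves a note: the alternative — stopping when the
*mean* tightness crosses 0.8 — lets small spurious boundary clusters with
tightness around 0.5 survive whenever the remaining clusters are tight
enough to carry the average, and makes the exact scheme terminate earlier
than the threshold ladder, whose natural convergence point is precisely
"no cluster below 0.8". The per-cluster rule makes the two schemes
consistent and removes the averaging artifact; the mean tightness is still
reported at every step.

## View contributions

With the final partition $F$ fixed as reference, the *raw* (never aligned)
replicate partitions of each view are treated as perturbations of $F$ and
the stability machinery is re-run per view, giving $R_t(k, l)$. The
tightness-based contribution is
$\zeta_{k,l} = R_t(k,l) / \sum_{l'} R_t(k,l')$, set to $1/L$ when the
denominator vanishes. The matching-weight-based contribution uses the OT
couplings $W_l^{(p)}$ of each raw partition against $F$:
$V_l^{(p)} = \mathbf{1}^\top W_l^{(p)} / \kappa_{p,l}$, averaged over $p$
into $v_{k,l}$ and normalized into $\eta_{k,l}$.

A structural fact shapes the defaults here. Balanced OT fixes the column
sums of every $W_l^{(p)}$ at $F$'s cluster proportions, so
$v_{k,l} = q_k \cdot \overline{1/\kappa_{p,l}}$ and $\eta_{k,l}$ is
constant across clusters — with equal cluster counts in the views it is
exactly 0.5 everywhere. $\eta$ is therefore a blunt instrument, meaningful
only as a global prior when $\zeta$ has nothing to work with. Accordingly
the selection rule ("use $\eta$ when more than 40% of clusters have
tightness 0") counts, by default, the clusters whose tightness is zero in
*every* view — exactly the clusters where $\zeta$ degenerates to its 0.5
fallback. Counting per view instead (`rule = "any"` or `"all"`) would
discard an informative $\zeta$ in mixed regimes where each cluster is
anchored in exactly one view; those variants and a pooled count remain
available.

# The synthetic-data generator

`simulate_views()` draws paired Gaussian-mixture views for `n` items.
Cluster means sit on a one-dimensional lattice in each view's feature
space with adjacent means `separation` apart in units of the
within-cluster standard deviation (fixed at 1), so `separation` is
directly the signal-to-noise margin; remaining coordinates carry pure
noise. Regimes: *complementary* (independent view labels; the truth is
their product), *consensus* (one shared label drives both views),
*mixed* (a 2×2 design where one pair of true clusters shares its view-B
mean and another its view-A mean, so each pair is separable in exactly one
view), and *ancillary* (view B is a single blob). Default conditions used
throughout the documentation and the acceptance script: $n = 1000$,
$m = 20$, separation 6, two dimensions per view, balanced mixing
proportions — sizes at which the full pipeline runs in seconds on one CPU.

What the generator does *not* emulate matters for interpreting green
tests: real single-cell data have count noise, dropout, batch effects,
unbalanced and non-spherical populations, and correlated features. Passing
recovery tests show the integration logic is correct on well-specified
mixtures, not that any particular dataset will reach similar agreement
scores. One quantitative consequence of the design: at separation 6 the
single-view Bayes boundary leaves a handful of points (a few per thousand)
on the wrong side in each view, and a late-integration method cannot
repair label errors present in its input partitions, so recovery ARI at
these conditions has a data-dependent ceiling slightly below 1 that the
pipeline attains.

# Numerical and degenerate-case choices

* Item indices are 0-free (1-based) in R; cluster labels are compacted to
  `1..K` with the original labels retained in a label map.
* The Jaccard distance of two empty sets is 0 (clusters that vanish
  together are the same), with a warning.
* MAP relabeling ties break toward the smallest reference label; merge
  tie-breaks are as documented above; all are deterministic.
* The transportation simplex selects the most negative reduced cost
  (Dantzig) and switches to Bland's rule after a long pivot sequence, so
  termination is guaranteed; degenerate pivots keep a spanning-tree basis.
* Points whose every product label is rare take the majority over rare
  labels, with a warning.
* A coverage requirement exceeding the available sets covers everything,
  with a warning; tightness with an empty cover is 0.
* Every stage derives its randomness from the master seed (per-replicate
  seeds by offset; the Leiden refinement is seeded); identical
  configuration and seed reproduce identical final labels bit for bit.

# Limitations

* Only the two-view path is validated; more views can be handled by
  progressive pairwise aggregation, but no claims are made for it.
* The greedy merge optimizes the tightness sum locally; no global
  optimality is implied.
* Stable but wrong single-view clusterings cannot be corrected by
  stability-guided merging — they look exactly like signal.
* In labels-only mode the caller is responsible for the perturbation
  scheme behind the replicate labelings; the package cannot verify it.
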