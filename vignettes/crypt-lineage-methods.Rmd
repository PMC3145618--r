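---
title: "Reconstructing cell lineages from microsatellite mutations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing cell lineages from microsatellite mutations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mslineage)
```

## The problem

Somatic microsatellite (MS) mutations accumulate with every cell
division, so in a mismatch-repair-deficient mouse the repeat counts of a
~120-locus panel act as a molecular division counter. From fragment-size
genotypes of single cells and whole colonic crypts, `mslineage`
reconstructs a cell lineage tree rooted at the zygote, estimates each
cell's *depth* (divisions since the zygote), locates each crypt's most
recent common stem cell (MRCSC), and tests whether labeled cell groups
form clades. A simulator generates the same kind of data under three
competing models of crypt stem-cell dynamics, providing ground truth for
every stage.

## Mutation model

Each locus-allele channel evolves independently. Per division it mutates
with probability $\mu$ (default $1/100$ per locus per division, the value
obtained by calibrating colon depths against the one-division-per-day
adult stem-cell clock). A mutation inserts or deletes one or two repeat
units; insertions and deletions are equally likely and single steps
outnumber double steps $r:1$ with $r = 7$ (measured on ex-vivo trees and
taken as a given parameter). The per-division net-change pmf is therefore

$$P(0) = 1-\mu,\quad P(\pm 1) = \frac{r}{2(r+1)}\mu,\quad
  P(\pm 2) = \frac{1}{2(r+1)}\mu .$$

At most one mutation event occurs per channel per division. The model has
no locus-specific or length-dependent rates and no point mutations; those
are deliberate simplifications shared by the estimator and the simulator.

The distribution of the net change after $t$ divisions is the $t$-fold
convolution of this pmf, computed exactly by iterated polynomial
multiplication. Tail entries whose cumulative mass falls below $10^{-14}$
are dropped (with one guard entry kept per side), so the support stays a
few standard deviations wide ($\sigma \approx \sqrt{1.375\,\mu t}$ repeat
units) and the pmf still sums to 1 within $\approx 10^{-10}$ even after
thousands of steps.

## Maximum-likelihood division distances

For two signatures the per-channel deviation differences $d_\ell = a_\ell
- b_\ell$ over channels measured in both cells are independent draws from
the $t$-step distribution, where $t$ is the number of divisions on the
lineage path between the cells. The estimate is

$$\hat t = \arg\max_{t \in \{0,\dots,t_{\max}\}} \sum_\ell \log P(d_\ell \mid t).$$

Numerical choices:

* the log-likelihood of every $(t, |d|)$ combination is precomputed once
  per model into a table, so the full-grid argmax is a single matrix
  product and exact by construction — no coarse-to-fine search is needed;
* differences outside the (truncated) support get the sentinel
  $\log P = -10^{18}$, so a $t$ that cannot produce an observed $|d|$
  (e.g. $|d| > 2t$) is never selected;
* ties pick the smallest $t$, which also makes identical signatures
  return exactly 0;
* `t_max` defaults to 3000 divisions — a generous bound for a mouse
  lifetime at up to three divisions per day;
* pairs sharing fewer than `min_shared = 10` loci are undefined; in the
  distance matrix they are imputed at the maximum defined distance
  (keeping neighbor joining total) and listed in `flagged_pairs`.

A worked consequence of the exact pmf: for two shared loci with
differences $(1, 0)$ at $\mu = 0.01$, the popular single-step
approximation $\hat t \approx -1/(2\ln 0.99) \approx 50$ is noticeably
off — the exact-likelihood argmax is $t = 64$, because return paths and
two-step events flatten the likelihood at larger $t$. The package (and
its independent closed-form oracle in the tests) returns 64.

## Trees, rooting, depths

Trees are built by canonical Saitou–Nei neighbor joining (via `ape`).
The tail sample — containing cells of all three germ layers, hence
carrying the zygote's alleles — is included as a leaf; its signature is
all-zero by construction, and the tree is re-rooted at its attachment
point. Negative NJ branch lengths are clamped to zero (counted and summed
in attributes). Depth is the root-to-node path length; the computed MRCSC
of a leaf set is its most recent common ancestor node. The median
signature of a crypt's cells (ties at even counts resolved toward zero,
the root state and parsimony-consistent choice) approximates the MRCSC's
signature and is how the simulator emits whole-crypt bulk DNA.

## Clade enrichment and replicate concordance

For every internal node holding $n$ of the $N$ sampled cells, of which
$b$ of the $B$ focal-type cells, the enrichment p-value is the
hypergeometric upper tail $\sum_{i \ge b} \binom{B}{i}\binom{N-B}{n-i} /
\binom{N}{n}$. The tail leaf is excluded from $N$: it is a rooting
device, not a sampled cell. The multiple-testing family is all internal
nodes of one tree for one focal group, corrected by Benjamini–Hochberg at
$q = 0.20$; the tree's headline clustering p-value is the smallest raw p
among surviving nodes. Raw and adjusted values are both reported.
Technical (PCR) replicates are assessed by their leaf-to-leaf path
distance against a resampled null of random same-tissue pairs.

## Depth statistics and calibration

Cohort medians carry a bootstrap standard error (2000 resamples, seeded);
the published ± values have no stated definition, so the bootstrap SE of
the median is used as the comparable uncertainty. Age contrasts use the
two-sample Kolmogorov–Smirnov test; depth-versus-age uses unweighted OLS
on cohort medians. Mutation-rate calibration exploits the adult clock:
the depth gap between cohorts, estimated under a trial rate, must equal
the age gap in days times one division per day; a fixed-point iteration
(tolerance 1% on the ratio, at most 20 rounds — in practice 2–4) updates
the rate multiplicatively. Doubling the assumed rate roughly halves every
inferred division count, which is what makes the iteration contract.

## What the simulator emulates — and what it does not

The generator encodes the study conditions: a 20-day embryonic phase at 3
divisions/day (60 embryonic divisions — the upper end of the known 1–3
range, chosen once so that embryonic ancestry is clearly visible in the
trees), adult colon stem cells at 1 division/day, a 45-day monoclonal
conversion interval, 120 loci of which half are X-linked (single-allele
in males), 10% allele dropout, and the mutation model above. Crypt
founders (and founders of any non-crypt groups such as B-lymphocyte-like
cells at one division per 4.5 days) branch off a random embryonic
genealogy; whole-crypt samples are emitted as the median signature of
that crypt's simulated cells; everything is converted to fragment sizes
around a synthetic root (second autosomal allele offset by 20 repeat
units so the two parental backgrounds stay distinguishable) and written
in the same table dialect the readers accept.

The three scenarios differ only in the adult phase. Under the immortal
strand, the crypt lineage accrues no replication mutations after
founding; sampled cells add 5 transit divisions. Under asymmetric-only
maintenance, every sampled cell descends directly from the founder stem,
so cells deepen with age while the MRCSC stays at founding depth. Under
ongoing monoclonal conversion the crypt MRCSC is pinned exactly one
conversion interval before sampling and each cell runs an independent
lineage from there. The pinned form (rather than re-seating at random
times) makes the true relative depth equal the interval times the
division rate — the quantity the reconstruction is asked to recover — at
the cost of ignoring conversion stochasticity. The simulator also ignores
spatial crypt geometry, mutation hotspots, selection, and WGA artifacts
beyond the missing-data mask; passing tests therefore show that the
*inference* works under the stated mutation process, not that real
capillary data are this clean.

## Known limitations

* **Star-resolution inflation of relative depths.** Cells of one crypt
  coalesce almost simultaneously, so their true subtree is a star.
  Neighbor joining resolves a noisy star into a binary tree with spurious
  positive internal edges, inflating MRCSC-to-leaf path lengths by about
  one SD of the pairwise-distance noise (≈ 10 divisions at 120 loci and a
  45-division interval, i.e. reconstructed relative depths run ~20–30%
  high of truth). The tests therefore verify the exact interval on the
  true tree and check reconstruction at order-of-magnitude level; the
  acceptance report carries the inflated value honestly. Depth *gains*
  between ages are unaffected, since the inflation is age-independent.
* **Depth estimates are marginally unbiased but noisy per cell** (SD ≈ 35
  divisions at 400 true divisions with 120 loci); cohort medians, not
  individual depths, are the meaningful output.
* **No joint tree likelihood.** Distances are estimated pairwise; a
  tree-wide likelihood or Bayesian reconstruction is out of scope.
* The published ± values and the exact inputs of the depth–age
  regression are not fully specified upstream, so those comparisons are
  qualitative.

## Problem sizes

The test suite and the acceptance script run mice with 2 crypts × 6
sampled cells plus 4–15 whole crypts per cohort (about 20–45 samples per
tree), 120 loci, and division grids up to a few thousand — sizes chosen
so a full run stays in the minutes range on a single core while keeping
cohort medians stable. Monoclonality detection is evaluated over 50
replicate simulations in the tests and 20 in the acceptance report;
calibration recovery is checked at μ ∈ {0.005, 0.01, 0.02} with 15 whole
crypts per cohort.
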