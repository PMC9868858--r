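---
title: "Three-facet beta diversity for paired road-disturbance surveys: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-facet beta diversity for paired road-disturbance surveys: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roadbeta)
```

## The question the package answers

Roads carve narrow, strongly modified corridors through otherwise natural
vegetation. A recurring observation is *biotic homogenization*: plant
communities along a road become more similar to one another than communities
in the adjacent interior vegetation are. `roadbeta` quantifies that loss of
between-community variety — beta diversity — in a paired sampling design
(each survey site contributes one roadside and one interior plot) and asks
whether the homogenization seen in species lists is mirrored in the
*functional traits* and the *evolutionary lineages* those species carry.

All computations work from presence/absence data. The unit of comparison is
the unordered pair of plots within the same category; roadside plots are
never compared with interior ones, because the question is about variety
*within* each habitat class.

## The partition at the core

For two communities, let `a` be the amount shared, and `b` and `c` the
amounts unique to each side. The Jaccard-family total dissimilarity and its
Podani-family decomposition into replacement and richness-difference
components are

$$\beta_{total} = \frac{b+c}{a+b+c},\qquad
  \beta_{repl} = \frac{2\min(b,c)}{a+b+c},\qquad
  \beta_{rich} = \frac{|b-c|}{a+b+c},$$

and the identity $2\min(b,c) + |b-c| = b+c$ makes the partition exact:
$\beta_{total} = \beta_{repl} + \beta_{rich}$, always. Replacement captures
turnover of equal numbers of elements; richness difference captures one side
simply having more.

What `a`, `b`, `c` *count* defines the facet:

* **Taxonomic** (`species_abc()`): numbers of species.
* **Functional** (`branch_abc()` on the UPGMA trait dendrogram): branch
  lengths of the dendrogram subtended by each community.
* **Phylogenetic** (`branch_abc()` on the phylogeny): branch lengths of the
  tree, i.e. shared and unique lineages. Because terminal branches dominate
  the branch sets, this is a *tip-weighted* phylogenetic beta diversity.

A community's branch set is the union of edges on the root-to-tip paths of
its members, taken from the **global root** of the supplied tree. We chose
global-root scoping (rather than re-rooting every pair at the MRCA of its
union) because "shared and unique lineages" reads most naturally as lineage
sets on one fixed tree, and because it makes the reduction property exact: on
a star tree with unit branches, branch-set `(a, b, c)` equals the species
counts, so the taxonomic facet is a special case of the branch machinery —
a property the test suite exercises on random data. Pair-wise MRCA scoping is
available as `branch_abc(..., mrca_rescope = TRUE)` since conventions differ
between software packages. Components are **length-weighted**, not edge
counts: lineage amount is naturally measured in branch length, and
unit-branch trees recover counts exactly.

### Basal-weighted phylogenetic beta diversity

The branch-set partition is insensitive to *where* on the tree differences
sit. As a complement, `mpd_between()` computes the mean patristic distance
over all ordered cross pairs of species, one from each community. Deep
divergences near the root dominate this quantity, so it is *basal-weighted*.
Species present in both communities enter as zero-distance pairs — the
standard between-community MPD convention; because the literature is not
unanimous, an `exclude_shared` flag averages over distinct-species pairs
only. On a star tree with branch length $L$, a community of $S$ species
compared with itself gives $2L(S-1)/S$, a closed form the tests check.

## The functional space

Mixed trait tables (quantitative and categorical columns, missing values
allowed) are turned into one global species-by-species Gower distance:
quantitative traits contribute $|x_i-x_j|/\mathrm{range}$, categorical
traits 0/1, and a pair's distance is the mean over the traits observed in
*both* species. Ranges are taken over the whole supplied table, not per
community: there is one functional space, matching the single dendrogram all
plots share. Two consequences worth knowing: a constant quantitative trait
is uninformative (contributes 0, with a warning), and the missing-data
renormalization means Gower values are dissimilarities, not guaranteed
metrics — the triangle inequality can fail, which is harmless here because
only the UPGMA dendrogram consumes them.

Whether an ordinal-looking trait is "quantitative" (rank scale) or
"categorical" is a declaration the user must make per column; no automatic
detection is attempted, because no rule survives contact with real trait
databases.

UPGMA (average linkage) turns the Gower matrix into an ultrametric
dendrogram: clusters merge at minimal distance, the merge node sits at half
the merge distance, and distances update as size-weighted averages.
Clustering is delegated to `stats::hclust`; on exact ties its deterministic
ordering decides, which can differ from a smallest-index rule but is
platform-stable, and exact ties have measure zero for continuous traits. The
tests verify ultrametricity (tolerance 1e-9) and equality of cophenetic
distances with an independent cubic-time reimplementation.

Before the functional space is built, quantitative traits pass a greedy
correlation screen (`prune_correlated()`, default Spearman, threshold 0.5,
columns scanned in their given order); the same screen thins collinear soil
variables before the distance exports. Greedy scanning in column order is
deliberately simple and deterministic; it is order-dependent, which is the
standard behaviour of such screens.

## Permutation statistics and their conventions

All permutation procedures are seeded, reproducible, and use the add-one
convention $p = (\#\{T_{perm} \ge T_{obs}\}+1)/(n_{perm}+1)$, so $p$ can
never be 0 and never falls below $1/(n_{perm}+1)$.

* **Mantel tests** (`mantel_test()`): Pearson correlation of the two
  lower-triangle vectors; the null jointly permutes rows and columns of the
  second matrix; one-tailed (greater), the standard convention for "are
  these distance structures positively associated". Lower triangles are
  vectorized in one fixed row-major (row > col) order everywhere, so the
  pair vectors of all facets and soil variables align; a 38-plot category
  gives 703 entries.
* **Blomberg's K** (`blomberg_k()`): the observed MSE ratio (tip variance
  about the phylogenetically corrected mean over phylogenetically corrected
  variance) scaled by its Brownian-motion expectation
  $(\mathrm{tr}(V) - n/\mathbf{1}^{\top}V^{-1}\mathbf{1})/(n-1)$, with $V$
  the tree's variance–covariance matrix. K is 1 in expectation under
  Brownian motion, near 0 for phylogeny-independent traits. Significance
  comes from shuffling tip values.
* **Paired sign-flip test** (`paired_signflip_test()`): two-sided test of
  zero mean paired difference by independent random sign flips. It stands
  in, clearly labelled, for a mixed-model category contrast: assumption-light
  and exact when the site differences are independent and symmetric.

### A calibration caveat that matters

The sign-flip test holds its level exactly on independent differences (the
suite verifies a type-I error within [0.03, 0.07] at $\alpha = 0.05$). But
the pipeline applies it to per-site differences of **per-plot mean beta**,
and those means are not independent across sites: every plot's mean shares
pairs with every other plot in its category. In null simulations (road
effect switched off) the empirical standard deviation of the mean site
difference is roughly 2.4 times what independent sign flips imply, so the
category-level test rejects far more often than $\alpha$. This is a
structural property of mean-of-shared-pairs statistics, not of the sign-flip
mechanics, and it equally afflicts mixed models fitted to the same per-plot
means. A level-correct alternative would permute category labels within
sites and recompute the beta means, but that requires cross-category plot
pairs, which this design never computes. Treat the pipeline's comparison
p-values as descriptive; the percent-change point estimates are unaffected.

## The synthetic study design

`sim_config()` fixes the conditions the generator emulates; its defaults
*are* the study design, chosen once:

| Knob | Default | Why |
|---|---|---|
| `n_sites` | 38 (76 plots) | the paired design size; gives 703 pairs per category |
| `n_species` | 300 | mid-range of a realistic regional pool for a desk-scale study |
| `birth_rate` | 1 (Yule) | simplest calibrated tree prior; tip-value SD ≈ 2.4 under unit-rate BM |
| traits | 9 quantitative + 3 categorical (4 levels), BM with $\sigma^2 = 1$ | mirrors a 12-trait mixed table; one trait (`trait09`) is tip-shuffled so the signal table has a negative control |
| `missing_rate` | 0.02 | exercises Gower's missing-data path without dominating it |
| `niche_width` | 1.5 | filter strong enough to structure communities, weak enough that plots hold ~100 species |
| environment | interior $N(0, 1)$, roadside $N(0.5, 0.4)$ | roadside conditions both shifted and *narrowed* — the filtering mechanism |
| `p_max` | 0.7 | occupancy ceiling; keeps presence/absence realistic rather than saturated |
| soil | pH 6.36 → 7.01, BK 0.90 → 1.15, TN 3.0 → 2.2 (+ 7 more) | road-shift directions and the pH values reported for this kind of system |

A species' niche optimum is its first Brownian trait value. That single
choice couples all three facets: filtering on the niche trait selects
phylogenetically and functionally similar species, so taxonomic, functional
and phylogenetic beta respond together — the correlation structure the
analysis is designed to detect. Occupancy is Bernoulli-independent across
species (filtering, not competition); empty plots are redrawn rather than
forced to a minimum richness, which avoids biasing composition while
honouring the nonempty-plot invariant. All randomness flows from one master
seed through fixed per-component offsets (tree, traits, communities, soil),
so each component is independently reproducible.

What the generator does **not** emulate: spatial autocorrelation along the
road, dispersal limitation, species interactions, abundance structure,
elevation gradients, and invasion dynamics of nonnative species. Passing
tests therefore demonstrate that the machinery recovers a planted filtering
signal at the design's size — not that any particular field system behaves
this way.

## Numerical choices and degenerate inputs

* Partition additivity is exact in floating point to well below 1e-12; the
  suite checks 10,000 random triples.
* `a + b + c = 0` (two empty branch sets) is an error, not a 0: the
  comparison is undefined.
* Distance matrices must be symmetric to 1e-12 with a zero diagonal;
  ultrametricity of UPGMA output is asserted to 1e-9.
* Trees without branch lengths are usable: every edge defaults to 1 with a
  warning, turning cladograms into edge-count analyses.
* Beta matrices set the diagonal to 0 by container convention; note the
  between-community MPD of a plot with itself is *not* 0 and is available
  through `mpd_between()` directly.
* The singular-$V$ case of Blomberg's K (zero-length terminal branches) is
  an explicit error rather than a silent pseudo-inverse.

## Problem sizes used by the test suite

The suite simulates everything it needs at run time: oracle-equivalence
checks use 6–30-taxon trees and 10–20-plot communities (hundreds of random
instances); calibration checks use a 50-tip tree with 200 Brownian
replicates and 500 permutation-test replicates at 199 permutations;
end-to-end recovery uses 50 replicate studies at the full default design
(38 sites, 300 species). These sizes were chosen so the full suite runs in a
few minutes while keeping every estimate's Monte Carlo error well inside the
asserted bands.

## Known limitations

* Presence/absence only; no abundance-weighted (Bray–Curtis/Baselga-family)
  decompositions.
* No mixed-model or SEM estimation: the per-plot mean tables and the
  703-row pair tables (`write_study_report()`) are exported precisely so
  those models can be fitted in dedicated software.
* The category comparison's permutation p-values are anti-conservative at
  the category level (see the calibration caveat above).
* Gower + UPGMA is one defensible functional space among several; no
  PCoA-quality diagnostics are provided.
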