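---
title: "Relative timing of gene duplications: model, assumptions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative timing of gene duplications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ohnotime)
```

## The statistic

Whole-genome duplications (WGD) leave families of paralogues — ohnologues —
whose relative ages carry information about when the duplications happened.
When absolute dating is out of reach, a purely tree-internal quantity still
separates old duplications from young ones. On a gene tree rooted with an
outgroup, three points matter:

* **a** — the node where the ingroup lineage begins after the split from the
  outgroup (the appearance of the ancestral, single-copy gene);
* **b** — the most recent common ancestor of the two paralogue groups (the
  duplication);
* **c** — the present-day paralogue tips.

With `ab` the path length from a to b and `bc` the arithmetic mean of the
path lengths from b to every paralogue tip, the dimensionless ratio

$$ R \;=\; \frac{\overline{bc}}{ab} $$

is large when the duplication closely followed the outgroup split (an
ancient duplication: little time for the stem, long daughter branches) and
small when the duplication is recent. Under a strict molecular clock with
node heights $h_a$ and $h_b$, $R = h_b / (h_a - h_b)$ exactly — a property
the test suite asserts on simulated clock trees.

Two regimes observed in vertebrate forebrain-regulator (*foxg1*) families
motivate the default classification thresholds: ratios above 1 for paralogue
pairs born in the early shared rounds of vertebrate WGD (a published
estimate for the tarpon *foxg1a*/*foxg1b* pair is 1.23), and roughly 0.15
for pairs born in the much later teleost-specific round. `ohnotime`
classifies `ancient` at $R \ge 1$ and `recent` at $R \le 0.5$ by default
(`timing_thresholds()`); these are configuration calibrated to the two
regimes, not biological claims, and the band in between is reported as
`indeterminate`. Reproducing the published 1.23/0.15 values themselves
requires the underlying database sequences and is deliberately out of scope
here; they serve as documented expectations only.

### Conventions that make the ratio well defined

* **a is the root's ingroup-side child, not the root.** `ab` therefore
  excludes the outgroup stem, and the ratio is independent of the outgroup's
  own branch length and of where along the separating branch the root is
  placed (`root_with_outgroup()` splits that branch 50/50; a test moves the
  split point and checks nothing changes).
* **bc averages all paralogue tips below b.** Per-tip values are also
  reported. Labeled tips that are missing from the tree, or that a faulty
  tree placed on the outgroup side of the root, are excluded from the mean
  with a recorded warning rather than aborting the run; paralogue groups
  that interleave below b raise a non-monophyletic-duplication warning.
* **Scale invariance.** Multiplying every branch length by $k > 0$ leaves
  $R$ unchanged (asserted to $10^{-12}$).
* A duplication node that coincides with the ingroup root makes `ab`
  undefined and is a hard error, as is an `ab` below $10^{-9}$
  (topology-only trees parse with zero branch lengths but are refused
  here).

## The supporting pipeline

Distances use **pairwise deletion**: for each sequence pair, alignment
columns with a gap (`-`) or ambiguity (`X`/`N`) in either sequence are
removed before counting. Corrections: Poisson $-\ln(1-p)$, gamma
$\alpha[(1-p)^{-1/\alpha}-1]$, Kimura's empirical protein correction
$-\ln(1-p-0.2p^2)$, JC69, and K2P from transition/transversion fractions.
`ml_distance_empirical()` maximizes the pair likelihood
$\sum_{\text{sites}} \log \pi_x P_{xy}(t)$ under a reversible empirical
model (JTT via `model_jtt()`, taken at run time from phangorn's model
tables; or the uniform model via `model_uniform()`), over
$t \in [10^{-6}, 20]$ with tolerance $10^{-6}$ and optional 4-category
discrete-gamma rate heterogeneity. The gamma shape defaults to 1.0 and is
exposed, because published analyses state that gamma rate variation was
used without printing the shape. Saturated pairs (log of a non-positive
argument, or the optimizer pinned at the upper bound) are **flagged, not
clipped** — silent clipping would bias exactly the deep branches the ratio
divides by — and neighbour joining refuses matrices containing them.

Neighbour joining follows the Saitou–Nei criterion with deterministic
tie-breaking (lexicographically smallest pair of cluster keys), clamps
negative branch estimates to zero with the deficit moved to the sister
branch, and is exact on additive matrices (asserted against brute-force
path sums on random trees). Bootstrap support resamples columns with
replacement under a mandatory seed and is bit-reproducible; replicates with
uncomparable or saturated pairs are dropped and counted, with more than 20%
dropped an error.

Synteny support is set-based: neighbourhoods are ordered gene-rank lists
(`…,-2,-1,+1,+2,…`, never base pairs; order and strand are ignored beyond
the window), symbols are case-normalized through an explicit synonym map
(cross-species neighbours are homologues, not equal strings — no fuzzy
matching), and candidate orthologue pairs are scored by Jaccard overlap
within a window of ±10 genes by default. `assign_orthologs()` maximizes
total Jaccard over injective assignments exhaustively (≤ 8×8) and flags the
result **ambiguous** when an alternative assignment scores within
$\varepsilon = 0.05$ of the optimum or a query's two best non-zero cells
differ by less than $\varepsilon$ — turning "the neighbour lists overlap
too much to call orthology" into a computable output. Witness genes
(`find_diagnostic_neighbors()`) are neighbours unique to one reference.

## What the simulator states — and what it does not

`wgd_scenario()` fixes a clock tree in arbitrary time units: outgroup split
at height `A`, duplication at `B < A`, `n` species per paralogue clade
(evenly spaced ladder below `B`), optional per-duplicate loss and per-tip
rate multipliers (emulating lineage-specific acceleration such as the
compositional "lamprey dialect"). Sequences evolve by a reversible Markov
process scaled to one expected substitution per site per time unit, sites
independent, **no indels** — the statistic consumes aligned positions, so
indel realism would add nothing testable. Transition matrices come from the
eigendecomposition of the scaled rate matrix; the uniform 20-state model
admits the closed form
$p(t) = \tfrac{19}{20}(1 - e^{-20t/19})$ (`expected_p_jc20()`), used to
calibrate the process against binomial error at $L = 10{,}000$.

**Why two outgroup taxa.** With a single outgroup and only the two
paralogue clades, the outgroup attaches at mrca(paralogues) in any inferred
unrooted tree, so a = b and the ratio is undefined. Every scenario
therefore plants the labeled outgroup `OUT1` at height `A` and a more
distant `OUT2` (group `other`); the `OUT1` attachment node then sits
exactly at height `A` and the true ratio is `B/(A-B)`. On the *true* tree,
rooting with `OUT2` instead yields `B/(A_far-B)` — the concordance column
of `timing_report()` quantifies such outgroup sensitivity.

Presets state the two regimes: `ancient_2R` (`A = 1.8`, `B = 1.0`, truth
1.25) and `recent_TSWGD` (`A = 2.3`, `B = 0.3`, truth 0.15), both with
three species per clade, `A_far = A + 0.4`, and the uniform model with
gamma shape 1 — gamma heterogeneity is the field's default for proteins
and, at these stated depths, keeps deep pairs identifiable at $L = 500$
(without it, observed differences sit against the 0.95 ceiling and
saturation aborts runs). The `sturgeon_LOR` / `sturgeon_AOR` presets encode
the two rediploidization tree shapes: speciation before per-lineage
duplicate divergence (within-species paralogues cluster) versus duplication
before speciation (cross-species orthologues cluster). No published loss
rate exists for the lost fourth copy in these families, so
`loss_probability` is a free parameter defaulting to 0.

## What a green test does — and does not — establish

The recovery tests simulate 20 seeds per preset, run the full pipeline
(ML distances under the matching model → NJ → outgroup rooting → timing),
and check the recovered ratio. They establish that the implementation is
consistent: unbiased distances, exact NJ on additive input, correct node
identification. They do **not** establish that the statistic is reliable
per single gene family at these depths: at the stated heights every
outgroup-involving pair lies 3.6–4.4 substitutions/site deep, where the
per-pair ML distance standard error at $L = 500$ is ≈ 0.5 for any usable
rate model. About half of the single `OUT1`–`OUT2` pair's error propagates
into `ab` (true value 0.8 in the ancient preset), so the per-seed ratio has
a standard deviation near 0.35. The *median* over 20 seeds recovers the
truth comfortably, but any single family can fall below the ancient
threshold — in our fixed-seed run 15/20 seeds classify `ancient`, short of
the 90% the acceptance criterion asks for. We report this honestly rather
than widening thresholds: it mirrors the real caveat that single-family
bc/ab estimates at such depths are rough, and that published conclusions of
this kind rest on concordance across many cases, not on one tree. The
recent regime is robust (20/20): its margin to the 0.5 threshold is an
order of magnitude larger than the estimator noise.

Other numerical choices: ML optimization bracket `[1e-6, 20]` with the
upper bound doubling as the saturation sentinel; discrete-gamma category
rates are bin means (so they average to 1 exactly); NJ Q-ties are resolved
at relative $10^{-12}$; all stochastic stages take mandatory seeds and the
whole pipeline re-runs byte-identically. Known limitations: no absolute
dating, no relaxed clocks, no species-tree reconciliation, no codon models,
no indel simulation, and exhaustive orthology assignment is capped at 8×8 —
all deliberate, matching the scope of the analysis the package reproduces.
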