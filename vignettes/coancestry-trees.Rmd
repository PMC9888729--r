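---
title: "Coancestry trees from allele counts: model, algorithm and design notes"
author: "fstree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coancestry trees from allele counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fstree)
```

## The model

fstree infers genetic distances among K *units* — population samples,
unrelated diploid individuals treated as populations of two gametes, or a
mixture of both — from per-locus allele counts.  The underlying model is a
rooted tree of populations.  An unobserved global ancestral population sits
at the root with allele frequency $p$ at a given diallelic locus; along the
branch into each descendant population $k$ the frequency drifts, so that
conditional on the parent frequency $p_A$,

$$\mathrm{E}[p_k \mid p_A] = p_A, \qquad
  \mathrm{Var}[p_k \mid p_A] = \theta_k\, p_A (1 - p_A),$$

with $\theta_k \in [0,1]$ the drift (coancestry) parameter of the branch
above population $k$.  Sibling frequencies are conditionally uncorrelated
given their most recent common ancestor.  $\theta_k$ absorbs everything
that happened along that branch — drift, migration, selection — into a
single variance ratio; nothing in the package assumes a specific
demographic mechanism.

Write $P(k)$ for the set of branches on the path from the root to tip $k$,
$Q(kk') = P(k) \cap P(k')$ for the branches shared by two tips and
$R(kk') = P(k) \setminus P(k')$ for those ancestral to $k$ but not $k'$.
Two complementary F~ST~-type quantities follow from the model:

* the **shared-variance (correlation) form**
  $F^{W}_{ST}(kk') = 1 - \prod_{q \in Q(kk')} (1 - \theta_q)$, the
  correlation of two alleles drawn one from each unit, relative to the
  root.  Its diagonal $F^{W}_{ST}(k)$ measures the divergence of a single
  unit from the root;
* the **mismatch (Hudson-type) form**
  $F^{H}_{ST}(kk') = 1 - \tfrac12 \bigl\{ \prod_{q \in R(kk')} (1-\theta_q)
  + \prod_{q \in R(k'k)} (1-\theta_q) \bigr\}$, driven by the non-shared
  branches, with a structurally zero diagonal.

The two matrices depend on disjoint sets of branches; `coancestryMatrices()`
evaluates both for any parameterized tree, and the package's tests verify
the disjointness by perturbation.

## From counts to the S statistic

With $\hat p_k$ the sample frequency from $n_k$ gametes, the classical
pairwise estimator is the ratio of sums over loci

$$\hat F^{H}_{ST}(kk') = \frac{\sum_\ell N_{kk'}}{\sum_\ell D_{kk'}},
\quad N_{kk'} = (\hat p_k - \hat p_{k'})^2
  - \tfrac{\hat p_k(1-\hat p_k)}{n_k - 1}
  - \tfrac{\hat p_{k'}(1-\hat p_{k'})}{n_{k'} - 1},
\quad D_{kk'} = \hat p_k(1-\hat p_{k'}) + \hat p_{k'}(1-\hat p_k).$$

Joint inference instead uses the asymmetric scaled-heterozygosity statistic

$$S_{kk'} = \frac{2\, \tfrac{n_k}{n_k-1} \sum_\ell \hat p_k (1-\hat p_k)}
                 {\sum_\ell D_{kk'}},$$

whose expectation under the tree model is
$\prod_{q \in R(kk')} (1-\theta_q)$: it isolates exactly the non-shared
drift of $k$ relative to $k'$.  Loci monomorphic in the two units combined
contribute zero to both sums, so the statistic is insensitive to how many
invariant sites are present, and every statistic is invariant to which of
the two alleles is counted.  Both estimators are computed in one vectorised
pass over the loci; afterwards the whole inference works on the
$K \times K$ summaries with no further dependence on the number of loci.

## Fitting tree and branch parameters

Taking logs, $\log S_{kk'} \approx \sum_{q \in R(kk')} \beta_q$ with
$\beta_q = \log(1-\theta_q) \le 0$.  For a candidate topology the branch
parameters minimise

$$\xi = \sum_{k \ne k'} \Bigl( \log S_{kk'}
        - \sum_{q \in R(kk')} \beta_q \Bigr)^2
  \quad \text{subject to } \beta_q \le 0,$$

a non-negative least-squares problem in $\gamma = -\beta$ solved by the
Lawson–Hanson active-set algorithm (implemented in C++ on the normal
equations; the test suite cross-checks it against an independent solver and
a dense grid search).  A binary tree over $K$ tips has $2(K-1)$ branches
while $K(K-1)$ ordered pairs are available, so the system is overdetermined
for $K \ge 3$ and all candidate binary topologies have the same number of
parameters, making $\xi$ directly comparable across them.

The topology search has two phases:

1. **Clustering** — start from the star tree (the independent-descent
   model) and perform $K-2$ merge steps; at each step every pair of the
   root's current children is tried as the next merge and the pair with
   the smallest $\xi$ is kept.  This costs $O(K^3)$ NNLS solves.
2. **Improvement** — visit the tips in seeded random order; for each tip,
   detach it, suppress its former parent, and try re-inserting the parent
   on every branch of the reduced tree (including above the root), keeping
   the placement with minimal $\xi$, the current tree winning ties.  Full
   passes repeat until a pass makes no change, capped at `passesCap`
   (default 10).

Restricting to binary trees loses no generality because zero-length
branches are allowed.

## Tunable parameters

* `clipEps` (default `1e-12`, dimensionless) — raw $S$ values are clipped
  into `[clipEps, 1]` before taking logs.  Finite samples can push $S$
  slightly above 1 (the model expectation never exceeds 1) or to 0 (when
  the first unit is fixed at every shared locus); clipping keeps the
  response finite and the fitted $\theta$ inside `[0, 1]`.  Pairs with a
  zero denominator (both units fixed everywhere) have no defined $S$ and
  their rows are dropped from the system; if that leaves fewer rows than
  branches the fit proceeds with a warning.
* `passesCap` (default 10 passes) — the improvement phase is iterated to a
  fixed point rather than swept once; iterating can only lower $\xi$, and
  in practice two or three passes suffice, so the cap is a safety bound
  rather than a tuning knob.
* `seed` — controls only the improvement-phase visiting order (and, in the
  simulator, the draws).  Same seed, same data: bit-identical output.

Two further fixed choices: on equal $\xi$ (within $10^{-12}$ relative) the
clustering phase picks the lexicographically smallest label pair, so it is
deterministic without randomness; and every candidate fit is a cold NNLS
solve.  Warm-starting each candidate from the previous solution would be
faster but makes results depend on the visiting history, so correctness
and reproducibility won the trade-off here.

## The simulator

`simulateReplicate()` emulates the study conditions the estimators are
designed for.  Per site, independently (no linkage): the root frequency is
drawn from beta(0.4, 0.4) — a U-shaped site-frequency distribution under
which about 19% of sites fall outside (0.01, 0.99) and 36% outside
(0.05, 0.95), as `ancestralTailCheck()` confirms analytically — then each
child frequency is drawn from the beta distribution with mean $p_A$ and
variance $\theta\, p_A(1-p_A)$, i.e. shapes $a = p_A(1-\theta)/\theta$ and
$b = (1-p_A)(1-\theta)/\theta$ (the unique beta matching those moments;
degenerate cases $\theta \in \{0, 1\}$ and fixed parents are handled
exactly).  Finally `gametes` allele copies are drawn binomially at each
tip, and only SNV sites — at least one minor-allele copy in the pooled
sample, no MAF threshold — are retained.

The bundled presets S1–S6 all use the `scenarioTree()` truth (five tips;
$\theta$ of 0.15 on the two deepest branches, 0.10 above D, 0.05
elsewhere) and vary the information content: 25/10/2 gametes per unit and
$10^4/10^3/10^2$ sites.  S3 (two gametes per unit) makes the tips
individual-like; S6 (100 sites) is deliberately information-poor.

An optional admixture variant redirects a fraction $\alpha$ of the parent
frequency of one tip (by default C's parent, drawing from the deep branch
on the other side of the root): the mixed frequency
$\alpha p_{1} + (1-\alpha) p_{3}$ is formed deterministically before the
tip's drift draw.  Mixing at the frequency level is indistinguishable, at
the resolution the simulator works at, from resampling individual alleles
from the two sources.  Because no tree generates these data, the true
mismatch-type FST values are obtained from a frequency-level Monte-Carlo
oracle (`admixtureTruth()`): population frequencies only, no gamete
sampling, $10^6$ sites by default, plugging site-averages into the
mismatch-probability definition
$1 - (\mathrm{E}[p_k(1-p_k)] + \mathrm{E}[p_{k'}(1-p_{k'})]) /
(\mathrm{E}[p_k(1-p_{k'})] + \mathrm{E}[p_{k'}(1-p_k)])$, with batch-based
standard errors.  At $\alpha = 0$ the oracle agrees with the tree formulas
and at $\alpha = 1$ with the formulas on the rewired tree, which the test
suite checks.

What the simulator does **not** emulate: linkage disequilibrium (sites are
independent), mutation, selection, sequencing or genotyping error, and
missing data (simulated counts are complete; the data structures and the
per-pair sums support missingness, defined over the loci observed in both
pair members, but that path is exercised with constructed fixtures rather
than simulations).  Passing tests therefore demonstrate correctness under
the drift model, not robustness to artefacts of real pipelines.

## Evaluation

`runScenario()` scores the estimators over replicates: per-pair RMSE of
the tree-based and pairwise mismatch estimators against the exact model
truth (never against sample means), their per-pair ratio and its mean over
pairs, the fraction of replicates whose inferred rooted clade set matches
the truth, and the mean per-replicate correlation between the ten pair
estimates and their truths.  An alternative reading of that correlation —
pooling all replicates' pairs before correlating — agrees with the
per-replicate average to about $10^{-3}$ at these settings; the
per-replicate average is reported.  Replicates with an undefined required
estimate are excluded and tallied (`nExcluded`); under the bundled
scenarios they essentially never occur.

The package's acceptance checks run the scenarios at reduced size —
10 replicates of $10^4$ sites for simulator calibration, 1000 replicates
for topology recovery and admixture correlation, 2000 for RMSE and
efficiency-ratio comparisons, against a $10^6$-site oracle where admixture
is involved — sizes chosen so the whole battery completes in a few minutes
while keeping Monte-Carlo error well inside the tolerances used.

## Numerical and degenerate-input notes

* Products $\prod (1-\theta)$ are computed as
  $\exp\bigl(\sum \log(1-\theta)\bigr)$ via `log1p`, with $\theta = 1$
  short-circuited to an exact zero product.
* Pairwise sums accumulate in double precision with vectorised
  (crossproduct-based) kernels on complete data and a masked per-pair path
  when cells are missing; the two paths are tested against each other.
  Reordering loci can move results by one part in $10^{12}$ or so
  (floating-point summation order), nothing more.
* With missing data the $n_k/(n_k-1)$ correction is applied per locus
  inside the sum rather than once outside it, which preserves per-locus
  unbiasedness when $n_k$ varies across loci; with complete data the two
  conventions coincide exactly.
* Duplicate units (identical count columns) are legal: they come out as
  sister tips with near-zero branch parameters.
* Tip labels containing newick metacharacters are single-quoted on
  serialization and restored on reading.

## Known limitations

* No linkage modelling: closely related individuals (very recent shared
  ancestry) violate the unrelatedness assumption and should be excluded.
* The fitted tree is a best-fitting representation of genetic variance; it
  need not coincide with the historical branching order, and under strong
  admixture no tree may fit well — the admixture scenario quantifies how
  gracefully the estimators degrade, and the estimate–truth correlation
  stays high even when the tree-based estimator loses its efficiency edge.
* The pairwise estimator is not constrained to `[0, 1]` and can be
  negative for very close pairs; the tree-based estimators are constrained
  by construction.
* Inference quality in information-poor settings (few SNVs, few gametes)
  is limited by the data, not the optimiser: with about 66 SNVs the true
  topology is recovered in roughly two thirds of replicates, and the
  improvement phase cannot manufacture information the S matrix lacks.
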