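---
title: "Joint and unique variation in multiblock data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint and unique variation in multiblock data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moca)
```

## The problem and the model

Descriptor tables for QSAR work arrive naturally partitioned into blocks —
all variables computed by one software package, or a panel of measured
biological endpoints — that share one set of compounds. The blocks overlap
heavily (most conventional descriptor packages encode molecular size one
way or another) yet each may carry information the others lack. `moca`
models this explicitly. For preprocessed blocks $X_1, \dots, X_N$ sharing
$n$ observations, every block is decomposed into

$$X_i = T_g P_{gi}' + T_{\ell i} P_{\ell i}' + T_{ui} P_{ui}' + E_i$$

with globally joint components (score direction present in all blocks),
locally joint components (present in $\ge 2$ but not all blocks), unique
components (one block), and an unmodelled residual. "Present in a block"
is an empirical statement about score similarity: each member block has its
own score vector for a joint component, and membership requires that vector
to correlate with the component's consensus score at
$|r| \ge 1 + \text{strictness}$.

The model is linear and assumes the shared structure is expressible as
common latent directions with block-specific loadings — the same assumption
underlying PCA, PLS and their multiblock descendants. Binary
fingerprint-like blocks violate it in spirit (their information is spread
over many tiny components) and are better analyzed separately.

## Preprocessing and the missing-value contract

All model fitting expects mean-centered blocks; by default columns are also
scaled to unit variance (`center_scale()`, standard deviation with the
$n-1$ denominator over *observed* cells). Constant columns must be removed
first (`remove_constant_columns()`, variance tolerance `1e-12`). Endpoint
concentrations are conventionally transformed to $-\log_{10}$ molar units
(`neg_log_molar()`) before modelling.

Missing cells are never imputed. Every iterative fit (PCA, PLS, OPLS, and
all internal deflations) skips missing cells in every inner product, which
is equivalent to giving them zero residual and zero leverage. Consequently
all explained-variance fractions are defined over observed cells only, and
residual matrices returned by the package are exactly zero at missing
positions. The practical limit of the contract: cross-product matrices
between blocks with heavy missingness are attenuated toward zero, which
makes joint-rank detection conservative rather than anticonservative.

## The five fitting steps and their thresholds

**1. Pairwise joint rank** (`fit_pairwise_joint()`). For each block pair,
both blocks are scaled to unit total sum of squares — this is what gives
every block equal weight regardless of its size — and the cross-product
$X_a'X_b$ is decomposed by SVD. Because of the norm equalization its trace
norm is at most 1, so each singular value is directly interpretable as a
fraction of the maximum attainable shared covariance, roughly
$\sqrt{f_a f_b}$ for a latent explaining fractions $f_a$, $f_b$ of the two
blocks; under independence the largest singular value shrinks as
$O(1/\sqrt{n})$. A direction is retained when its singular value exceeds
`sv_threshold` (default 0.02) **and** its paired score vectors correlate at
$|r| \ge 0.5$. The second condition matters: overfit cross-covariance
directions of unrelated variables can clear a small singular-value
threshold at moderate $n$, but their paired scores correlate weakly
(empirically $\sim 0.45$ at $n = 200$), far below any genuinely shared
structure worth modelling ($\ge 0.75$ in all our study conditions), so the
correlation gate removes them at the source.

**2. Compression** (`collect_and_compress()`). Each block's score vectors
from all its pairwise models are collected — on their natural scale, so a
direction's column norm reflects the covariance it carries — and an SVD
keeps the smallest orthonormal basis reaching `compress_r2 = 0.999`
cumulative variance. The tight default is deliberate: with spurious
directions already filtered in step 1, compression only needs to
deduplicate near-copies of the same latent seen through different
partners, and a looser cut (e.g. 0.98) measurably discards weak but
genuinely shared directions — a small endpoint-block component shared with
a large descriptor block contributes only about 1% of the descriptor
block's collected variance, and such small components are precisely the
interesting signal when a target block is in the model.

**3–4. Split and unique extraction** (`split_joint_unique()`,
`extract_unique()`). The joint part of a block is its regression onto the
joint basis (observed cells only); NIPALS PCA on the remainder yields
unique components. A unique component is kept only if it explains at least
`unique_r2 = 0.02` of the block's original sum of squares **and** exceeds a
noise floor: 1.05 times the sum of squares the leading principal component
of an i.i.d.-noise matrix of the same dimensions would capture (the
Marchenko–Pastur edge, $(\sqrt{n} + \sqrt{p})^2/(np)$ of the current
residual). Without the floor, small residual blocks always emit "unique"
components — the top noise eigenvalue of a 7-column residual carries about
20% of its variance — which contradicts how small endpoint blocks behave in
practice.

**5. Classification** (`classify_joint()`). Candidate components are
extracted iteratively: the leading principal direction of the pooled
remaining bases seeds a consensus score; each block contributes its
best-matching direction *within the span* of its remaining basis (the
normalized projection of the consensus onto the span — the compression
fixes only each block's joint subspace, not the orientation of individual
basis vectors, so matching raw basis columns across blocks would be
rotation-sensitive and unreliable); consensus and matches are re-estimated
until stable; matched directions are deflated and the process repeats.

Two design points deserve emphasis:

* *The candidate structure does not depend on strictness.* The consensus
  refinement and deflation operate on all blocks passing a fixed relevance
  gate ($|r| \ge \min(1+\text{strictness},\ 0.5)$, i.e. constant 0.5 for
  all strictness settings down to $-0.5$). Strictness only decides which
  gated blocks are *labeled* members. Relaxing strictness therefore only
  ever adds members to a fixed set of candidates, which makes each block's
  joint explained variance non-decreasing as strictness is relaxed — a
  property the strictness sweep relies on, and one that a fully greedy
  threshold-dependent classification does not in fact guarantee (different
  thresholds then carve the bases into different partitions, and we
  observed violations up to 0.1 in joint variance before adopting this
  design). Below strictness $-0.5$ the gate follows the threshold and the
  guarantee weakens; such settings are rarely meaningful.
* *The strictness test is against the consensus score* (the "final loading
  vector"), not pairwise between members. For heterogeneous components —
  a noisy endpoint block joining several well-correlated descriptor
  blocks — pairwise correlations sit noticeably below each member's
  consensus correlation, and requiring the pairwise bound would reject
  components of exactly the kind a relaxed-strictness analysis is meant to
  find. Variance along basis directions that fail membership returns to
  the block's residual and is picked up, if systematic, by the unique
  extraction.

Variance bookkeeping is sequential: member score vectors are deflated from
each block one at a time with observed-cell regressions, and every
explained fraction is a measured drop in residual sum of squares. By
telescoping, `r2xj + r2xu + r2_residual = 1` holds per block to floating
precision, with or without missing values, at every strictness.

## Strictness in practice

The default is $-0.03$ (membership at $|r| \ge 0.97$), a strict setting
appropriate for calling blocks redundant. Under heavier noise the
*estimated* score vectors of a genuinely shared factor decorrelate: with a
factor explaining 40% of a block's variance and observation noise of the
magnitude used in our simulations, block-to-consensus correlations land
near 0.96–0.99, and weak target-block factors near 0.85–0.92. A strict
threshold rejects these *by design* — that is what strictness means — so
analyses that specifically look for weaker cross-block structure (a small
noisy endpoint block) should relax to about $-0.2$, which is also the
setting used throughout our recovery simulations. The strictness sweep
(`strictness_sweep()`) makes the trade-off visible, and its
mean-center-only meta-PCA of the R2Xj table (center-only because all
entries share the 0–1 scale and a common mechanism) summarizes whether
relaxation changes the structure of the block overlap or merely the amount
of variation called joint; on the bundled example table one component
carries 94% of the variance, i.e. only the amount changes.

## The synthetic-data generator

`generate_multiblock()` emulates the structure the model assumes: latent
factor scores drawn as Gaussian vectors, orthogonalized and scaled to unit
variance; each block a sum of its member factors times fixed unit-norm
random loading vectors plus i.i.d. Gaussian noise; optional
missing-at-random masking; everything deterministic given the seed.
Factor strengths are specified as design variance fractions and the
amplitudes solved so the expected share matches. The default study
conditions — 200 observations, three blocks of 30/50/80 variables, one
global factor (design share 0.4), one local factor over the first two
blocks (0.2), one unique factor per block (0.15), noise sd 0.3 — reflect
descriptor-block practice, where a dominant size-related component
commonly explains 30–45% of a conventional block. The
`pesticide_like_fixture()` adds a realistic target scenario: five
descriptor-like blocks plus a 7-variable endpoint block with 30% missing
cells, a strong global factor loading on everything, one descriptor-only
local factor, and two small endpoint-joint factors (target shares 0.17 and
0.09) that only a relaxed strictness can recover.

What the generator does *not* emulate: count- or fingerprint-valued
descriptors, heavy-tailed or discrete distributions, structured
missingness (real endpoint panels lose whole assays, not random cells),
and inter-species correlation patterns beyond generic shared latents.
Passing recovery tests therefore demonstrates correctness of the
decomposition under its own model assumptions, not robustness to every
real-data pathology.

Test and simulation sizes throughout the package (e.g. 10 recovery seeds,
20 null seeds, $n = 200$–$300$) are chosen to make the checked properties
statistically unambiguous while keeping a full test run in well under a
minute per file.

## Numerical choices

* NIPALS convergence: relative change of the score vector
  $\|t_{new}-t_{old}\|/\|t_{new}\| \le$ `tol` (default `1e-9`), at most
  `max_iter = 500` iterations; non-convergence returns the component
  flagged with a warning. Near-tied eigenvalues converge slowly
  (the rate is the eigenvalue ratio), so comparisons against exact SVDs in
  the test suite raise the iteration cap instead of loosening tolerances.
* Initialization is deterministic: the column of largest observed variance.
  No random numbers are used anywhere in fitting; only the generator
  consumes seeds.
* Sign conventions: every loading/direction vector is flipped so its
  largest-magnitude element is positive; consensus members are
  sign-aligned to the consensus (or, in `consensus_and_disagreement()`, to
  the first member). Reported correlations in the block metrics are
  absolute values, since score signs are arbitrary up to these
  conventions; a signed variant can only be smaller.
* Explained variance is always a measured residual sum-of-squares drop
  over observed cells, never a formula evaluated from loadings — this is
  what makes the conservation identity exact under missingness.
* Degenerate inputs fail early with named offenders: columns with fewer
  than two observed cells, constant columns under unit-variance scaling,
  zero-variance blocks, constant responses in OPLS, more latent factors
  than $\min(n, p)$ in the generator.
* Cross-validated $Q^2$ in `fit_pls()` uses 7 contiguous folds by
  observation order — deterministic and adequate for randomly ordered
  observations; shuffle the rows first if the input has a meaningful
  order.

## Known limitations

* Component-count rules based on cross-validated significance (as used by
  commercial implementations) are not replicated; the package uses
  explicit thresholds, all exposed in `moca_options()`. As a consequence,
  weak borderline structure may land on either side of the joint/unique
  split near the thresholds, and small "unique" components can appear in
  small blocks as the unexplained tails of accepted joint components.
* Multi-response OPLS is not implemented; `fit_pls()` (PLS2) covers the
  multi-response case and single-response `fit_opls()` the interpretable
  two-part split.
* The jackknife loading intervals assume exchangeable observations and a
  stable component ordering between refits; with near-degenerate
  eigenvalue spectra the sign-alignment can pair different subspaces and
  the intervals become conservative.
* Redundancy and predictivity inherit the joint decomposition: a factor
  rejected as joint contributes to neither metric even if a bespoke
  two-block regression would find it.
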