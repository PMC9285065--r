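# moca — Multiblock Orthogonal Component Analysis

Data tables in QSAR and cheminformatics projects are often organized in
**blocks**: all molecular descriptors computed by one software package form
one block, a panel of biological endpoints another, and all blocks share the
same compounds. `moca` decomposes such multiblock data into

- **globally joint** components — systematic variation present in *every*
  block,
- **locally joint** components — variation shared by a strict subset of at
  least two blocks, and
- **unique** components — variation found in exactly one block,

plus an unmodelled residual per block, in the OnPLS/O2PLS family of latent
variable methods. The decomposition answers practical questions such as
*which descriptor packages are redundant and can be dropped?* and *which
block is most promising for predicting the biological endpoints?* without
fitting a separate regression model per block.

## The model

Each preprocessed block `X_i` (mean-centered, usually unit-variance scaled)
is decomposed as

```
X_i = T_g P_gi' + T_li P_li' + T_ui P_ui' + E_i
       global      local        unique      residual
```

where the global/local score vectors of different member blocks are
constrained to be similar: a component is accepted as joint only when each
member block's score vector correlates with the component's consensus score
at `|r| >= 1 + strictness`. The **strictness** parameter lives in `[-1, 0)`
— the closer to 0 the stricter (default `-0.03`, so `|r| >= 0.97`). The
fitting algorithm proceeds in five steps: pairwise joint-rank estimation
for every block pair (SVD of the norm-equalized cross-product, so every
block enters with equal weight regardless of size), per-block compression
of the pairwise scores into a joint basis, splitting each block into joint
part and residual, extraction of unique components from the residuals, and
classification of the joint bases into global and local components under
the strictness rule.

All fitting goes through NIPALS-type iterations that skip missing cells in
every inner product, so missing values need no imputation, have zero
residual and no leverage.

Two block-level decision metrics summarize a fitted model for a target
block `T` (e.g. biological endpoints):

- **redundancy** `R_T = Σ_j R2Xj_T · max_A |corr(t_jA, t_jT)|` — how well
  the target's joint information is already covered by the best-correlated
  other block (high ⇒ the block can be dropped);
- **predictivity** `P_A = Σ_j R2Xj_T · |corr(t_jA, t_jT)|` — the fraction
  of the target block's variance block `A` could explain in a regression,
  estimated from the single multiblock model.

## Worked example

```r
library(moca)

# three synthetic descriptor-like blocks (30/50/80 variables, 200 compounds)
# with one planted global factor, one local factor shared by A and B, and
# one unique factor per block, noise sd 0.3
sim <- generate_multiblock(synthetic_spec(seed = 1))
fit <- moca(sim$data, strictness = -0.2)
fit
#> Multiblock orthogonal component model: 3 blocks, 200 observations
#>   strictness -0.2: 1 global, 1 local, 9 unique component(s)
#>              A     B     C
#> R2Xj     0.538 0.524 0.279
#> R2Xu     0.254 0.165 0.178
#> residual 0.208 0.311 0.543
```

The planted structure is recovered: one global component over all three
blocks, one local component over exactly `A+B`, and per-block unique
components; `R2Xj + R2Xu + residual = 1` per block by construction. The
block metrics:

```r
summary(fit)          # per-component table (kind, members, mean R2)
redundancy(fit, "A")          #> 0.523  — A's joint part is nearly fully
                              #   covered by the best other block
predictivity(fit, "A", "C")   #> 0.273  — A could explain ~27% of C,
                              #   essentially all of C's joint variance
recovery_report(fit, sim$truth)  # matched components vs planted factors
```

Relaxing strictness moves variance from unique to joint; the sweep
summarizes this with a mean-center-only meta-PCA of the R2Xj table:

```r
sw <- strictness_sweep(sim$data, c(-0.01, -0.03, -0.05, -0.1, -0.2, -0.5))
sw$table          # conditions x blocks, non-decreasing down each column

# the bundled 12-condition x 11-descriptor-block example table
ex <- strictness_sweep_example()
pca <- r2xj_table_pca(ex$r2xj)
100 * pca$r2[1]   #> 94.1  — one dominant component: relaxing strictness
                  #   changes how much variation is called joint, not the
                  #   structure of the block overlap
```

CSV datasets with a YAML/JSON block configuration are read with
`read_dataset()`; fitted models serialize to JSON + TSV via `write_moca()`.
A thin command-line interface with `fit`, `summary`, `metrics`, `sweep` and
`simulate` subcommands ships in `inst/cli/moca.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","moca.R",package="moca"))')" \
    fit --data data.csv --blocks blocks.yaml --strictness -0.03 --out model/
```

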