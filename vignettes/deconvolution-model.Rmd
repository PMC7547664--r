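---
title: "Model and methods behind spotdecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind spotdecon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotdecon)
```

# The problem

A spatial transcriptomics capture location ("spot") collects transcripts
from the handful of cells lying on top of it, so its count vector is a
mixture of the expression profiles of several cell types. Given an
annotated single-cell RNA-seq reference from the same tissue, spotdecon
estimates, for every spot, the proportion of its transcript mass
attributable to each reference cell type.

# The model

## Single-cell reference (step 1)

Counts of gene $g$ in cell $c$ of type $z_c$ are modelled as negative
binomial,

$$y_{gc} \sim \mathcal{NB}(s_c\, r_{g z_c},\, p_g), \qquad
  s_c = \sum_g y_{gc},$$

with a rate $r_{gz} > 0$ per gene and type, a success probability
$p_g \in (0,1)$ per gene shared across types, and the cell's library size
$s_c$ absorbing sequencing depth. The convention is pinned so that the
mean is $s_c r_{gz} p_g / (1 - p_g)$ and, crucially, rates are additive:
$\mathcal{NB}(r_1, p) + \mathcal{NB}(r_2, p) \sim \mathcal{NB}(r_1 + r_2, p)$
whenever $p$ is shared. Sharing $p_g$ across types is exactly what makes
a sum over cells of different types stay inside the NB family.

The parameters are maximum-likelihood estimates: the negative
log-likelihood is minimized by first-order gradient descent (Adam, all
moment parameters at their defaults, only the learning rate exposed).
Positivity of $r$ is enforced by a softplus transform of an unconstrained
matrix and $p$ by a sigmoid of a logit vector. Because counts are raw,
no normalization or log-transform is applied anywhere.

## Spatial mixture (step 2)

A spot's counts are the sum of the (unobserved) per-cell contributions,
so with shared $p_g$ the additive property collapses the sum
analytically:

$$x_{sg} \sim \mathcal{NB}\!\left(\beta_g \sum_z v_{sz}\, r_{gz}
  + \gamma_s\, \mathrm{softplus}(\epsilon_g),\; p_g\right).$$

* $v_{sz} > 0$ is a *scaled quantity coefficient*: the product of a
  spot-level scaling factor and the number of type-$z$ cells at $s$.
  Only the product is identifiable, which is why absolute cell numbers
  are out of reach but proportions are not.
* $\beta_g > 0$ is a per-gene technique bias correcting capture
  efficiency differences between the single-cell and spatial assays; it
  is shared by all spots fitted together.
* $(\gamma_s, \epsilon_g)$ form a *dummy cell type* with free gene rates:
  it absorbs transcripts from cell types absent from the reference and
  other structured noise. A standard normal prior on the unconstrained
  $\epsilon_g$ (a $\tfrac12\sum_g \epsilon_g^2$ penalty) keeps the dummy
  from grabbing explanatory power it does not need. All other parameters
  carry flat priors.

$r$ and $p$ are frozen at their step-1 values; $v$, $\beta$, $\gamma$,
$\epsilon$ are the MAP estimate obtained by minimizing the negative log
posterior with the same optimizer. Proportions normalize each spot's
quantities over the reference types, excluding the dummy:

$$w_{sz} = \frac{v_{sz}}{\sum_{z'} v_{sz'}},$$

and the dummy's unnormalized weight is reported separately as
$\gamma_s / (\gamma_s + \sum_z v_{sz})$.

One subtlety in this construction: a normal prior is placed on a
quantity that must be positive inside an NB rate. We resolve it by
passing $\epsilon_g$ through softplus inside the rate while placing the
prior on the unconstrained parameter; this keeps the prior exactly
standard normal and the rate positive.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `epochs` | 50000 | Adam steps; the reference setting used for real data |
| `learning_rate` | 0.01 | Adam step size (other Adam parameters fixed at defaults) |
| `top_genes` | 5000 | genes kept, ranked by total single-cell expression |
| `lower`, `upper` | 25, 250 | per-type cell bounds for reference subsampling |
| `lb`, `ub` (generator) | 10, 30 | cells per synthetic spot (1-10 emulates Visium-scale spots) |
| `alpha` (generator) | 1 | per-cell count scaling when pooling cells into spots |
| `reps` (Dirichlet null) | 1000 | null-distribution repetitions |
| `alpha_level` (co-localization) | 0.01 | significance threshold on raw two-sided p-values |

# Numerical choices

**Initialization.** For step 1 the default start is method-of-moments:
$r_{gz}$ begins at the per-type mean of $y/s$, which is mean-consistent
with the $p = 0.5$ start. A generic small random start
(`init = "random"`) is also available, but it costs many thousands of
extra epochs: the likelihood has a curved ridge between $r$ and $p$
(both can trade off to match the mean), and a first-order optimizer
crawls along it. The moments start lands on the ridge directly and the
two starts reach the same optimum — we verified that the long random-init
run and the short moments-init run agree to four digits in the recovered
parameters.

For step 2 the default start is small random values, which works well
when $\beta$ is estimated: the shared bias absorbs the overall count
scale, per-spot quantities stay small, and their *ratios* — the only
thing proportions depend on — converge quickly. When $\beta$ is fixed
at 1 the quantities themselves must reach the library-size scale, and
because softplus is asymptotically linear the optimizer covers that
distance only linearly in the number of epochs; `init = "scaled"`
(automatic in that case) therefore starts each spot at the value whose
predicted total matches its observed total. With reduced epoch budgets a
modestly larger learning rate (0.02-0.1) is appropriate for step 2; the
proportion estimates converge long before the absolute scale does.

**Other choices.**

* Ties in top-gene selection break by ascending lexicographic gene id,
  so selections are platform-independent.
* The generator's nearest-integer operation rounds half away from zero.
* If all of a synthetic spot's type counts round to zero, the
  largest-proportion type gets one cell; if a type's demand exceeds its
  available cells, it is capped (sampling is without replacement) and
  the recorded truth renormalized.
* Cells with zero library size and genes with zero total count are
  dropped before step 1 (their parameters are unidentifiable); spots
  with zero total count are dropped before step 2. All with warnings.
* Proportion tables are validated to sum to 1 per row within 1e-6; the
  dummy share is excluded from that normalization by construction.
* Every randomized routine takes an explicit seed and uses a local RNG
  stream, so composed calls are reproducible and never disturb the
  caller's RNG state.

# The synthetic generators

`generate_nb_sc()` samples annotated single-cell data directly from the
step-1 model with known parameters; it exists so parameter recovery can
be tested against a known truth. `generate_spots()` is deliberately
*not* model-based: it pools the counts of real (or simulated) cells —
drawing the number of cells, the number and identity of present types,
and Dirichlet proportions per spot — so that benchmarks built with it do
not favour the NB model family by construction. The
generation/validation split (stratified halves sharing no cells, odd
cell to the generation side) prevents information leakage between spot
assembly and the reference fit.

What the generator does **not** emulate: spatial autocorrelation between
neighbouring spots, segmentation errors, bleed-over between adjacent
capture locations, and platform-specific capture-efficiency profiles
(a global `alpha` is the only depth knob). Passing benchmarks on these
spots therefore demonstrates correct inference under the stated mixture
assumptions, not robustness to every artefact of real arrays.

The evaluation protocol scores per-spot RMSE between estimated and true
proportions, compares methods with a one-sided paired Wilcoxon
signed-rank test across spots, and contextualizes RMSE against a null
of flat-Dirichlet draws. The null is scored draw-vs-truth (a
draw-vs-draw variant is available behind `compare = "draws"`); the
recorded ground truth is the per-spot normalization of the rounded cell
counts.

# Problem sizes used in the packaged checks

The packaged tests and the acceptance script run at desk scale, chosen
once as representative: parameter recovery uses 3 types x 100 genes x
200 cells per type (3000 epochs); the deconvolution benchmark uses 5
types, 200 genes, 1000 source cells split in half, and 200 spots in the
10-30 cells regime (3000/4000 epochs, learning rate 0.02 for step 2);
the withheld-type study uses 5 types with one withheld, 120 genes and
100 spots. The generator itself handles the full 1000-spot x 500-gene
configuration in well under a minute; fitting budgets simply scale with
`epochs x cells x genes`.

# Known limitations

* Absolute cell counts per spot are not identifiable (only proportions).
* The dummy share is a ratio of quantities on different scales ($\gamma$
  multiplies free rates, $v$ multiplies reference rates), so it is a
  relative indicator across spots of one fit, not a calibrated fraction.
* All spots passed to one `fit_st()` call share one $\beta$; sections
  from different batches should be fitted separately if their biases
  differ.
* Gene matching is exact, case-sensitive string equality; no alias
  resolution is attempted.
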