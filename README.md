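# spotdecon

Probabilistic cell-type deconvolution of spatial transcriptomics spots
from an annotated single-cell RNA-seq reference.

A capture location on an ST/Visium-style array (or a Slide-seq bead)
collects transcripts from the several cells lying on it. Given raw
single-cell counts with cell-type labels, spotdecon estimates for every
spot the proportion of its transcript mass contributed by each reference
cell type — the input to mapping cell types across a tissue section and
to asking which types co-localize.

## The model

Both assays are modelled with negative binomial counts sharing a
per-gene success probability, which makes rates additive across the
cells in a spot:

**Step 1 (reference, maximum likelihood).** For cell *c* of type
*z<sub>c</sub>*:

> y<sub>gc</sub> ~ NB(s<sub>c</sub> r<sub>g z_c</sub>, p<sub>g</sub>),
> &nbsp; s<sub>c</sub> = Σ<sub>g</sub> y<sub>gc</sub>

with rate r<sub>gz</sub> > 0 per gene and type, success probability
p<sub>g</sub> shared across types, and the library size s<sub>c</sub>
absorbing depth.

**Step 2 (spatial, maximum a posteriori).** With r and p frozen:

> x<sub>sg</sub> ~ NB(β<sub>g</sub> Σ<sub>z</sub> v<sub>sz</sub>
> r<sub>gz</sub> + γ<sub>s</sub> softplus(ε<sub>g</sub>), p<sub>g</sub>)

where v<sub>sz</sub> is a per-spot scaled quantity coefficient,
β<sub>g</sub> a per-gene technique bias between assays, and
(γ<sub>s</sub>, ε<sub>g</sub>) a noise-absorbing **dummy cell type**
whose free rates carry a standard normal prior. Proportions are the
per-spot normalization w<sub>sz</sub> = v<sub>sz</sub> / Σ<sub>z'</sub>
v<sub>sz'</sub>, dummy excluded. Both steps optimize with Adam (only the
learning rate exposed) on softplus/sigmoid-parameterized unconstrained
variables.

The package also ships the semi-synthetic benchmark machinery: a spot
generator that pools real cells (so benchmarks do not favour the NB
family by construction), a generation/validation splitter, a fully
synthetic NB single-cell generator for parameter-recovery studies, and
the evaluation toolkit (per-spot RMSE, one-sided paired Wilcoxon
comparison, flat-Dirichlet RMSE null, cell-type co-localization, and
max-scaling for display). See the methods vignette
(`vignettes/deconvolution-model.Rmd`) for assumptions, initialization
strategy and limitations.

## Worked example

Build a synthetic benchmark, deconvolve it, and score the result:

```r
library(spotdecon)

# a fully synthetic reference: 4 cell types, 150 genes
truth <- withr::with_seed(7, {
  raw <- matrix(exp(rnorm(150 * 4, 0, 1.3)), 150, 4)
  nb_ground_truth(sweep(raw, 2, colSums(raw), "/"),
                  probs = runif(150, 0.2, 0.8), lib_size = 1200)
})
ref <- generate_nb_sc(truth, cells_per_type = 150, seed = 1)

# assemble 100 semi-synthetic spots from half the cells,
# deconvolve them against the other half
halves <- split_generation_validation(ref$counts, ref$annotation, seed = 2)
spots <- generate_spots(halves$generation$counts, halves$generation$annotation,
                        n_spots = 100, lb = 10, ub = 30, seed = 3)

scfit <- fit_sc(halves$validation$counts, halves$validation$annotation,
                fit_config(epochs = 2000, seed = 4))
#> <sc_fit> 150 genes x 4 cell types (from 300 cells)
#>   NLL 101144.69 -> 99600.16 over 2000 epochs

stfit <- fit_st(spots$counts, scfit,
                fit_config(epochs = 3000, learning_rate = 0.02, seed = 5))
w <- compute_proportions(stfit)
print(w, n = 3)
#> # A tibble: 100 × 6
#>   spot       type1  type2     type3   type4 dummy_share
#>   <chr>      <dbl>  <dbl>     <dbl>   <dbl>       <dbl>
#> 1 spot_1 0.0000337 0.148  0.0000294 0.852        0.0772
#> 2 spot_2 0.476     0.0725 0.450     0.00163      0.185
#> 3 spot_3 0.000237  0.0785 0.332     0.590        0.181
```

Each row is one spot on the proportion simplex over the reference types;
`dummy_share` is the relative weight the noise-absorbing dummy type took
for that spot. Scoring against the generator's ground truth:

```r
rr <- rmse(w, spots$truth)
nul <- dirichlet_null(spots$truth, reps = 1000, seed = 6)
c(mean_rmse = mean(rr$rmse), null_mean_rmse = mean(nul$mean_rmse))
#>      mean_rmse null_mean_rmse
#>     0.08526951     0.34761115
```

A mean per-spot RMSE of 0.085 against a flat-Dirichlet null of 0.348
means the fit recovers the true mixtures about four times more
accurately than uninformed guessing on the simplex. Which types share a
spatial distribution:

```r
tidy(colocalization(w))
#> # A tibble: 6 × 5
#>   type_a type_b estimate     p_value significant
#>   <chr>  <chr>     <dbl>       <dbl> <lgl>
#> 1 type1  type2   -0.336  0.000637    TRUE
#> 2 type1  type3   -0.192  0.0552      FALSE
#> 3 type1  type4   -0.502  0.000000104 TRUE
#> 4 type2  type3   -0.501  0.000000113 TRUE
#> 5 type2  type4    0.0124 0.903       FALSE
#> 6 type3  type4   -0.463  0.00000123  TRUE
```

Mostly negative correlations are expected here: the generator assigns
types to spots independently, so types compete for each spot's simplex.

`autoplot()` methods draw loss curves for both fit objects and a
correlation heatmap for `colocalization()` results;
`plot_proportions()` gives a coordinate-free per-type occupancy strip.
A command-line wrapper over the same functions lives in
`inst/cli/spotdecon.R` (subcommands `fit-sc`, `fit-st`, `simulate`,
`evaluate`, `coloc`).

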