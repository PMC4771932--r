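# decaywood

Statistical pipeline for microbial community succession along a wood-decay
gradient, for microbial ecologists working with amplicon count tables from
decaying-wood surveys (bacterial 16S and fungal ITS OTU tables with wood
chemistry measured per sample).

Dead wood decomposes through successive stages in which wood density
falls, pH and C/N drop, moisture and fungal biomass rise, and the
bacterial community restructures. `decaywood` implements the complete
analysis such surveys use:

- **rarefaction + alpha diversity** (bias-corrected Chao1
  `S_obs + F1(F1−1)/(2(F2+1))`, Shannon `H = −Σ p_i ln p_i`) with OLS
  regressions of diversity against wood density;
- **decay-stage partitioning** by a multivariate regression tree on
  Bray–Curtis dissimilarity (`d = Σ|x−y| / Σ(x+y)`), with distance-based
  impurity `Σ_{i<j} d²(i,j)/n` and leaves named early/middle/late by
  descending density;
- **Metastats-style differential abundance**: Welch t on relative
  abundances with a permutation null (add-one p, `p ≥ 1/(B+1)`) and
  Benjamini–Hochberg q-values;
- **genus co-occurrence networks**: all-pairs Pearson r with
  `t = r√((n−2)/(1−r²))` p-values, edges at `|r| > 0.80` and FDR-adjusted
  `p < 0.05`, degree statistics, Cytoscape-readable exports;
- **neutral vs niche community assembly** — the core: each sample's rank
  abundance distribution is fitted to the broken-stick, niche-preemption,
  log-normal, Zipf and Zipf–Mandelbrot models (Poisson likelihood) and to
  the zero-sum multinomial of neutral theory via an exact, log-space
  implementation of the Etienne sampling formula; models are compared by
  `AIC = −2 logL + 2 npar` and Akaike weights
  `w_i = exp(−ΔAIC_i/2)/Σ exp(−ΔAIC/2)`;
- a **synthetic decay-study generator** with known ground truth (density
  bands, planted correlations, per-stage assembly mechanism) so the whole
  pipeline is testable without sequence data.

See `vignettes/assembly-models.Rmd` for the models, their assumptions and
the package's design choices.

## Worked example

```r
library(decaywood)
library(dplyr)

study <- simulate_decay_study(seed = 7)   # 19 parents x 3 replicates
rar   <- rarefy(study$bacteria, depth = 1080, seed = 7)
div   <- diversity_table(rar)
regress_diversity(div, study$metadata)
#> # A tibble: 2 × 7
#>   metric    slope intercept      r r_squared  p_value     n
#>   <chr>     <dbl>     <dbl>  <dbl>     <dbl>    <dbl> <int>
#> 1 chao1   -454.      265.   -0.978     0.956 4.57e-39    57
#> 2 shannon   -5.72      5.62 -0.889     0.790 2.63e-20    57
```

Bacterial richness and diversity rise as density falls (negative slope
against density = increase with decay), here with r² of 0.96 and 0.79 —
the generator's gradient is strong by design.

```r
avg  <- average_replicates(rar, study$metadata)
env  <- study$metadata |> distinct(replicate_of, .keep_all = TRUE) |>
  mutate(sample_id = replicate_of)
tree <- fit_mrt(avg, env, max_leaves = 3)
tree$splits
#> # A tibble: 2 × 2
#>   variable     threshold
#>   <chr>            <dbl>
#> 1 wood_density     0.295
#> 2 wood_density     0.391
count(assign_stages(tree, env), stage)
#> # A tibble: 3 × 2
#>   stage      n
#> 1 early      6
#> 2 late       8
#> 3 middle     5
```

The tree recovers the planted density bands (0.30 and 0.40 g/cm³) to
within the spacing of the gradient and partitions the 19 parents into the
three decay stages.

```r
cmp <- compare_models(as.numeric(rar[1, -1]))  # densest sample, neutral-planted
glance(cmp)
#> # A tibble: 1 × 6
#>   best_model verdict     s     j margin scoring
#> 1 zsm        neutral    46  1080      2 rank_poisson
```

The first (early-stage, neutral-generated) sample is classified neutral:
the ZSM's Akaike weight is ≈ 1. `tidy(cmp)` lists all six models with
log-likelihoods, AICs and weights; `plot_akaike_weights()` draws the
samples-by-models weight heatmap; `autoplot(cmp)` overlays fitted rank
abundance curves on the data.

`run_pipeline(pipeline_config(...))` chains all stages from the four TSV
inputs to a directory of TSV/JSON/GraphML outputs plus a manifest and log;
`inst/scripts/decaywood.R` is a thin command-line wrapper over
`simulate_decay_study()` and `run_pipeline()`.

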