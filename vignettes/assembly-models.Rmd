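---
title: "Community succession and assembly in decaying wood: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community succession and assembly in decaying wood: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decaywood)
```

decaywood analyses bacterial and fungal community tables collected along a
wood-decay gradient. This vignette explains the statistical machinery, the
choices made where the design was genuinely open, and what the synthetic
data generator does and does not emulate. It states no empirical result
that the package's tests and acceptance script do not themselves compute.

## The pipeline at a glance

Given a bacterial and a fungal OTU table (samples × taxa), a taxonomy map,
and per-sample wood measurements (density, pH, moisture, C/N, ergosterol),
`run_pipeline()` executes:

1. **Rarefaction** of every replicate to a common depth (defaults: 1,080
   reads for bacteria, 2,000 for fungi). Samples below depth are excluded
   from that kingdom only, and logged.
2. **Alpha diversity** (observed richness, bias-corrected Chao1, Shannon)
   and OLS regressions of diversity against wood density, the proxy for
   decay progress.
3. **Decay-stage partitioning** with a multivariate regression tree (MRT)
   on Bray–Curtis dissimilarities of parent-averaged bacterial
   communities, leaves named early/middle/late by descending mean density.
4. **Differential abundance** between stage pairs with a Metastats-style
   permutation t test on genus-level relative abundances, BH-corrected.
5. **Co-occurrence networks** from all-pairs Pearson correlations of
   genus-level, replicate-averaged abundances of both kingdoms, thresholded
   at |r| > 0.80 with FDR-adjusted p < 0.05.
6. **Assembly classification** per sample: five niche rank-abundance
   models and the neutral zero-sum multinomial compared by AIC and Akaike
   weights.

## Diversity and its regressions

Chao1 uses the bias-corrected form
`S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, which stays defined when no
doubletons are observed; with no singletons it equals observed richness.
Results are therefore slightly below the classic `F1^2 / (2 F2)` form when
`F2` is small — a documented, deliberate difference. Shannon entropy is
reported in nats (the natural-log convention; multiply by `log2(e)` for
bits). Rarefaction subsamples reads without replacement, each sample on a
deterministic substream of the global seed, so a sample rarefies
identically alone or within a table.

`linear_fit()` reports the slope, intercept, Pearson `r`, `r²` and the
two-sided slope p-value on `n - 2` degrees of freedom. Both `r` and `r²`
are exposed because signed strength-of-fit values in this literature are
Pearson correlations even when labelled R²; the package never reports a
signed quantity as `r_squared`. Replicates enter regressions pooled (one
point per replicate) by default; `average = TRUE` collapses them to parent
means first.

## Decay stages from a multivariate regression tree

The MRT partitions samples by thresholds on environmental covariates to
minimize within-leaf community heterogeneity. Because the community
contrast is expressed as a Bray–Curtis matrix (non-Euclidean), node
impurity uses the distance-based surrogate for the sum of squares about
the centroid:

> impurity(node) = Σ_{i<j ∈ node} d(i,j)² / n_node

Each greedy split maximizes the impurity decrease over all (covariate,
threshold) pairs, thresholds being midpoints between consecutive sorted
unique covariate values; ties break deterministically by covariate order
then lower threshold. There is no cross-validation pruning: tree size is a
parameter with default `max_leaves = 3`, matching the three-stage design
of decay surveys. A greedy tree is not guaranteed to be the globally
optimal partition of that size (the test suite verifies the greedy
procedure against an independent brute-force enumeration of split
sequences, and separately that the *first* split is the global best
single split, where greedy and exhaustive provably coincide).

Leaves are named by descending mean wood density — early, middle, late —
because density is the field's decay proxy; with more than three leaves
the remainder are `stage4`, `stage5`, ….

## Differential abundance

`metastats_test()` converts counts to within-sample relative abundances,
computes a Welch t statistic per taxon, and estimates its null by randomly
relabelling samples across the two groups ("1000 bootstrap" in the
original tool's vocabulary is operationally a relabelling test; a
with-replacement mode is available behind `mode = "bootstrap"`). The
two-sided p-value uses the add-one rule `(1 + #{|t*| ≥ |t|}) / (B + 1)`,
so p is never 0 and its floor is `1/(B + 1)`. With small groups,
`exhaustive = TRUE` enumerates every distinct relabelling and returns the
exact permutation p. Sparse taxa (fewer than two carrying samples in a
group) are tested but flagged `low_information` rather than routed to a
different test. BH q-values are computed across taxa.

## Co-occurrence networks

Genera are first filtered to those with at least five representatives.
"Representative" is read as a sequence read (total count ≥ 5), with the
prevalence reading (present in ≥ 5 samples) available via
`mode = "samples"`. Pearson correlations are computed across
replicate-averaged relative abundances; p-values come from the t transform
`t = r sqrt((n-2)/(1-r²))`. Edges require `|r| > 0.80` strictly *and* a
significant p; by default p-values are BH-adjusted across all pairs and
the adjusted value must pass 0.05. Both thresholds are configuration
values because the field uses several conventions (raw p < 0.05, adjusted
p < 0.001, …); the run log records which was active. Nodes are genera with
at least one edge; isolated genera are not part of the network. Exports
(edge TSV, node TSV, GraphML) are Cytoscape-readable.

Averaging for networks operates on relative abundances, not raw counts.
At equal rarefaction depth the two coincide; the relative form remains
correct if depths differ.

## Neutral versus niche assembly

This is the package's core computation. For one sample with ranked
abundances `a_1 ≥ … ≥ a_S`, `J = Σ a_r`:

**Niche models.** Expected abundances per rank:

| model | λ_r | free parameters |
|---|---|---|
| broken stick | (J/S) Σ_{k=r..S} 1/k | 0 |
| preemption | J α(1−α)^(r−1) / (1−(1−α)^S) | α ∈ (0,1) |
| log-normal | exp(μ + σ Φ⁻¹((S−r+0.5)/S)) | μ, σ > 0 |
| Zipf | J p₁ r^γ | p₁ ∈ (0,1], γ < 0 |
| Zipf–Mandelbrot | J c (r+β)^γ | c > 0, γ < 0, β > −1 |

Note the preemption form is normalized over the S observed ranks (some
implementations omit the `1−(1−α)^S` denominator). The log-normal maps
rank to a normal quantile through midpoint plotting positions; tied
observed abundances keep their input order. Each model is fitted by
maximizing the Poisson log-likelihood
`Σ_r [a_r ln λ_r − λ_r − ln a_r!]` — Nelder–Mead from a deterministic
grid of five starts on transformed (unconstrained) parameters, with
golden-section search for the one-parameter preemption model, and a
convergence tolerance of 1e-8 on the log-likelihood. The
Zipf–Mandelbrot starts include the fitted Zipf solution (β = 0), so its
likelihood never falls below Zipf's (the models are nested).

**Neutral model.** `zsm_loglik()` evaluates the exact probability of the
abundance configuration under the zero-sum multinomial of neutral theory —
the Etienne sampling formula — with fundamental biodiversity number θ and
immigration probability m (`I = m(J−1)/(1−m)`). The combinatorial
coefficients `K(D, A)` are built by log-space convolution of per-species
terms derived from unsigned Stirling numbers of the first kind, and the
sum over ancestral immigrant counts `A = S..J` uses log-sum-exp, so the
computation cannot overflow at any `J`. At `m = 1` the expression reduces
to the Ewens sampling formula, evaluated directly. The data-dependent
coefficients are computed once per sample, making each subsequent
likelihood evaluation linear in `J`; `fit_zsm()` then maximizes over
`(ln θ, logit m)` by multi-start Nelder–Mead. Estimates driven to the
boundary (e.g. θ diverging on an all-singleton sample) are reported with
`converged = FALSE`.

**Comparison.** Every model is scored by `AIC = −2 logL + 2 npar`
(npar: 0, 1, 2, 2, 3 for the niche models, 2 for the ZSM) and AICs are
converted to Akaike weights `w_i = exp(−ΔAIC_i/2)/Σ exp(−ΔAIC/2)`. The
verdict is *neutral* or *niche* according to the winning family, and
*both* when the best neutral and best niche AICs lie within a margin
(default ΔAIC ≤ 2 — the conventional "essentially equivalent support"
band).

### A known, deliberate limitation: mixed likelihood constructions

The niche models are scored on a rank-wise Poisson likelihood; the ZSM is
scored on the probability of the whole abundance configuration. These are
the constructions used by the standard tools of this literature (vegan's
`radfit` and the TeTame program), and the package reproduces both
faithfully — our ZSM optimum for the classic Barro Colorado forest census
(`vegan::BCI` summed over plots) matches the published TeTame values to
three decimals. But the two constructions are *not* probabilities on the
same space, and their comparison through a single AIC scale is inherited
from the tools, not statistically principled. In practice the
configuration likelihood is generous to the ZSM on communities with few
tied rare species, and harsher on singleton-rich communities (the
`Σ ln Φ_j!` multiplicity term). Consequences you should expect:

- On synthetic communities of moderate evenness (say S ≈ 50 at J ≈ 1080,
  where the rarest expected abundances are still ≈ 5 reads), the ZSM's
  AIC dominates the niche models' even when the data were generated from
  a niche model. The package's own model-recovery tests document exactly
  this: preemption- and neutral-generated samples are recovered at high
  rates, while log-normal-, Zipf- and broken-stick-generated samples of
  that shape are claimed by the ZSM.
- On singleton-rich samples (as real amplicon tables typically are) the
  balance shifts and niche models can win.

`compare_models(..., scoring = "configuration")` offers a like-for-like
alternative that rescores the niche models on the multinomial probability
of the observed configuration under their fitted expected proportions.
The exact configuration probability of a niche model sums over all
assignments of observed counts to species — a matrix permanent that is
intractable at realistic S — so this scoring uses the dominant
(rank-sorted) assignment, a strict lower bound. It does not reverse the
ZSM's advantage on even communities, and the default remains the
literature's construction.

## The synthetic decay study

`simulate_decay_study()` generates the processed-table level of a
19-parent, 3-replicate survey: a density gradient 0.50 → 0.15 g/cm³ with
stage bands early > 0.40, middle 0.30–0.40, late < 0.30 g/cm³; bacterial
replicate depths ≥ 1,080 and fungal ≥ 2,000 reads; bacterial observed
richness rising from ~35 OTUs at the densest samples to roughly 200
at the most decayed (defaults `richness_base = 35`,
`richness_slope = 500` OTUs per g/cm³ lost — chosen to reproduce the
range reported for processed pyrosequencing tables of this design, since
only strength-of-fit statistics, not slopes, are published); per-stage
covariate means and dispersions that mimic measured wood chemistry (pH
drop after the early stage, a late-stage moisture surge, declining C/N,
rising ergosterol); one fungal phylotype dominating every sample
(55–85% share); an indicator OTU confined to each stage; and planted
genus pairs with strong positive or negative cross-parent correlation.
Assembly mechanism is planted per stage — early parents are
neutral-generated (θ solved so the Ewens expected richness matches the
stage's target), middle and late niche-generated — giving every pipeline
stage a known ground truth. Niche samples are drawn Poisson around the
model's expected abundances (the same error model the fitter assumes,
keeping generator and fitter conjugate); neutral samples come from the
sequential urn construction whose stationary law the ZSM likelihood
evaluates.

One global seed expands into per-component substreams through a fixed
counter scheme (`derive_seed(seed, counter)`): counters 1–3 cover
densities, covariates and planted correlations, 100+p / 300+p the
bacterial / fungal parent profiles, 500+i / 700+i the replicate draws.
Any component is therefore reproducible in isolation.

What the generator does **not** emulate: sequencing reads and their
errors (no chimeras, no OTU-clustering noise), compositional coupling
beyond the planted pairs, spatial or temporal autocorrelation between
parents, and the heavy singleton tails of real amplicon data are only
partially reproduced (12–28% singletons per sample in the default
configuration). Tests passing on these data show the statistical
machinery is correct under its own assumptions; they do not certify
behaviour on real 454/Illumina tables.

## Numerical and design choices

- **Problem sizes.** The test suite exercises the Ewens/total-probability
  oracles exhaustively at J ≤ 10, model recovery at 100 seeds per
  generator (S ≈ 50, J = 1080), stage-threshold recovery at 50 simulated
  studies, permutation calibration at 200 null tables, and network
  calibration at 200 null tables against a 500,000-pair Monte-Carlo tail
  estimate — sizes chosen to give stable Monte-Carlo bands at desk scale.
- **Determinism.** Every stochastic step takes a seed; the pipeline's
  outputs are a pure function of (inputs, configuration, seed), verified
  byte-for-byte in the tests.
- **Degenerate inputs.** All-zero samples are rejected where the quantity
  is undefined (Shannon, Bray–Curtis) or defined to 0 (Chao1); constant
  covariates collapse the MRT to one leaf with a warning; constant genera
  are excluded from correlation with a warning; empty permutation groups
  and sub-depth samples raise errors naming the offending samples.
- **Unclassified taxa** are pooled per kingdom at the aggregation rank
  rather than dropped, so per-sample totals — and hence relative
  abundances — are conserved exactly.
- **Replicate averaging** operates on relative abundances (coincides with
  count averaging at equal depth, robust otherwise).
- **Excluded samples** are removed per kingdom only, mirroring surveys
  that drop a sample from one marker's analysis but keep the other.

## Limitations

- The AIC comparison across likelihood constructions discussed above.
- The MRT offers no surrogate splits or categorical covariates, and no
  cross-validated size selection.
- Correlation networks use plain Pearson correlations on relative
  abundances; compositional effects (spurious negative correlation from
  the unit-sum constraint) are not corrected — SparCC-style approaches
  are out of scope.
- Permutation p-values are bounded below by `1/(B+1)`; q-values inherit
  that granularity.
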