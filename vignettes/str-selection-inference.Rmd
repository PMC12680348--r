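---
title: "Inferring selection at short tandem repeats from allele frequencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring selection at short tandem repeats from allele frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strsel)
```

## The model

Short tandem repeats (STRs) mutate by gaining or losing whole repeat units at
rates orders of magnitude above the single-nucleotide rate. `strsel` models
the evolution of the allele-length distribution at one locus with three
components, iterated once per generation, and layers an approximate Bayesian
computation (ABC) scheme on top to learn how natural selection is distributed
across sets of loci.

**Allele grid.** A locus is represented by a vector of frequencies over
`n = 25` allele lengths centred on the optimal allele `xopt`, indexed by the
offset `k = x - xopt` in repeat units (`k` from -12 to +12). Because every
allele length must be at least one repeat unit, the default grid requires
`xopt >= 13`; classes with shorter optima should use a narrower grid
(`allele_grid(xopt, n)` with smaller odd `n`).

**Mutation** follows a generalized stepwise model. An allele of length `x`
mutates with probability `mu(x)` where

```
log10 mu(x) = log10(mu0) + L * (x - ref_len)
```

clamped into `[1e-8, 1e-3]`. By default `ref_len = xopt`, so `mu0` is the
rate of the optimal allele and `L` (log10 units per repeat) captures the
well-documented speed-up of mutation with repeat length. Step sizes are
geometric with parameter `rho` (`P(|step| = d) = rho (1-rho)^(d-1)`; `rho`
near 1 means nearly all mutations are single steps), and the direction is
biased toward the optimum with strength `beta`: the probability of expanding
is `(1 - beta rho k)/2`. Both direction probabilities are clamped to `[0, 1]`
and renormalised so the model stays total even where `beta rho |k| > 1`, a
regime the default parameters never reach. Step mass that would leave the
grid is accumulated on the boundary allele, which conserves probability
without inventing alleles outside the modelled window; whether the original
implementations clip or renormalise is not documented, and the choice is
invisible at the default parameters because the boundary mass is tiny.

**Selection** is linear in the distance from the optimum:
`w(x) = 1 - s |x - xopt|`, floored at zero. `s` is on the homozygote scale; a
diploid's fitness is the average of its two allele fitnesses, so one copy of
an allele one unit from the optimum costs `s/2`. The deterministic update is
the standard random-mating diploid reweighting: allele `i` is multiplied by
its marginal fitness `(w_i + wbar)/2` and the vector renormalised by the mean
fitness `wbar`. With `s = 0` the update is the exact identity.

**Drift and demography.** Each generation the post-selection frequencies are
resampled multinomially at `2 N(t)` alleles. `N(t)` follows a five-epoch
European history: 7,310 diploids for a 50,000-generation burn-in, expansion
to 14,474 at 5,920 generations before present, a bottleneck to 1,861 at
2,040, a divergence-era size of 1,032 at 920, then continuous exponential
growth at rate 0.00307 until 205 generations ago and 0.0195 to the present
(~505,000). Growth is evaluated as `N e^(rate t)` at integer generations —
the convention of the coalescent literature the history comes from. The
ancestral epoch is treated as open-ended into the past so the size query is
defined for any time at or before the span. After the final generation an
*end sampling* step draws `N` alleles (the empirical sample size, default
1,000) so simulated and observed frequency spectra share their sampling
noise.

## Scaled simulation mode

Full trajectories run 55,920 generations. For test suites and interactive
exploration a rescaled mode divides sizes and epoch durations by a factor
`lambda` (default choice here: 10) while multiplying mutation rates (and
their clamp bounds), growth rates and the selection coefficient by `lambda`.
This is the standard population-genetic rescaling: it preserves `4 N mu` and
`2 N s`, the compound parameters that control heterozygosity and the
efficacy of selection, so scaled runs reproduce full-run summary
distributions at a tenth of the cost. Two caveats are worth knowing. First,
the rescaling saturates for `s > 1/lambda` (the scaled coefficient is capped
at 1); those loci are under such strong selection that they are essentially
monomorphic either way, so ordering is preserved. Second, discreteness
effects (sizes rounded, durations rounded) introduce per-epoch errors of at
most one generation. All simulation-heavy tests in the package run at
`scale = 10`; desk-scale checks of closed-form arithmetic run no simulations
at all.

## Joint DFE inference

Per-locus selection inference at an STR is confounded: a near-monomorphic
locus may have a low mutation rate, strong selection, or both. The joint
mode therefore assumes the selection coefficients of a *class* of loci (same
canonical repeat unit, same optimal = modal allele) are drawn from a gamma
distribution with shape `a` and scale `b`, and infers `(a, b)` by ABC using
per-locus heterozygosity `h = 1 - sum(p^2)` as the summary statistic:

1. Draw `a ~ Uniform(0, 1)` and the mean `a b` from a lognormal whose log has
   mean `log(3e-4)` and standard deviation `log(30)` (natural logs — the
   sources the prior is calibrated against quote `log` unqualified, and the
   package exposes both constants, so the base convention is configurable
   away).
2. Draw one `s` per locus from `Gamma(a, b)`; fetch a simulated
   heterozygosity per locus from a precomputed lookup table, keyed by `s`
   rounded to one significant digit (values below `1e-5` round to 0).
3. Score the draw by sorting the simulated and observed heterozygosity
   vectors and taking the mean absolute difference — an L1 distance between
   empirical quantile functions.
4. Accept the best 1% of `z` draws (default `z = 50,000`) and report the
   accepted pair with the median `a*b`. With an even accepted count, the
   lower of the two central order statistics is reported, so the point
   estimate is always a member of the accepted set. Ties in the distance
   ranking resolve by draw order.

Lookup tables store, per one-significant-digit key from 0 to 1, a
configurable number of end-sampled replicate simulations (default 50).
During ABC a random replicate is served per query. Observed sets larger
than 1,000 loci are subsampled once before inference; when observed and
simulated vectors differ in length, the longer is subsampled without
replacement.

The per-locus mode (`infer_locus_s()`) runs the same ABC on a single locus's
heterozygosity over a uniform grid of candidate `s` values. It exists
chiefly as the comparison baseline: it standardises on the heterozygosity
summary (the historical per-locus method compared whole frequency vectors),
which keeps the two modes commensurable within this package at the price of
not reproducing the historical method byte for byte.

### What the synthetic validation shows — and does not

The package validates inference on data generated by its own simulator
(`generate_synthetic_dataset()` writes a frequency table plus a truth
sidecar). On the high-mutation dinucleotide class (`mu0 = 1e-4`, the
baseline of the standard validation regime) with `a = 0.6`, 100-locus
datasets and `z = 2,000`, the median of 10 repeated estimates recovers true
mean `s` of `1e-4`, `1e-3` and `1e-2` within a factor of three with no
consistent direction of error.

Two limits of identifiability are worth stating plainly, because they are
properties of the method, not bugs. Heterozygosity carries no information
about `s` once `2 N s` is well below 1 — with this demography, roughly
`s < 1e-4`. For data simulated under strict neutrality the accepted set is
therefore the prior conditioned on "mean below detectability", whose median
lands in the few-times-`1e-5` range rather than collapsing to 0; the same
mechanism floors the joint estimate at a few times `1e-5` when the true mean
is `1e-5` on a low-mutation class. The qualitative contrast survives — the
per-locus mode overshoots such truths by another order of magnitude — but
point estimates below `~1e-5` should be read as "compatible with
neutrality", not as measurements. A denser prior tail or a sharper summary
statistic would be needed to do better; both are out of scope here.

Synthetic data also inherit the simulator's idealisations: a single known
optimum, perfect genotypes (unless the 0.1%-per-allele error model is
switched on), free recombination between loci, and no stutter or sequence
imperfections. Passing recovery tests demonstrates internal consistency of
the inference machinery, not robustness to every failure mode of real STR
genotyping.

## Mutation-model selection and goodness of fit

For putatively neutral loci (`s = 0`), candidate mutation models of the form
`log10 mu = log10 mu0 + L (x - r)` are compared by pooling ABC draws
uniformly across candidates and reporting each candidate's share of the
accepted draws — under the uniform model prior, an approximation to relative
likelihood. Acceptance is over the pooled set, not per candidate.

Model fit is checked post hoc by `ks_fit_score()`: 100 rounds of fresh
simulation of a matched-size dataset, each compared to the observed
heterozygosities by a two-sample two-sided KS test (asymptotic p-values);
the score counts rounds with `p > 0.05`, and classes scoring at or below 50
are excluded from burden analyses. The rounds always simulate fresh
trajectories rather than reusing lookup replicates: a 50-replicate pool
differs from the true distribution by about `1/sqrt(50)`, which is the KS
detection scale at the usual 50-locus round size and would systematically
deflate the score. To equalise power across classes of very different
sizes, rounds can be capped (`subsample_cap = 50` mirrors the published
subsetting variant).

## Fitness burden accounting

`str_denovo_burden()` converts a class record (locus count `N_c`,
optimal-allele rate `mu_c`, step parameter `rho`, DFE mean `s_c`) into the
expected per-generation fitness loss
`N_c * 2 * mu_c * sum_i P(step = i) * s_c * 0.5 * |i|` over steps `i` in
±1..20. The step law is the symmetric truncated geometric implied by the
mutation model at the optimum (direction 1/2 each; truncation mass beyond
|20| is dropped, not renormalised, and reported as `truncation_deficit`).
The `scaled` flag halves burdens so `s` refers to one allele copy, matching
SNV conventions; unscaled is the default for STR-only outputs. The SNV
counterpart is the closed form `2 L mu s`, and noncoding burdens
extrapolate linearly in the assumed fraction of sites under selection
because the target size enters that product linearly.

For *inherited* variants the DFE must be conditioned on segregation —
strongly selected alleles far from the optimum rarely survive to be
observed. `inherited_allele_s()` draws 1,000 coefficients from the class
DFE, simulates frequencies for each, records `(s, allele frequency)`
whenever the observed allele segregates, and samples one `s` with
probability proportional to recorded frequency (normalised over the
recorded table, which is the convention that reproduces the canonical
5/8–1/4–1/8 worked example). Observed variants are carried as
`|allele - optimal|`; the simulated frequency of the `+offset` allele is
used when checking segregation, which is exact for `beta = 0` (the model is
then symmetric in the offset sign) and an approximation otherwise.
Per-variant reductions `offset * s` below `1e-5` are rounded to zero, above
1 capped at 1, offsets beyond the grid contribute zero, and poor-fit
classes are excluded.

## Numerical and design notes

- The per-generation loop (mutation matrix product, selection reweighting,
  multinomial draw) is compiled (Rcpp) and uses R's RNG, so any pipeline is
  reproducible from a single `set.seed()`.
- Mutation matrices are exactly row-stochastic (boundary absorption), and
  the suite checks them to `1e-12`.
- Modal-allele ties resolve toward the smallest `|k|`, then the negative
  (shorter) side — the published material never defines ties, and this
  choice agrees with the tie-toward-shorter rule used when grouping observed
  loci.
- Repeat units are canonicalised to the lexicographically minimal rotation
  over both strands (`TG`, `GT`, `CA` → `AC`); the published grouping states
  the motif only by example.
- Locus filters: reference length at least 11/5/7 repeat units for
  di-/tri-/tetranucleotides and call rate at least 0.8.
- Test-suite problem sizes (100-locus datasets, `z = 2,000`, 10 repeats,
  50 replicates per lookup key, `scale = 10`) follow the scaled validation
  design; production defaults (`z = 50,000`, full demography) are the
  published operating point.
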