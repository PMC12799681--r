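---
title: "Quantifying receptor density variability across individuals and regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying receptor density variability across individuals and regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recvar)
```

## The model

PET receptor mapping yields, per tracer study, a group mean volume μ and a
group standard deviation volume σ over subjects, registered to a common
space and parcellated to a cortical (100 regions) plus subcortical (54
regions) atlas pair. `recvar` treats these two regional maps as the data
and asks two complementary questions:

1. **How much does binding vary across individuals within a region?**
   The inter-individual coefficient of variation, CV(r) = σ(r)/μ(r).
   Because the standard deviation of biological measurements scales with
   the mean (σ ≈ c·μ^β, the fluctuation-scaling law;
   `std_mean_scaling()` estimates β as the OLS slope of log σ on log μ),
   raw σ maps mostly re-express the mean map; dividing by μ removes that
   trivial component.
2. **How much does the group profile vary across regions?** The
   inter-regional CV: sd(μ)/mean(μ) over the valid regions of one
   compartment, using the sample (n−1) standard deviation.

Their quotient, the **regional-to-population CV ratio** =
inter-regional CV / mean(CV(r)), summarizes a receptor in one number:
above 1, spatial structure dominates subject noise and the regional rank
order of density is approximately conserved in every individual; below 1,
individual differences dominate and a single-subject map would be a poor
rendition of the group map.

Significance of "inter-regional exceeds inter-individual" is assessed by
bootstrap: the retained CV values of the compartment are resampled with
replacement (resample size = number of retained regions), the mean of each
of n_boot = 10,000 resamples is recorded, and p is the plain fraction of
null means ≥ the empirical inter-regional CV (no +1 correction — the
estimator is the verbatim count). With a seed fixed the result is
bit-reproducible; across seeds p fluctuates within binomial error
√(p(1−p)/n_boot).

## Assumptions and masking rules

- Volumes are assumed co-registered; the package performs no registration
  and errors on grid mismatch.
- σ maps are taken as contributed. Whether a site used the n or n−1
  denominator across subjects is unknowable downstream; none of the
  statistics computed here depend on that choice.
- CV is unstable as μ → 0, so a **low-binding filter** omits a region iff
  its mean binding is in the bottom 5th percentile of the map's valid
  regions (linear interpolation, inclusive boundary, evaluated over
  cortex + subcortex jointly) **and** below 0.1 binding units. The
  conjunction is the conditional reading of the rule; `filter_policy()`
  also offers `or` and `percentile_only` because the prose rule admits
  both readings. Note an edge of the inclusive boundary: when the
  interpolated percentile lands exactly on an observed value, that value
  is omitted too.
- Tracer-specific rules are data, not code: a study carries
  `reference_exclusion` ids (e.g. occipital cortex for a mu-opioid tracer
  quantified against an occipital reference — binding there is
  definitionally non-specific) and a `striatum_only` flag (low-affinity
  D2 tracers quantify reliably only where density is high). Anatomical
  targets resolve to label ids via name-tag presets (`region_preset()`),
  since label lists are atlas-specific.
- A retained region with μ ≤ 0 (possible in V_T/BP_ND maps from upstream
  modelling noise) is invalidated with a warning rather than crashing or
  producing a negative CV.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `percentile_cut` | 5 | % | bottom tail of mean binding considered unstable |
| `absolute_threshold` | 0.1 | binding units | absolute floor under which CV denominators are untrusted |
| `combine` | `"and"` | — | how the two filter clauses combine |
| `n_boot` | 10,000 | resamples | null resolution ≈ 1/n_boot |
| `alpha` | 0.05 | — | conventional flag threshold; no multiplicity correction by default, matching per-tracer reporting (a Benjamini–Hochberg pass can be applied to the summary table by the user) |
| `n_subjects` (simulator) | per template | subjects | cohort sizes mirror the real multi-site studies (8–100) |

The absolute threshold is deliberately dimensioned in binding units, so
the filter as a whole is *not* invariant to rescaling the maps by k > 0;
the CV statistics themselves are. Scale invariance holds exactly under
`percentile_only`, and under the default policy whenever the rescale does
not move regions across the 0.1 cut.

## The synthetic cohort generator

`generate_cohort()` draws subject s, region r as
`shift_s · (μ_r + ε_{s,r})` with sd(ε) = CV_r·μ_r and
`shift_s ~ lognormal(0, baseline_shift_sd)`. It emulates: per-tracer mean
profiles on realistic binding scales (lognormal-shaped spatial profiles,
affinely rescaled to an exact target inter-regional CV), mean-scaled
subject noise (β = 1 fluctuation scaling by construction; other β are
expressible through the CV field), near-zero binding only through the
filter path, separate 100-region cortical and 54-region subcortical
compartments, and the cohort sizes of the real studies (e.g. N = 100 for
the DASB-like serotonin-transporter template, N = 86 for the
carfentanil-like opioid template).

Two noise families are offered. The default is gaussian clamped at zero —
binding measures are nonnegative — and at the CV levels simulated (≤ 0.6)
the clamping touches at most ~2% of draws, a bias far below the recovery
tolerances used in testing. Lognormal is available because true
subject-level distributions are unknown (individual data are not
shareable) and outliers could skew contributed σ maps.

The multiplicative subject shift makes the "conserved spatial profile,
individual-specific baseline" scenario literal: raising
`baseline_shift_sd` from 0 to 0.3 adds ≈ √(e^0.09 − 1) ≈ 0.31 of common
CV to every region — so every regional CV rises — while leaving the
group-mean map's rank order untouched, which is exactly the dissociation
the CB1/mGluR5-like archetype requires.

What the generator does **not** emulate: PET physics and kinetic
modelling error structure, spatial autocorrelation of noise across
neighbouring regions, site/scanner batch effects, or age structure within
a cohort. Passing tests therefore establish correctness of the statistics
under the stated generative model, not robustness to every property of
real tracer data.

## Numerical and design choices

- **Percentile convention**: `quantile()` type 7 (linear interpolation),
  computed over the whole map's valid regions, not per compartment — one
  documented convention so results are reproducible. The per-compartment
  alternative is a one-line policy change but is not exposed, to avoid a
  silently different retained set between figures.
- **Inter-regional CV inside `receptor_variability()`** is computed over
  the post-filter retained regions, so the numerator and denominator of
  the ratio (and the bootstrap comparison) refer to the same region set.
  The standalone `interregional_cv()` follows its own contract: all valid
  regions of whatever map it is given.
- **n−1 standard deviation** everywhere a dispersion across regions or
  subjects is computed; the common default of mainstream numerics stacks.
- **Consistency scoring** defaults to original-vs-others (with one other
  map the score is simply that Spearman r); an all-pairs mode is provided
  because averaging over every pair among replicates is the other
  defensible reading when three or more maps exist.
- **Permutation p** for the small-n cross-receptor correlations
  (ratio vs consistency, CV vs cohort covariates): two-sided, shuffling
  one vector, plain proportion; the asymptotic p is reported alongside
  for comparison. With ~6–16 receptors the t-approximation is not
  trustworthy.
- **Random-number contract**: one top-level seed; every tracer, bootstrap
  and replicate stream derives its own seed deterministically from
  (seed, stream id) (`derive_seed()`), so per-tracer results are
  independent of which other tracers are present. RNG state is always
  restored after use.
- **Degenerate inputs**: constant maps error in `minmax_scale()`
  ("degenerate range") and in rank correlations ("zero variance");
  fewer than 2 valid regions error in `interregional_cv()`; a
  compartment that cannot be estimated (e.g. cortex of a striatum-only
  tracer) yields NA statistics inside the fit rather than an error, and
  `report_summary()` excludes it from the significance denominator with
  a note.
- **Exact piecewise-constant round trip**: `parcellate_volume()` snaps a
  region whose voxels are all equal to that constant, so
  `parcellate(embed(m)) == m` bitwise — sum/count alone can be off by one
  ulp.

## Problem sizes used in the shipped tests

Unit and property tests run on the default 154-region atlas pair with
cohorts of 4–200 subjects; calibration-style checks use 10–50 seeded
replicates (CV recovery: 20 replicates at N = 50; bootstrap regime
separation: 40 replicates per regime at n_boot = 10,000; Monte-Carlo vs
enumerated bootstrap p: n_boot = 200,000 over 10 seeds). These sizes were
chosen so each statistical bound sits several standard errors away from
its threshold under the generative model.

## Known limitations

- The synthetic atlas preserves label bookkeeping, not anatomy; presets
  ("occipital", "striatum") are name tags, and results on it say nothing
  about real parcellations' partial-volume behaviour.
- The filter's absolute clause ties results to the map's native units by
  design; comparing tracers quantified in different measures (BP_ND, V_T,
  B_max, SUVR) is meaningful only because CV itself is unit-free.
- Consistency scores treat replicate maps as independent; replicate
  cohorts from one site with shared processing inflate them.
- No spatial-autocorrelation-preserving null is used — the bootstrap
  resamples regions as exchangeable units, which matches the estimator
  being tested but ignores spatial dependence among regions.
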