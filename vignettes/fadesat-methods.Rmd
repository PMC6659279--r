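---
title: "Desaturation indices and phylogenetic regression: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Desaturation indices and phylogenetic regression: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fadesat)
```

This vignette is the package's own account of the science it implements:
the quantities, the statistical model, the tunable parameters, what the
synthetic-data generator does and does not emulate, and the choices made
where the design was genuinely open.

## The two indices

Adipose tissue composition is reported as percent by weight (wt%) per
fatty acid. The **Δ9-desaturation index** is the ratio of the five
monounsaturated fatty acids reachable through the Δ9-desaturase pathway
(14:1ω5, 16:1ω7, 16:1ω9, 18:1ω9, 18:1ω7) to their three saturated
precursors (14:0, 16:0, 18:0). Because most polyunsaturated fatty acids
are dietary, they are excluded; the index is read as a proxy for
endogenous desaturase activity. The **double bond index** is
Σ x·(wt%)/100 over every fatty acid in the profile, with x the number of
double bonds — total unsaturation with diet folded back in. The contrast
between the two is the analytical lever: an effect present in the Δ9-DI
but absent from the DBI is hard to attribute to diet.

Parsing accepts the dialects common in the composition literature
(`16:1ω7`, `16:1w7`, `16:1n-7`, `16:1(n-7)`) through an explicit,
extensible prefix table; anything else fails loudly. Two decisions about
raw tables:

* **Missing formula FAs count as wt% 0**, with a warning. Published
  composition tables omit trace FAs inconsistently, and silently
  refusing such tables would exclude most of the literature. This is a
  choice about data handling, not a claim that the true abundance is
  zero.
* **Profiles are not renormalised to 100% before computing** (a
  `renormalize` flag exists, default off). Both indices are ratios or
  weighted sums of the raw published wt%, and renormalising would change
  the DBI (though not the Δ9-DI) whenever totals fall short of 100.
  `validate_profile()` flags totals outside 100 ± 5 percentage points by
  default.

Branched-chain FAs parse with zero double bonds and therefore never
enter the Δ9-DI numerator and contribute nothing to the DBI.

## The regression model

For n species with trait vector y (one of the indices), design matrix X
and phylogeny with Brownian covariance V (V[i, j] = shared root-to-MRCA
branch length),

y = Xβ + ε,  ε ~ MVN(0, σ²·V(λ)),

where V(λ) multiplies the off-diagonal of V by Pagel's λ ∈ [0, 1]. The
likelihood is profiled: for fixed λ, β̂ and σ̂² have closed forms computed
in the whitened space U⁻ᵀy, U⁻ᵀX with V(λ) = UᵀU the Cholesky
factorisation — no explicit matrix inverse is formed, which keeps the fit
stable on the nearly singular covariances produced by very short sister
branches. σ̂² is the ML estimator (divisor n); standard errors carry the
n/(n − p) adjustment and confidence intervals use the t distribution
with n − p degrees of freedom, since the paper trail for this kind of
analysis states only the confidence level. λ̂ maximises the profile
log-likelihood by an 11-point coarse grid that brackets the optimum
followed by Brent's method (tolerance 1e-6) in the bracketing window,
with both endpoints checked explicitly. The grid-then-Brent arrangement
costs ten extra likelihood evaluations but removes the assumption that
the profile is unimodal, and the test suite holds it to the property
that a 101-point grid never beats the returned optimum.

λ is bounded above at 1.0 rather than at the largest value keeping V(λ)
positive definite; the parameter is defined on [0, 1] and values above 1
have no interpretation in this model. The tree is not rescaled to unit
height — scale is absorbed by σ², and raw branch lengths keep λ̂
comparable across prunings of the same tree.

## Model selection

Each candidate model is scored by AICc = −2lnL + 2k + 2k(k+1)/(n−k−1).
The parameter count is k = p + 2 when λ is estimated (coefficients plus
σ² and λ) and p + 1 when the covariance is fixed; counting both variance
parameters matches common practice for λ-PGLS model selection, and k is
reported in every output table so a reader can re-derive the penalty.
Akaike weights are exp(−Δᵢ/2) normalised to sum 1; the evidence ratio of
two models is the ratio of their weights, exp((Δ_b − Δ_a)/2) — a 2.0-unit
gap is e ≈ 2.7, a 1.2-unit gap e^0.6 ≈ 1.8. Ties in the ranking break by
fewer parameters, then model name, so output ordering is deterministic.

The named five-model suites are: for the full dataset, environment ×
latitude interaction, additive, latitude-only, environment-only, null;
for the semi-aquatic subset, latitude + log hair density, latitude ×
log hair density, hair-density-only, latitude-only, null. Environment is
dummy-coded against a **fully-aquatic reference level** (configurable),
so the environment coefficients read directly as
fully-aquatic-vs-terrestrial and fully-aquatic-vs-semi-aquatic intercept
differences, and per-environment latitude slopes from the interaction
model combine the marginal slope with the interaction coefficient using
the delta-method variance. Effect size is r = √(1 − RSS_model/RSS_null)
with each residual sum of squares taken in that fit's own V(λ̂)-whitened
space; r² is the share of whitened variance explained.

## Polytomies

Supertrees contain multifurcations. Each fit is repeated across random
resolutions: every polytomy is replaced by a uniformly random binary
arrangement whose new internal edges have length zero, so the tip
covariance matrix is exactly unchanged by resolution and across-iteration
variation reflects only the interaction of topology with λ̂'s profile.
Per-iteration seeds derive from one master seed (drawn once, recorded in
the per-iteration table), so a run is bit-reproducible. Both the mean
(used for ranking) and the median of AICc, λ̂ and the coefficients are
reported, since no single aggregation rule is canonical; within a suite,
every model is fitted to the *same* sequence of resolved trees so AICc
differences are never topology artefacts. Single-iteration failures are
recorded and excluded, with a hard error if more than 1% fail. The
default iteration count in the command-line tools is 1000, matching the
scale at which resolution-induced spread stabilises; the examples and
tests use 1–100 iterations because the aggregate of a binary (or
lightly polytomous) tree converges immediately.

## Other analysis choices

* **Latitude enters as |latitude| by default** (`latitude_mode =
  "signed"` available). The datasets this analysis is built for mix
  hemispheres, and latitude is a thermal proxy: 35° S and 35° N are the
  same distance from the thermal equator.
* **Hair density** is log-transformed (natural log); where primary and
  secondary (underfur) densities are reported separately they are summed
  before transformation. Records without hair density are excluded only
  from the hair-density suite, never from the main suites.
* **Per-FA latitude regressions are ordinary least squares**, not PGLS:
  they are a descriptive decomposition of which individual FAs drive an
  index trend, flagged at α = 0.01, and are restricted in the pipeline
  to pinniped species where the index–latitude signal lives. An FA with
  constant wt% across species returns slope 0 with an undefined p-value
  and an explicit flag.
* **Blubber-section subanalysis**: marine-mammal blubber is stratified
  (outer layer MUFA-rich, less diet-influenced), so pinnipeds sampled by
  whole cores and by outer layer are fitted separately with latitude-only
  PGLS; groups under 3 records are refused rather than fitted.

## The synthetic-data generator

The generator's defaults are the study conditions: 54 species split 15
terrestrial / 25 semi-aquatic / 14 fully-aquatic, latitudes uniform on
0–80°, and log-normal hair densities (meanlog = log 100, sdlog = 1.2,
i.e. a median of ~100 hairs/mm² spanning roughly 10–1000, the range from
sparse-furred semi-aquatic species to dense-furred otters). Trees are
Yule (pure-birth) with unit speciation rate; a configurable fraction of
internal edges can be collapsed into polytomies, pushing each collapsed
edge's length onto its child's daughter edges first so the tree stays
ultrametric with unchanged tip depths. Responses are drawn from exactly
the model the estimator assumes: y = Xβ + ε with ε built by Cholesky
factorisation of σ²·V(λ). Environments are assigned to clade-contiguous
blocks of tips by default, because phylogenetically clustered predictors
are precisely the confounding a λ-aware method must handle; i.i.d.
assignment is available and understates that difficulty.

FA profiles with prescribed (Δ9-DI, DBI) pairs are constructed over a
fixed 12-FA panel (the eight formula FAs plus 18:2ω6, 20:4ω6, 20:5ω3,
22:6ω3). Writing s, m, P for the SFA, MUFA and PUFA masses and x̄ for the
mean double-bond count of the PUFA mix, the constraints m = DI·s,
s(1 + DI) + P = 100 and m + x̄P = 100·DBI have a unique solution once x̄
is drawn (Dirichlet mix, tilted toward 22:6ω3 when the target DBI
demands it); a pair is feasible iff DI/(1 + DI) ≤ DBI < 6, and
infeasible targets error with the feasible interval. Within-group mass
splits are Dirichlet, so profiles look heterogeneous while hitting the
indices exactly and totalling exactly 100.

What the generator does **not** emulate: diet-driven covariance between
PUFAs and latitude, blubber stratification gradients within an
individual, measurement error in published composition tables, and
non-ultrametric trees. Passing tests therefore demonstrate that the
estimator recovers the generative model it assumes — parameter recovery,
ranking behaviour, interval coverage — not that real blubber data meet
those assumptions.

## Problem sizes and numerical tolerances

The test suite exercises λ recovery at 200 tips × 50 replicates per
generating value, model-selection ranking at 60 tips × 20 replicates,
and interval coverage at 60 tips × 50 replicates; these sizes put
Monte-Carlo noise well below the asserted margins while keeping a full
run in tens of seconds. Agreement between the Cholesky-whitened fit and
an explicit-inverse computation is held to 1e-8 on small trees; the
λ-search tolerance is 1e-6; index round-trips are held to 1e-9 (hand
values) and 1e-6 (constructed profiles). Degenerate inputs have defined
behaviour: a saturated fit (n = p) and an exactly-zero residual vector
are errors, not silent σ̂² = 0 likelihood blow-ups; AICc is reported as
NA when n ≤ k + 1 and an explicit error when requested directly.

## Limitations

Real-data reproduction requires the user to supply the published species
table and a mammalian supertree; neither ships with the package. REML,
Ornstein–Uhlenbeck and κ/δ branch transforms, measurement-error models
and multivariate responses are out of scope. The aggregation rule across
polytomy resolutions (mean vs median) is a reporting choice, not an
inference about the original analysis, and both are always emitted.
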