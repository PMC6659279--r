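# fadesat

Do mammals that live in colder water carry more desaturated fat? Blubber
has to stay supple at skin temperatures close to that of the surrounding
water, and one way to lower the melting point of a fat store is to convert
saturated fatty acids (SFAs) into monounsaturated ones (MUFAs) via the
Δ9-desaturase pathway. `fadesat` is an R package for testing that idea
comparatively: it computes desaturation summaries from fatty-acid (FA)
composition tables and relates them to environment, latitude and hair
density across a mammalian phylogeny, for anyone working on comparative
lipid physiology or thermal ecology.

## The quantities and the model

Two summaries of a composition profile (wt% per FA):

* **Δ9-desaturation index** — the ratio of the five Δ9-pathway MUFAs to
  their three saturated precursors,

  Δ9-DI = (wt%14:1ω5 + wt%16:1ω7 + wt%16:1ω9 + wt%18:1ω9 + wt%18:1ω7) /
  (wt%14:0 + wt%16:0 + wt%18:0).

  Polyunsaturated FAs are mostly dietary and are excluded, so the index
  tracks endogenous desaturase activity.

* **Double bond index** — DBI = Σ x·(wt%)/100 over *all* FAs, with x the
  number of double bonds: total unsaturation, diet included.

Each index is then modelled across species with **phylogenetic
generalized least squares**: y = Xβ + ε, ε ~ MVN(0, σ²·V(λ)), where V is
the Brownian-motion covariance of the phylogeny (shared root-to-MRCA
branch length) and Pagel's λ ∈ [0, 1] scales its off-diagonal — λ = 0 is
phylogenetic independence, λ = 1 full Brownian covariance. β and σ² are
profiled analytically through one Cholesky factorisation; λ is estimated
by bounded maximum likelihood. Candidate models (environment × latitude
interaction, additive, single-predictor, null; analogously for hair
density) are ranked by AICc with Akaike weights and evidence ratios, and
every fit is repeated across random resolutions of the tree's polytomies
(new internal edges get length zero, so tip covariances are unchanged)
and aggregated. Inference is by 95% confidence intervals: an effect is
called significant when its interval excludes 0.

A seeded synthetic-data module generates Yule trees, λ-scaled Brownian
traits with clade-structured predictors, and FA profiles constructed to
hit prescribed index values exactly, so the entire pipeline is testable
without any external download.

## Worked example

```r
library(fadesat)

# indices from one composition profile (wt%)
p <- fa_profile("Arctocephalus forsteri", c(
  "14:0" = 4.1, "16:0" = 14.2, "18:0" = 1.9,
  "14:1w5" = 1.2, "16:1w7" = 9.8, "16:1w9" = 0.4, "18:1w9" = 28.5, "18:1w7" = 5.1,
  "18:2w6" = 1.6, "20:4w6" = 1.0, "20:5w3" = 6.3, "22:6w3" = 8.9),
  section = "outer")
delta9_desaturation_index(p)   # 2.227723
double_bond_index(p)           # 1.371

# a synthetic 54-species study: semi-aquatic-only latitude effect (slope 0.06)
cfg <- sim_config(seed = 42, n_tips = 54, polytomy_fraction = 0.25,
                  true_beta = c("(Intercept)" = 2.3, latitude = 0,
                                environmentsemi_aquatic = -1,
                                environmentterrestrial = -1,
                                "latitude:environmentsemi_aquatic" = 0.06,
                                "latitude:environmentterrestrial" = 0),
                  true_lambda = 0.5, sigma2 = 0.3)
tree  <- simulate_tree(cfg)
recs  <- simulate_traits(resolve_polytomies(tree, 42), cfg, model_spec("interaction"))
suite <- run_model_suite(recs, tree, response = "delta9_di",
                         suite = mammal_suite(), n_iter = 100, seed = 1)
suite
#> <suite_result> response = delta9_di, n = 54, 100 iterations
#> <model_comparison> 5 models, n = 54
#>              model    aicc delta_aicc weight lambda     r k
#> 1      interaction 159.567      0.000      1  0.259 0.732 8
#> 2         additive 175.762     16.195      0  0.366 0.512 6
#> 3    latitude_only 181.001     21.434      0  0.527 0.000 4
#> 4 environment_only 190.824     31.258      0  0.000 0.349 5
#> 5             null 193.049     33.483      0  0.000    NA 3
#> per-environment latitude slopes (interaction model):
#>     environment   slope     low   high significant
#> 1 fully_aquatic  0.0273  0.0031 0.0516        TRUE
#> 2  semi_aquatic  0.0512  0.0364 0.0659        TRUE
#> 3   terrestrial -0.0122 -0.0338 0.0094       FALSE
```

The comparison table ranks the five candidate models by across-resolution
mean AICc (`delta_aicc` = distance from the best model, `weight` = Akaike
weight, `lambda` = mean ML Pagel's λ, `r` = effect size against the
intercept-only model). Here the generating interaction model wins
outright and the recovered semi-aquatic slope (0.051, CI 0.036–0.066)
covers the simulated truth of 0.06, while the terrestrial slope is
correctly flagged non-significant.

The same analyses run from a shell via the bundled entry point:

```sh
Rscript inst/cli/fadesat simulate  --out-dir sim --seed 42 --n-tips 54
Rscript inst/cli/fadesat reproduce --species-csv sim/species.csv \
    --tree sim/tree.nwk --fa-csv sim/fa_composition.csv --out-dir results
```

`reproduce` writes Table-style model comparisons for both indices,
per-environment slopes, group summaries, the pinniped blubber-section
subanalysis and per-FA latitude regressions, plus a JSON manifest with
input checksums and every seed used. To run it on real data, supply your
own species CSV (columns `species`, `environment`, `latitude`, optional
`hair_density`, `blubber_section`, `pinniped`, `delta9_di`, `dbi`) and a
Newick phylogeny containing the study species.

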