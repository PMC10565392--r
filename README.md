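# treedemog

Hierarchical Bayesian analysis of tree growth and mortality along soil
phosphorus and moisture gradients in forest census-plot networks.

Tropical forests on strongly weathered soils span steep gradients of
plant-available (resin-extractable) phosphorus, and the classic
life-history expectation is that species adapted to infertile soils grow
slower but die less. Testing that requires estimating, species by species,
how growth and mortality respond to shade, size, soil P and moisture —
then comparing species under *common* conditions. `treedemog` is written
for forest ecologists with stem-mapped, multi-census plot data (and for
anyone who wants a fully verifiable synthetic testbed of that design).

## The models

**Growth** (trees alive at both censuses): relative growth rate
RGR = (ln dbh₂ − ln dbh₁)/T follows a robust Student-t,

    RGR_obs ~ t(RGR_pred, σ, ν)
    RGR_pred = β₀ⱼ + β₁ⱼ log(shading + offset) + β₂ⱼ log(dbh)
             + β₃ⱼ log(resin P) + β₄ⱼ moisture

with the normality ν estimated, so growth outliers are downweighted
rather than trimmed.

**Mortality** (all trees alive at census 1), interval-censored so plots
censused 3 and 16 years apart are comparable:

    status ~ Bernoulli(1 − (1 − p_annual)^T)
    p_annual = logistic(β₀ⱼ + β₁ⱼ log(shading + offset) + β₂ⱼ log(dbh)
             + β₃ⱼ log(resin P) + β₄ⱼ moisture)

**Second level**: each species coefficient β_kj ~ Normal(μ_k, σ_k) with
μ_k linear in the species' P, shade and moisture associations and all
their interactions (8 terms, coefficients γ_k,0..7).

**Shading index**: Σ BA·exp(−α·d) over larger neighbours within 10 m,
with one distance-decay α per neighbour size class (≤100, 100–300,
>300 mm dbh), selected by an exhaustive AIC grid search; trees within
10 m of a plot edge are excluded as focal trees.

Fitting uses an adaptive Metropolis-within-Gibbs sampler (C++ core) with
conjugate second-level draws and interweaved non-centred moves, three
chains, and Gelman–Rubin diagnostics (threshold 1.1). The sampler is
validated against an independent grid-approximation posterior and by
credible-interval coverage of generating parameters across seeded
synthetic datasets.

## Worked example

Simulate the default desk-scale community (20 plots spanning resin P
0.2–12.9 mg kg⁻¹, 60 species, 150 stems/plot, census intervals 3–16 y),
run the full pipeline, and look at the growth–mortality trade-off:

```r
library(treedemog)

d <- simulate_dataset(scenario_config(), seed = 1)
d
#> Synthetic dataset: 3000 stems, 20 plots, 60 species
#>   dead fraction: 0.202

res <- run_pipeline(d, out_dir = "demo_out",
                    mcmc = mcmc_config(seed = 1,
                                       sigma_k_range = c(1e-8, 1e3)))
res
#> Demographic analysis pipeline (seed 1)
#>   selected alpha: 0.5, 0.2, 0.7
#>   eligible species: 45
#>   growth max Rhat: 1.255 ; mortality max Rhat: 1.146
#>   trade-off slopes: low-P 7.77; high-P -6.01
```

The generating distance-decay coefficients (0.5, 0.2, 0.7) are recovered
by the AIC search. The trade-off slope is the within-group regression of
log annual mortality on RGR (positive = the classic within-site
trade-off; in this community the designed coupling is weak, so the
smaller high-P group's slope is noise-dominated), while the standardized
predictions (`res$predictions$q5`, `q50`, `q95`) show the between-group
pattern: under infertile conditions the high-P-associated species suffer
higher mortality, and that disadvantage shrinks or reverses at the
fertile end of the gradient.

```r
posterior_summary(res$fit_growth, c("sigma", "nu"))
#>   parameter     median      lower      upper     rhat significant
#> 1     sigma 0.01195592 0.01107371 0.01287225 1.002231        TRUE
#> 2        nu 2.17946002 1.90293269 2.52766802 1.001636        TRUE
```

The fitted normality ν ≈ 2.2 flags the heavy-tailed growth residuals the
generator put in (ν = 2.16). Dropping `sigma_k_range` to 10⁻⁸ widens the
uniform hyper-SD prior below the natural scale of the moisture row
(coefficients are O(10⁻⁵) when moisture deficit enters in raw mm); see the
methods vignette.

For field data, `read_dataset()` ingests census/plot/species CSVs (schemas
documented there, with column remapping and row-indexed validation) and
the same `run_pipeline()` applies.

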