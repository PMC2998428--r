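# reefuse

Use–availability habitat selection analysis for juvenile reef fish surveys.

Newly settled reef fish are often habitat specialists, and the habitat they
depend on as juveniles — algal meadows, live coral, dead coral skeletons,
particular coral morphologies — may differ from where the adults live.
`reefuse` implements a three-tier analysis of belt-transect survey data
(30 × 1 m transects nested within locations, spanning coral-reef and
algal-meadow habitat) that quantifies this specialisation:

1. **Habitat scale** — a Bayesian hierarchical logistic model of species
   presence per transect,

   `y_i ~ Bernoulli(p_i)`, `logit(p_i) = α₀ + α₁·x_i + λ_l(i)`,
   `λ_l ~ Normal(0, σ²_loc)`,

   with `x_i` an algal-meadow indicator and a location random intercept,
   sampled by a built-in adaptive Metropolis-within-Gibbs MCMC (default
   1,000 burn-in + 10,000 retained iterations, Normal(0, 1000) priors on the
   coefficients, half-Normal(0, 2) hyperprior on σ_loc). Per-habitat
   occurrence probabilities get equal-tailed 95% credible intervals; a
   species is classified `coral_greater` / `algal_greater` when the two
   intervals do not overlap. Geweke, Raftery–Lewis and cross-correlation
   diagnostics are built in.

2. **Microhabitat scale** — on transects where a species occurs, the
   percentage of its groups on live coral, dead coral, and both combined,
   with 95% confidence intervals; a preference is flagged when the CI lower
   bound exceeds the mean availability of that substrate (e.g. live coral
   use above mean live coral cover).

3. **Growth-form scale** — for live-coral-preferring species seen on ≥ 12
   transects, selection ratios `w = use proportion / availability
   proportion` per coral growth form (branching, corymbose, encrusting,
   foliaceous, massive, plate, submassive), with transect-level bootstrap
   CIs; a form is `preferred` when the CI lower bound exceeds 1.

A synthetic survey generator (`generate_survey()`) simulates the whole
observation process under known parameters — cover composition, occupancy
model, group formation, electivity-weighted microhabitat choice — so every
stage is verifiable against planted truth. The packaged census table
(`table1_counts()`: 56 species, 11 families, 6,979 individuals over 214
transects) ships as a plain-text fixture.

## Worked example

Simulate a survey with one planted coral specialist (common on reefs,
rare in meadows, 10× live-coral electivity, 8× corymbose electivity) and
one neutral species, then run the full gated pipeline:

```r
library(reefuse)

cfg <- pipeline_config(
  simulation = simulation_config(
    list(species_truth("Pomacentrus synthetica", alpha0 = 1, alpha1 = -3,
                       sigma_loc = 0.3, electivity = c(live_coral = 10),
                       gf_electivity = c(corymbose = 8)),
         species_truth("Halichoeres synthetica", alpha0 = 0, alpha1 = 0)),
    seed = 7),
  seed = 7)
report <- run_pipeline(cfg)
report
#> <pipeline_report>
#>   2 species summarised, 2 retained (>= 5 individuals)
#>   occupancy: 2 fits (1 coral_greater, 0 algal_greater)
#>   preference: 1 live-coral, 0 dead-coral, 1 structure preferrers
#>   selectivity: 1 species screened, 3 preferred form flags
```

Tier 1 — the planted species' occurrence probability is 0.73 (95% CI
0.64–0.82) on coral-reef transects vs 0.13 (0.06–0.22) on algal meadows;
the non-overlapping intervals classify it `coral_greater`, while the
neutral species shows `no_distinction`:

```r
report$occupancy[, c("species", "p_coral_mean", "p_algal_mean", "classification")]
#>   species                p_coral_mean p_algal_mean classification
#> 1 Halichoeres synthetica        0.472        0.608 no_distinction
#> 2 Pomacentrus synthetica        0.727        0.132 coral_greater
```

Tier 2 — on its 108 occupied transects, 77.6% (CI 70.6–84.7) of the planted
species' groups sat on live coral, far above the simulated ~38% live coral
availability, so `prefers_live` (and `prefers_structure`) are TRUE; the
neutral species (23.3%, CI 16.7–29.8) is not flagged.

Tier 3 — only the planted species passes the gate (live-coral preferrer on
≥ 12 transects). Its corymbose selection ratio is 8.5 (bootstrap CI
7.0–10.6), recovering the planted 8× electivity:

```r
dplyr::filter(report$selectivity, growth_form == "corymbose")
#>   species                use_proportion availability_proportion index_w ci_lo ci_hi preferred
#> 1 Pomacentrus synthetica          0.564                   0.066    8.54  6.99  10.6      TRUE
```

`plot_occurrence()`, `plot_preference()` and `plot_selectivity()` draw the
corresponding species panels; `tidy()`/`glance()` give broom-style summaries
of individual `fit_occupancy()` objects, and `read_survey()` /
`write_survey()` move surveys in and out of delimited files.

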