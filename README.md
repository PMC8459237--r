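# ventsucc

Functional-trait succession analysis for benthic colonization time series.

After a large disturbance — here, the archetype is a seafloor eruption that
paves over a deep-sea hydrothermal-vent community — colonists are collected
from sampling surfaces recovered at a series of dates, and the question is
not just *which species* return but *which functions*: body sizes, feeding
methods, trophic levels, protection, dispersal strategies.  `ventsucc`
packages the full quantitative pipeline for that question, for ecologists
working with counts-per-surface tables and species-by-trait modality
tables:

1. **Mixed-type species dissimilarity** — the Gower coefficient with
   Podani's tie-corrected extension for ordinal traits,
   `d_ij = Σ_k w_ijk δ_ijk / Σ_k w_ijk`, skipping missing values through the
   weights.
2. **Functional guilds** — agglomerative clustering of the dissimilarity
   matrix with an automatic cutoff chosen by a within/between-distance
   tradeoff (macro-averaged silhouette by default; full criterion trace and
   a linkage/criterion scan are provided because neither choice is
   canonical).
3. **Diversity through time** — Hill number of order 1 (`exp` of the
   Shannon index) for species and guilds, and Rao's quadratic entropy
   `Q = Σ_i Σ_j d_ij p_i p_j` for abundance-weighted functional diversity.
4. **Trend inference** — multinomial logistic regression of guild or
   modality counts with logits quadratic in time,
   `log(p_k(t)/p_b(t)) = β0_k + β1_k t + β2_k t²`, tested by randomizing
   surfaces against fixed observation times and comparing deviances; and
   quadratic OLS on each diversity index tested by permutation of R².
   Strict and add-one-smoothed permutation p-values are both reported.
5. **Synthetic ground truth** — a generator that plants guild structure in
   trait tables and quadratic softmax trends in abundances, so every stage
   of the pipeline is testable without external data.

## Worked example

```r
library(ventsucc)

cfg   <- synth_config(seed = 2026)        # 58 species, 12 planted guilds
tr    <- make_traits(cfg)                 # trait specs + modality table
ab    <- make_abundances(cfg)             # 36 surfaces across 7 times + reference

d     <- gower_podani(tr$table, tr$specs)
model <- select_cutoff(cluster_guilds(d, "complete"), d)
model
#> guild_model: 12 guilds of 58 species (criterion cluster_silhouette, cutoff height 0.270)
#> guild
#> A B C D E F G H I J K L
#> 5 5 5 5 5 5 5 5 5 5 4 4

series <- pool_by_time(retain_species(filter_samples(ab), tr$table))
div    <- diversity_series(series, model, d)
round(div, 3)
#>     time_months is_pre hill_species hill_guild  raoq
#> pre          NA      1       13.076      2.986 0.250
#> 9             9      0       40.703      8.630 0.473
#> 22           22      0       37.799      8.121 0.472
#> 33           33      0       36.328      7.845 0.464
#> 66           66      0       18.650      4.206 0.331
#> 96           96      0       10.894      2.521 0.215
#> 108         108      0        9.944      2.300 0.195
#> 135         135      0        9.149      2.142 0.176

post <- div[!div$is_pre, ]
randomization_test_r2(post$hill_guild, post$time_months, n_rand = 999, seed = 1)
#> randomization test (R2): observed 0.9710, n_rand 999
#>   p (strict) = 0; p (smoothed) = 0.003 [mode: smoothed]
```

Reading the output: the guild cutoff lands at dissimilarity 0.270 and
recovers the 12 planted guilds; the pooled series shows effective species
and guild numbers declining across this particular simulated succession
(the planted trends for seed 2026 happen to concentrate abundance late in
the series); and the quadratic trend in guild diversity (R² = 0.971) is
significant under permutation — no more than a couple of the 999 shuffles
of values against times fit as well.

The same pipeline runs from files (`read_trait_table()`,
`read_abundance()`, long or wide counts dialects) via `cmd_run()`, which
writes the dissimilarity matrix, Newick dendrogram, guild labels,
per-trait modality-abundance tables, guild-abundance table, diversity
series, trend report and a run log into an output directory.  A thin
command-line wrapper lives at `inst/scripts/ventsucc`
(`ventsucc simulate|run|scan-clustering --config cfg.yaml`).

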