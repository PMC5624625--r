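# gradiv

Community-phylogenetics analysis of plot-based vegetation surveys along
environmental gradients, for ecologists asking *which processes assemble
local communities*: environmental filtering, competition, or neutral
dynamics. gradiv covers the full chain for three facets of diversity —
taxonomic, phylogenetic and functional — and ships a synthetic-data
generator with known ground truth so every inferential stage has a
recovery test.

## What it computes

**Phylogenetic signal** of each functional trait:

- Blomberg's *K* = [(x−â1)ᵀ(x−â1) / (x−â1)ᵀC⁻¹(x−â1)] ÷
  [(tr C − n/(1ᵀC⁻¹1)) / (n−1)], with â the GLS mean and C the
  phylogenetic variance–covariance matrix; *K* = 1 under Brownian motion.
- Pagel's λ by profile maximum likelihood on [0, 1] (off-diagonal of C
  scaled by λ).
- Significance for both by randomly re-arraying trait values across the
  tips (1000 randomizations, add-one correction).

**Functional dendrogram**: log-transform + z-score the traits, PCA
(correlation matrix, deterministic signs), Euclidean distance on the
retained component scores, UPGMA with a lexicographic tie-break;
cophenetic distances feed the functional dispersion metrics.

**Alpha/beta diversity**: species richness and Bray–Curtis similarity
(taxonomic); abundance-weighted mean pairwise distance
MPD = Σᵢ≠ⱼ fᵢfⱼdᵢⱼ / Σᵢ≠ⱼ fᵢfⱼ within or between plots, a tip-shuffle
null model that holds the community matrix fixed, and the net relatedness
index

```
NRI = −1 × (MPD_sample − mean MPD_null) / sd MPD_null
```

(positive = clustering, negative = overdispersion), computed identically
on the phylogeny (phylogenetic diversity) and the trait dendrogram
(functional diversity).

**Driver attribution**: climate PCA (two axes from seven climate
variables), log-slope and arcsine-√ rocky-area-ratio habitat transforms,
geographic distance under an equidistant cylindrical projection, climatic
/ habitat / environmental Euclidean distances (D²env = D²clim + D²habit
exactly), simple OLS, simple Mantel tests, all-subsets OLS with AICc and
summed-Akaike-weight variable importances (15 models for four predictors,
7 for three), variation partitioning by partial regressions, and multiple
regression on distance matrices (MRM) with permutation p-values.

**Synthetic data**: Yule phylogenies (depth-normalized), traits from
σ²C(λ), and gradient communities assembled by filtering (optima follow a
conserved trait), competition (limiting-similarity rejection) or neutral
placement, plus elevation-driven climate and noisy habitat variables —
all deterministic given a `scenario_config()`.

## Worked example

Simulate a 50-plot filtering transect (species pool shrinking with
elevation), then run the full pipeline:

```r
library(gradiv)
cfg <- list(
  scenario = scenario_config(n_species = 60, n_plots = 50, seed = 17,
                             scenario = "filtering", elev_bias = 2),
  n_null = 199, n_perm = 199, n_perm_signal = 199, seed = 17)
res <- run_all(cfg)

res$signal[, c("trait", "K", "p_K", "lambda_hat", "p_lambda")]
#>             trait     K   p_K lambda_hat p_lambda
#> 1      max_height 0.744 0.005      1.000    0.005
#> 2     leaf_length 0.944 0.005      1.000    0.005
#> 3      leaf_width 1.311 0.005      1.000    0.005
#> 4 flowering_onset 0.546 0.005      0.951    0.005
#> 5       seed_mass 0.920 0.005      0.995    0.005

head(res$alpha_phylo[, c("unit_id", "mpd_obs", "null_mean", "null_sd", "nri")], 4)
#>   unit_id mpd_obs null_mean null_sd    nri
#> 1    p001    1.47      1.49  0.0449  0.456
#> 2    p002    1.52      1.49  0.0444 -0.643
#> 3    p003    1.53      1.49  0.0404 -0.947
#> 4    p004    1.51      1.49  0.0343 -0.509

mean(res$alpha_phylo$nri)
#> [1] 0.64

subset(res$importance_alpha, index == "PAD")
#>   index variable importance              best
#> 5   PAD pc1_clim       1.00 pc1_clim+pc2_clim
#> 6   PAD pc2_clim       0.52 pc1_clim+pc2_clim
#> 7   PAD  slope_t       0.26 pc1_clim+pc2_clim
#> 8   PAD    rar_t       0.27 pc1_clim+pc2_clim
```

Traits simulated under Brownian motion show strong signal (λ̂ ≈ 1, all
permutation p at the floor of 1/200); the filtering community is
phylogenetically clustered on average (mean NRI +0.64); and the summed
Akaike weights correctly attribute the dispersion gradient to the climate
axes (importance 1.00 and 0.52) rather than to the pure-noise habitat
variables (0.26, 0.27) — the ground truth the generator built in.

A command-line wrapper with `simulate` / `signal` / `dendrogram` /
`alpha` / `beta` / `all` subcommands lives at `inst/cli/gradiv.R`:

```sh
Rscript inst/cli/gradiv.R simulate --n-species 120 --n-plots 50 \
    --scenario filtering --seed 1 --out sim/
```

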