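# symnet

Contemporaneous symptom-network analysis for ordinal patient-reported
outcomes, built around the 13-item severity domain of the MD Anderson
Symptom Inventory (MDASI).

Cancer survivors typically carry several co-occurring symptoms (fatigue,
disturbed sleep, distress, nausea, ...). Treating each symptom marginally
ignores how they sustain one another. A *symptom network* instead treats
each symptom as a node and estimates, for every pair, the association that
remains after conditioning on all other symptoms (and on relevant
covariates): the partial correlation

&nbsp;&nbsp;&nbsp;&nbsp; w<sub>ij</sub> = −k<sub>ij</sub> / √(k<sub>ii</sub> k<sub>jj</sub>),

where K is the precision matrix of a latent Gaussian underlying the 0–10
ordinal ratings. `symnet` implements the full estimation-and-inference
stack used in this literature:

* **polychoric correlations** for ordinal items (two-stage ML with
  positive-semidefinite repair), Spearman as a fast alternative;
* **graphical lasso** (block coordinate descent, authored here in
  Rcpp/RcppArmadillo) over a 100-point log-spaced penalty path with
  **extended-BIC** selection (γ = 0.5 by default) and covariate control;
* **centrality indices** — strength, closeness, betweenness (fractional
  tie credit), expected influence — on the weighted graph with edge length
  1/|w|;
* the **network density** statistic Σ<sub>s</sub> (sum of absolute Spearman
  correlations over all pairs) and **node predictability** (variance of a
  node explained by its selected neighbors);
* **inference by resampling**: nonparametric bootstrap CIs for edge
  weights, the case-dropping correlation-stability (CS) coefficient,
  bootstrapped difference tests for edges and centralities, and a
  label-permutation test for subgroup density differences;
* a **synthetic cohort generator** (latent Gaussian graphical model with
  calibrated zero-inflated item marginals, covariate effects, and
  survivorship strata with a denser "<5 years" network) providing ground
  truth for every stage.

## Worked example

```r
library(symnet)

spec <- generator_spec(n_per_group = c("<5y" = 200, "5-10y" = 120, ">10y" = 80),
                       seed = 7)
d <- generate_study(spec)
d
#> symptom_dataset: 400 participants x 13 items, 3 covariates, groups: <5y/>10y/5-10y

reg <- overall_severity_regression(d, min_positive = 50)
reg
#> severity regression (n = 400): R2_adj = 0.180, F = 30.229
#>       covariate       beta            p
#>    chemotherapy  0.3391380 5.250230e-13
#>  cardiovascular  0.1508333 9.759536e-04
#>  duration_years -0.2157878 2.776551e-06
#> selected (p < 0.05 ): chemotherapy, cardiovascular, duration_years

net <- estimate_network(d, estimation_settings(), covariates = reg$selected)
net
#> pcor_network: 13 nodes, 33 edges (lambda = 0.0601, gamma = 0.50, n = 400)
#>   conditioned on: chemotherapy, cardiovascular, duration_years

ct <- centrality_table(net)
head(ct[order(-ct$strength), ], 4)
#>      node strength   closeness betweenness expected_influence
#>      pain 1.140967 0.005954617           9          0.6395326
#>  vomiting 1.054419 0.005682508           5          0.8965398
#>  distress 1.052051 0.006316343          15          0.4809554
#>   sadness 1.043354 0.006316693           4          1.0024474

network_density(d)
#> network density (spearman basis): 23.7445

density_comparison_test(d, c("<5y", "5-10y"), n_perm = 500, seed = 7)
#> density permutation test: |diff| = 27.853 (<5y: 38.98 vs 5-10y: 11.13), p = 0.001996
```

Reading the output: the severity regression retains all three covariates
(positive chemotherapy and cardiovascular effects, negative survivorship
duration), so the network is estimated conditionally on them. The selected
network keeps 33 of 78 possible edges; the strongest nodes carry summed
absolute edge weights around 1.1. The generator gave the "<5y" stratum a
1.5× denser latent network, and the permutation test detects exactly that
contrast (Spearman density 38.98 vs 11.13, p ≈ 0.002).

The heavyweight inference pieces follow the same pattern:

```r
boot <- bootstrap_edge_ci(d, estimation_settings(), covariates = reg$selected,
                          B = 1000, seed = 7)      # percentile CIs per edge
stab <- case_dropping_stability(d, estimation_settings(), "strength",
                                B = 1000, seed = 7) # CS coefficient
diff <- bootstrap_difference_test(boot, "edges")    # pairwise edge tests
```

`run_full_pipeline()` chains every stage (data → regression → network →
metrics → bootstraps → subgroup comparisons) from one config list or YAML
file and writes all artifacts plus a `summary.json`; rerunning with the
same seed reproduces every file byte for byte. The same pipeline is
scriptable from a shell via `inst/scripts/symnet.R`
(`simulate | estimate | metrics | bootstrap | stability | difftest |
compare | run`).

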