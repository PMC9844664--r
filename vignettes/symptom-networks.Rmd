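---
title: "Estimating contemporaneous symptom networks from ordinal severity ratings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating contemporaneous symptom networks from ordinal severity ratings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symnet)
```

## The model

`symnet` estimates an undirected *contemporaneous* network over the 13
symptom-severity items of the MD Anderson Symptom Inventory (MDASI), each
rated 0–10 at a single time point. Nodes are symptoms; an edge between
symptoms $i$ and $j$ is the partial correlation

$$ w_{ij} = -\,\frac{k_{ij}}{\sqrt{k_{ii}\,k_{jj}}}, $$

where $K = (k_{ij})$ is the precision (inverse-covariance) matrix of a
latent multivariate Gaussian assumed to underlie the observed ordinal
scores. A zero $w_{ij}$ means conditional independence given all other
nodes; a nonzero edge is a candidate direct association that survives
conditioning on the rest of the network (and, optionally, on covariates).

Estimation proceeds in three stages:

1. **Ordinal correlations.** Because the items are heavily zero-inflated
   ordinal scales, Pearson correlations of raw scores are attenuated and
   distorted. We estimate *polychoric* correlations: for each pair of items
   the marginal category proportions fix per-item normal thresholds
   ($\tau_k = \Phi^{-1}$ of the cumulative proportions), and the latent
   correlation $\rho$ maximizes the bivariate-normal cell-probability
   likelihood over $(-0.999, 0.999)$ by bounded 1-D search (tolerance
   $10^{-6}$). This two-stage scheme (thresholds first, then $\rho$) is the
   standard, stable choice; full joint ML buys little at these sample sizes.
   The pairwise matrix need not be positive semidefinite, so it is repaired
   by eigenvalue clipping at $10^{-6}$ followed by rescaling to unit
   diagonal; a flag records whether the repair changed anything. Spearman
   correlations (Pearson on average ranks) are available as a faster
   alternative input and are the basis of the density statistic below.

2. **Sparse precision estimation.** The graphical lasso maximizes
   $\log\det K - \operatorname{tr}(SK) - \lambda \sum_{i \ne j} |k_{ij}|$
   (diagonal unpenalized) by block coordinate descent over columns of the
   working covariance, each block an inner lasso coordinate descent with an
   active-set strategy. The penalty path holds 100 log-spaced values from
   $\lambda_{\max}$ (the largest absolute off-diagonal of $S$, at which the
   network is exactly empty by the KKT conditions) down to
   $0.01\,\lambda_{\max}$, with warm starts along the path.

3. **Model selection.** The extended BIC,
   $\mathrm{EBIC} = -2\ell(\hat K) + E\log n + 4\gamma E \log p$ with
   $\ell(\hat K) = \tfrac{n}{2}(\log\det\hat K - \operatorname{tr}(S\hat K))$
   and $E$ the number of selected edges, picks the penalty. We default to
   $\gamma = 0.5$, the conservative field standard for psychometric
   networks.

### Covariate control

Covariates associated with overall severity (selected by a standardized
linear regression of the 0–130 total severity score, two-sided
$\alpha = 0.05$; binary candidates with fewer than 100 positive cases are
screened out for power) are controlled in the default mode by entering the
joint network as additional nodes — rank-based correlations link them to the
symptoms — and then dropping their rows and columns from the selected
partial-correlation matrix. Because partial correlations condition on *all*
other nodes, the retained symptom–symptom edges are adjusted for the
covariates. This preserves the ordinal margins that polychoric estimation
needs. A `residualize` mode (symptom ranks pre-residualized on covariates)
is kept for sensitivity analysis; the two modes coincide exactly when no
covariates are supplied.

## Network summaries

* **Strength** $r_s(i) = \sum_j |w_{ij}|$ and **expected influence**
  $\sum_j w_{ij}$ (signed).
* **Shortest-path metrics** use edge length $1/|w_{ij}|$, so strong
  associations are short. **Closeness** is the reciprocal of the *sum* of
  distances to reachable nodes — the convention of the software family this
  analysis style comes from; an isolated node gets 0. (Sum vs. mean differ
  per node only by a constant factor; the choice is documented here and
  configurable downstream of the distance matrix.) **Betweenness** counts,
  for every other pair, shortest paths through the node, splitting credit
  equally across tied shortest paths. Ties have measure zero for continuous
  weights but arise in constructed graphs, so the fractional rule is the
  safe general definition.
* **Network density** $\Sigma_s$ is the sum of absolute Spearman
  correlations over all node pairs — a global connectivity summary that has
  been linked to prognosis. Note it is a property of the *correlation*
  matrix, not of the sparsified network; an `edge_weights` basis is offered
  for sensitivity.
* **Node predictability** is the variance share of each node's
  rank-transformed score explained by ordinary least squares on its selected
  network neighbors' rank-transformed scores (0 for isolated nodes;
  collinear neighborhoods are flagged). This reproduces the meaning of the
  usual mixed-graphical-model predictability — variance explained by the
  neighborhood — without a second model family; it is an approximation, and
  documented as such.

## Resampling inference

* **Edge accuracy**: nonparametric bootstrap (resampling participants with
  replacement, default $B = 1000$) refits the *entire* estimator per
  replicate — including penalty re-selection — so model-selection
  uncertainty propagates into the percentile 95% CIs. Replicates that fail
  to estimate are dropped and counted; more than 10% failures aborts.
* **Centrality stability**: the case-dropping subset bootstrap removes a
  proportion $q$ of participants (grid 0.10–0.75 in steps of 0.05), refits,
  and correlates subsample centralities with the full-sample values. The
  CS coefficient is the largest $q$ at which at least 95% of replicates
  correlate $\ge 0.7$; values above 0.5 are preferred and 0.25 is the
  interpretability floor.
* **Difference tests**: for every pair of edges (or node statistics) the
  bootstrap distribution of the difference yields a central percentile
  interval; a pair differs significantly when the interval excludes zero.
  No multiplicity correction is applied, mirroring common practice; treat
  isolated significant pairs with caution.
* **Subgroup density**: the absolute difference of two strata's Spearman
  densities is compared against a null built by permuting stratum labels
  (default 1000 permutations), with the add-one p-value
  $(1 + \#\{d^\ast \ge d\})/(1 + n_\mathrm{perm})$, which cannot be zero.
  The underlying contrast (survivorship strata differing in global
  connectivity) names no canonical test, so a label-permutation test is
  this package's construction of it.

All resampling draws per-replicate seeds from a counter-indexed substream of
one master seed, so results are bit-reproducible and enlarging $B$ never
reshuffles earlier replicates.

## The synthetic-data generator

Real MDASI cohort data are not redistributable, so the package ships a
generator that plays the role of ground truth for every downstream stage.
It emulates a community cancer-survivor cohort:

* **Items.** 13 zero-inflated 0–10 items. A latent standard-normal score per
  item is cut at 10 per-item thresholds. The first cutpoint reproduces each
  item's published prevalence (27.8%–72.7%); the remaining mass decays
  geometrically over scores 1–10 with the rate solved so the item mean
  matches its published value (1.02–2.71). Zero inflation therefore lives
  entirely in the first cutpoint — no separate zero-mass component — which
  keeps the latent-Gaussian assumption exact, so polychoric recovery tests
  are well-posed. The latent scale is fixed to unit variance per item;
  thresholds absorb location and scale, which identifies the polychoric
  parameters.
* **Network.** A random graph (default edge probability 0.2) with partial
  correlations of magnitude 0.1–0.4 and random sign, plus two anchored
  strong edges — distress–sadness and nausea–vomiting at 0.35 — mirroring
  the robust pair associations this literature reports. Positive
  definiteness is enforced by diagonal augmentation and rescaling to a
  unit-diagonal implied correlation matrix (which leaves partial
  correlations unchanged when no augmentation is needed and shrinks them
  uniformly when it is).
* **Strata.** Three survivorship strata, default sizes 530/320/215 (summing
  to 1065; the source cohort reports no stratum sizes, so these follow the
  published duration distribution, mean 5.5 years, range 0.5–26). Stratum
  densities are manipulated by multiplying off-diagonal partial correlations
  (default 1.5/1.0/1.0, the "<5y" network denser), re-projected to positive
  definite by eigenvalue clipping at $10^{-3}$ — deterministic and
  order-independent — then rescaled to a unit-diagonal implied correlation.
* **Covariates.** Binary chemotherapy (prevalence 0.512) and cardiovascular
  disease (0.142), and survivorship duration uniform within each stratum's
  year range. Effects enter as latent mean shifts applied uniformly to all
  items (defaults +0.25 SD chemotherapy, +0.20 SD cardiovascular, −0.02
  SD/year duration), chosen to reproduce the published sign pattern of the
  severity regression (positive chemotherapy and cardiovascular effects,
  negative duration effect) at realistic magnitudes.

What the generator does *not* emulate: longitudinal autocorrelation,
missing-data mechanisms, item-level floor effects beyond the threshold
model, informative sampling, and any non-Gaussian latent dependence
(e.g. tail dependence between symptoms). Tests passing on this generator
therefore validate the *machinery* — estimator, metrics, resampling — under
the stated model, not robustness to violations of it.

## Numerical choices

* Glasso convergence: outer tolerance $10^{-6}$ (relative to the mean
  absolute off-diagonal of $S$) on the working covariance, inner coordinate
  descent to $10^{-8}$; the single-fit entry point defaults tighter
  ($10^{-7}$). Failure to converge is an error, never silently accepted.
* Edge support is read at $|k_{ij}| > 10^{-6}$.
* Polychoric cell probabilities floor at $10^{-12}$ inside the likelihood;
  the bivariate-normal CDF uses 48-node Gauss–Legendre quadrature on the
  correlation-integral identity, accurate to well below the estimation
  noise for $|\rho| \le 0.999$; estimates at the boundary are clamped to
  $\pm 0.999$ and flagged.
* Zero-variance items get Spearman correlation 0 (flagged), not `NaN`;
  degenerate stability replicates (constant centralities) count as
  correlation 0, flagged.
* Missing data: listwise deletion at dataset construction, so a single
  effective $n$ feeds the likelihood, the EBIC, and every resampling stage.
* Subgroup boundaries: "<5y" is $[0.5, 5)$, "5–10y" $[5, 10]$, ">10y"
  $(10, 26]$ years.

## Known limitations

* EBIC over the *penalized* likelihood (no refit) inherits the documented
  behavior of this estimator family: when strong true edges are present,
  decreasing $\lambda$ keeps improving the likelihood by unshrinking them,
  and small spurious edges ride along. Support recovery therefore has high
  recall but only moderate precision at cohort-scale $n$; the bootstrap
  difference tests and edge CIs are the instrument for judging which edges
  are trustworthy, not the raw support.
* Percentile bootstrap CIs of L1-shrunk edge weights over-cover zero for
  null edges (the sampling distribution has an atom at 0), so they must not
  be read as significance tests of absent edges.
* The density statistic uses marginal Spearman correlations and is not
  adjusted for covariates; the permutation test compares strata on exactly
  that statistic.
* Reported strength values depend on whether covariate nodes are included
  and on the correlation basis; this package reports raw sums over symptom
  nodes only and makes no attempt to match any particular published scale.

## Problem sizes used in the shipped validation

The test suite and the acceptance script validate the machinery at desk
scale: oracle equivalence of the glasso on $p = 3$ problems and of the
centralities on 6-node graphs; polychoric recovery at $n = 5000$; support
recovery at $n = 1000$ over 20 generator draws; bootstrap CI calibration at
$n = 300$, $B = 500$, 50 simulations; stability at $n \in \{120, 2000\}$
with $B = 200$ (evaluation grid 0.10/0.25/0.50/0.75); permutation level and
power at 200 and 20 replications; and a full pipeline run at cohort scale
($n = 1065$, $B = 200$). These sizes are the package's own validation
choices; the estimators themselves default to the field-standard
$B = 1000$ and 1000 permutations.
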