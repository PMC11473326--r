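---
title: "Models and methods for low-phosphorus seedling screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for low-phosphorus seedling screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lowPmaize)
```

## The trial and its model

The package analyses replicated seedling trials in which a panel of
maize inbred lines is phenotyped for root and shoot traits under two
phosphorus regimes — an optimal applied-P condition (AP) and a low-P
stress condition (NAP) — in a randomized block design. The reference
parameterization shipped with the package describes such a trial with
151 lines, 3 blocks per condition and 13 traits.

Within one condition, each trait is modelled as

$$y_{ij} = \mu + b_j + g_i + e_{ij},$$

with fixed block effects $b_j$, random line effects
$g_i \sim N(0, \sigma^2_G)$ and residuals
$e_{ij} \sim N(0, \sigma^2)$. Across conditions the combined model is

$$y_{ijc} = \mu + \pi_c + b_{j(c)} + g_i + (g\pi)_{ic} + e_{ijc},$$

with fixed condition effects $\pi_c$, blocks nested in conditions, and
an additional random line-by-condition interaction
$(g\pi)_{ic} \sim N(0, \sigma^2_{G\times P})$. A single residual
variance is assumed across conditions: the reference trial reports one
combined residual component, and a heteroscedastic extension is out of
scope. Variance components are estimated by REML (through `lme4`, the
standard mixed-model engine for this design), and genotypic values are
reported on the observable trait scale as $\hat\mu + \mathrm{BLUP}(g_i)$,
i.e. shrunken line means. For balanced data these REML estimates
coincide with the ANOVA method-of-moments estimators truncated at zero,
which the test suite asserts to $10^{-6}$ relative tolerance; the
optimizer tolerances are tightened to $10^{-12}$ to make that sharp.

Random effects are tested by the likelihood-ratio deviance
$2(\ell_{\text{full}} - \ell_{\text{reduced}})$ against $\chi^2_1$. The
reduced model for the line term is the fixed-effects-only linear model,
whose restricted log-likelihood (`logLik(..., REML = TRUE)`) is on
exactly the same scale as the mixed fit — we verified that the REML
criterion of the mixed model evaluated at zero variance equals the
linear-model value. Because the null hypothesis pins a variance to the
boundary of its space, the plain $\chi^2_1$ reference is conservative;
we keep it as the primary p-value (it is the conventional report for
this design) and expose the 50:50 boundary-mixture p-value as
`p_value_mixture`. The conservatism is quantified in the test suite: the
empirical type-I rate at $\sigma^2_G = 0$ stays below the nominal 0.01
over 500 simulated trials.

## Genetic parameters

Entry-mean heritability per condition is
$h^2 = \sigma^2_G / (\sigma^2_G + \sigma^2/r)$ and, combined,
$h^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_{G\times P}/p +
\sigma^2/(rp))$, with $r$ replications and $p$ conditions. Estimates
are clamped to $[0, 1]$ (truncated variance components can otherwise
produce degenerate ratios); the raw value is kept as an attribute. The
coefficient of variation is reported as $100\sqrt{\sigma^2}/\bar{y}$ —
the residual CV on the genotypic mean, which is the definition that
reproduces the reference trial's printed CV column exactly (e.g. 21.79
for lateral root length under stress). The stress response is
$100\,(\bar{y}_{AP} - \bar{y}_{NAP})/\bar{y}_{AP}$, negative for traits
such as root:shoot ratio and root tissue density that increase under
P starvation.

## Correlations and multicollinearity

Pearson correlations are computed between trait BLUP vectors within a
condition, and Spearman rank correlations between the same trait's
BLUPs across conditions; the latter diagnose cross-over interaction
(tolerant-ranking changes), and ties receive average ranks — BLUPs of
continuous traits essentially never tie. Significance is flagged at
0.01 with no multiplicity correction, matching the conventional report
for this kind of table.

Before diversity analysis, collinear traits are pruned by variance
inflation factors, $VIF_j = 1/(1 - R^2_j)$, equivalently the diagonal
of the inverse trait-correlation matrix. Derived traits (total dry
weight = root + shoot dry weight, and the ratio traits) make exact or
near dependences common, so the matrix can be singular; the
implementation then falls back to per-trait regressions via QR and
reports infinite VIFs for the involved traits. Pruning removes, at each
step, the trait with the largest VIF taken as the **maximum over the
two conditions**, until all VIFs are at or below the threshold
(default 10) under both. The joint-maximum criterion enforces by
construction that the same traits are discarded under AP and NAP, and
alphabetical tie-breaking makes the procedure deterministic. The
eight-trait set retained in the reference trial (SD, PH, RSR, DG, LRL,
RV, RAD, RTD) ships as `trait_preset("paper8")` so downstream stages
can reproduce that selection on new data.

## Diversity

BLUPs are standardized per trait (mean 0, sd 1, denominator $n-1$
throughout), and line-pair distances are mean Euclidean distances —
root-mean-square differences over traits,
$d_{ik} = \sqrt{\tfrac{1}{T}\sum_t (z_{it} - z_{kt})^2}$. Dividing by
the trait count makes the distance scale invariant to how many traits
survive pruning, which is the convention in plant-diversity studies and
keeps distances on standardized traits in the sub-unit range reported
for panels of related lines. UPGMA (size-weighted average linkage)
produces an ultrametric tree; the implementation delegates to
`stats::hclust` and is cross-checked against a brute-force $O(n^3)$
agglomeration oracle in the tests. Trees export to Newick with the
half-merge-height branch-length convention via `ape`.

Clusters come from the Mojena rule: cut at
$\bar{h} + k\,\mathrm{sd}(h)$ over the fusion levels $h$. The constant
defaults to $k = 1.25$, the Milligan–Cooper recommendation, and is
user-configurable; merges strictly above the cutoff are severed while
equality merges are kept, so a degenerate tree with all fusion levels
equal yields one cluster.

## Selection indices

Tolerance is quantified on relative trait values, the elementwise ratio
of NAP to AP genotypic values (denominators within $10^{-8}$ of zero
are rejected by name — BLUPs of biological traits are bounded away from
zero, but the guard must exist). The ratios are standardized and
subjected to PCA on their correlation matrix; components with
eigenvalue $\ge 1$ (Kaiser rule) are retained and combined as
$\mathrm{LPTI} = \sum_i PC_i \cdot CR_i$ with contribution rates
$CR_i = \lambda_i / T$ — the share of **total** variance, not of
retained variance, so the weights do not inflate when few components
survive. LPPI applies the identical construction to the standardized
NAP BLUPs themselves. Eigenvector signs are arbitrary; each component
is oriented so its loading sum is positive, which makes lines that are
uniformly large on predominantly positively-correlated trait sets score
positively — the natural "more is better" reading for biomass-type
panels. The orientation is a documented convention, not an inference.

Lines are classified by index signs into TG (tolerant, good
performance: both indices positive), TP, SG and SP; since both indices
are weighted sums of zero-mean scores, zero is the natural threshold,
and exact zeros fall on the sensitive/poor side. Top-$k$ and
bottom-$k$ selection uses the sum of the two index rankings (rank 1 =
highest index), with alphabetical tie-breaks; single-index rankings are
available via the `criterion` argument. The rank-sum rule is our
choice for "selection on both indices" — no unique rule is implied by
that phrase — and it reproduces the qualitative behaviour expected of
it (lines at the top of both single-index rankings are always
selected).

## The synthetic generator

`simulate_phenotypes()` draws, per trait,
$y = \mu_c + b_{j(c)} + g_i + (g\pi)_{ic} + e$ with a line effect shared
across conditions and independent condition-specific deviations. This
makes the combined-model decomposition identifiable and induces
cross-over rank changes: the across-condition correlation of total line
effects is $\sigma^2_G / (\sigma^2_G + \sigma^2_{G\times P})$, so the
default parameterization produces the low-to-moderate cross-condition
Spearman correlations characteristic of real low-P trials. Defaults
come from the reference trial: condition means and reductions from its
summary table, and the **combined-analysis** variance components per
trait — those are the identifiable parameters of this model, whereas
the per-condition genetic variances it reports differ by condition,
which a homoscedastic shared-effect model cannot represent. Block
effects are drawn $N(0, 0.25\,\sigma^2)$ — no block variance is
reported anywhere for this design, and a quarter of the residual
variance is a realistic magnitude for greenhouse blocks. Missing-data
injection (uniform, configurable rate) exists but is off by default;
the design is balanced. One global seed drives everything, with
per-trait streams derived deterministically from it, so equal
configurations give byte-identical tables.

What the generator does **not** emulate: cross-trait correlations
(traits are simulated independently, so VIF pruning on simulated data
rarely discards anything — the pruning logic is instead exercised on
panels constructed with exact derived-trait identities), non-Gaussian
residuals, spatial greenhouse trends, and condition-specific residual
variances. Passing tests on simulated panels therefore validate the
estimators under the stated model, not the model's adequacy for any
particular real data set.

## Numerical choices and problem sizes

Variance components are estimated with lme4's bounded optimizer at
tightened tolerances ($10^{-12}$); zero estimates are genuine boundary
values, not truncations of negative numbers. Small negative LRT
deviances from convergence noise are clamped to zero (p = 1).
Heritabilities are clamped to $[0,1]$ with the raw ratio retained.
Standardization refuses constant traits by name; correlation matrices
flag constant traits with `NA` entries and a warning instead.

The test suite validates parameter recovery at the reference trial's
own scale (151 lines, 3 blocks, 200 simulated trials; the mean REML
estimate recovers the generating components within 0.3% in our runs,
asserted at 5%), the LRT size at the null over 500 trials, UPGMA
against the brute-force oracle on 100 random 8-leaf matrices, VIF
against per-trait regressions at $10^{-8}$, and latent-factor recovery
of LPTI (Spearman > 0.9 at noise sd equal to 30% of the signal sd).
These sizes were chosen so the whole suite runs in about a minute while
keeping Monte-Carlo error an order of magnitude below every asserted
tolerance.

## Known limitations

Heritability standard errors and confidence intervals are not computed
(none are conventionally reported for this design). Subgroup structure
within clusters has no principled rule under the Mojena cut and is not
implemented. Genetic correlations from bivariate mixed models (as
opposed to correlations of genotypic values) are out of scope, as are
alternative stress indices (stress susceptibility index, geometric mean
productivity) and linkages other than UPGMA, though `hclust` makes the
latter an easy escape hatch for the curious user.
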