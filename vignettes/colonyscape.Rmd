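---
title: "Methods: from worker genotypes to habitat quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from worker genotypes to habitat quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonyscape)
```

# The inference problem

Bumblebee colonies cannot be counted directly, but the workers a collector
nets while they forage carry enough genetic information to reconstruct the
colonies behind them. `colonyscape` implements the full chain:

1. partition genotyped workers into full-sister families
   (`reconstruct_sibships()`),
2. triangulate each family's colony as the mean center of its sisters'
   capture points and measure per-worker geodesic foraging distances
   (`colony_records()`),
3. summarize grid cells by the effective colony number `colNe` and the
   average colony-level mean foraging distance `aveMeanFD`
   (`summarize_cells()`),
4. relate those two responses to landscape and demographic covariates
   (`spearman_fdr()`, `best_subset_regression()`, `rda_fit()`,
   `varpart3()`).

A seeded generator (`simulate_study()`) emulates the whole data-generating
process so each stage can be validated by parameter recovery.

# The sibship model

## Genetic assumptions

Bumblebees are haplodiploid: females are diploid, males haploid, so full
sisters always share their father's single allele. The model further
assumes one queen per colony (polygyny is extremely rare in bumblebees)
and one mating per queen; the rare multiply-mated queen produces half-sib
subsets that the model will simply report as separate full-sib families,
which biases colony counts slightly upward but leaves foraging-distance
triangulation valid within each subset.

Genotyping error uses two rates. A *mistype* (default `e = 0.01`) replaces
an observed allele, independently per allele, by a random allele drawn from
the locus frequencies; this covers miscalls and mutations. A *dropout*
(default 0) voids the locus call. Defaults reflect what a well-curated
microsatellite panel achieves after chromatogram review.

## Likelihood

For a putative family with members $w = 1..s$, locus $\ell$, queen alleles
$(a,b)$ and father allele $c$:

$$L_\ell = \sum_{a \le b} p_a p_b (2 - \delta_{ab}) \sum_c p_c
  \prod_w \left[\tfrac12 P(o_w \mid \{a,c\}) + \tfrac12 P(o_w \mid \{b,c\})\right]$$

where $P(o \mid t)$ applies the mistype model to the unordered observed
pair $o$ given true genotype $t$. Loci are independent and log-likelihoods
sum; missing calls contribute zero. With one member this reduces exactly to
the Hardy–Weinberg genotype probability, which is also the "unrelated"
null (`unrelated_loglik()`), so likelihood-ratio comparisons are coherent
by construction.

The sum over $(a,b,c)$ is evaluated on a *collapsed allele space*: alleles
not observed in any member are pooled into a single rest class carrying
their summed frequency. Because the summand is constant across unobserved
alleles, this is exact, and it keeps evaluation fast even for loci with 30
alleles. The test suite checks the collapsed sum against naive full
enumeration.

Observed alleles missing from the frequency table receive a floor
frequency, default $1/(2n+1)$ with $n$ the number of workers the
frequencies were estimated from. Frequencies themselves are estimated from
all workers before reconstruction; this admits a slight upward kinship
bias but avoids a circular dependency on the partition.

One property worth stating because it is easy to get wrong: sharing an
allele at every locus does **not** guarantee that a pair fits the full-sib
model better than the unrelated null. A pair (A,B)/(A,C) forces the shared
allele to be paternal, and at an equifrequent locus that constraint costs
more likelihood than it buys. Only identical multilocus genotypes carry a
guaranteed nonnegative gain (brute-force confirmed in the tests). True
12-locus sister pairs still separate essentially perfectly from unrelated
pairs (AUC > 0.99 at the panel's diversity).

## Search, support, retention

Reconstruction is a multi-restart randomized agglomerative search: start
from singletons, repeatedly apply the merge with the largest positive
total-log-likelihood gain, stop when no gain exceeds `tau` (default 0; a
stricter positive value acts as a complexity penalty). Candidate merges
are restricted to pairs sharing at least one allele at all but
`allow_mismatch = 2` jointly typed loci — a speed device only, since a
true sister pair loses sharing at two or more of twelve loci with
probability well under 1% at `e = 0.01`.

Cluster *support* is the fraction of restarts (default 3) whose final
partition contains exactly that member set; the reported partition is the
highest-likelihood restart. This restart-consensus support is a stated
stand-in for the posterior inclusion probabilities a full-likelihood MCMC
sampler would give; it is coarse (steps of 1/restarts) but uses the same
retention rule: clusters with support ≥ 0.80 (inclusive) and ≥ 2 members
are kept (`filter_clusters()`), everything else reverts to singletons.

# Spatial conventions

* **Geodesic distance** is haversine on a sphere of radius 6,371,008.8 m;
  an ellipsoidal (Karney-style) alternative sits behind
  `geodesic_distance(..., method = "ellipsoid")` and differs by < 0.3% at
  city scale.
* **Mean centers** are computed on a local tangent plane centered on the
  points' centroid and unprojected back to WGS84; at ≤ 50 km extents the
  planar/spherical discrepancy is below a metre (tested against geodesic
  midpoints).
* **Triangulability**: families whose capture points are pairwise within
  `coord_tol_m = 0.5` m count as a single netting spot and cannot be
  triangulated; they are dropped along with singletons. The tolerance is
  configurable and 0 switches to exact coordinate equality.
* **Cell assignment** uses half-open intervals `[west, east) × [south,
  north)`, a declared convention so a colony center on a grid line lands
  in exactly one cell.
* Sisters captured in a different cell than their colony still contribute
  their distances to their own colony; `aveMeanFD` is a property of the
  colonies *located* in a cell, not of the captures made there.

`colNe = 4.5Nmn/(1+2m)` defaults to `m = n = 1` (single mating, single
queen), i.e. `1.5 N`; both parameters are overridable for sensitivity
analysis, and `colNe -> 2.25·N·n` as `m` grows.

# Popgen QC

Descriptive genetics run on a colony-pruned dataset (one random sister per
multi-member family, seeded) so family structure does not masquerade as
Hardy–Weinberg departure. Observed heterozygosity is the heterozygote
fraction; expected heterozygosity uses Nei's small-sample correction
$\frac{2n}{2n-1}(1 - \sum p_i^2)$ — stated explicitly because published
tables do not always say which estimator they use, so comparisons should
be read qualitatively. The HWE screen is a seeded Monte-Carlo allele
permutation (default 10,000 shuffles, minimum 100): re-pair the observed
alleles, compare heterozygote counts. The two-sided p doubles the smaller
*mid-p* tail (floored at `1/(n_shuffles+1)`): for a discrete count
statistic the plain doubled tail is visibly non-uniform under the null,
while the mid-p version passes a KS uniformity check. Flags use Bonferroni
`alpha/L` over the `L` loci tested (0.05/12 ≈ 0.004 for a 12-locus panel).
Missing data are excluded locus-wise.

# The statistical battery

All decisions a reader might need to replicate numbers:

* **Spearman/FDR** (`spearman_fdr()`): rho on mid-ranks, two-sided
  p-values, BH step-up adjustment over the set of tested pairs.
* **VIF** (`vif_screen()`): $1/(1-R^2_j)$ from regressing each predictor
  on the others; flagging at 5 is advisory, with an explicit keep-list for
  variables retained on biological grounds; exact collinearity reports an
  `Inf` sentinel.
* **Best subsets** (`best_subset_regression()`): exhaustive enumeration up
  to `max_size`, beam search beyond $2^{20}$ subsets. Adjusted
  $R^2 = 1-(1-R^2)(n-1)/(n-p-1)$; AIC fixed as
  $n\ln(\mathrm{RSS}/n) + 2(p+2)$ (Gaussian likelihood, error variance
  counted) — only AIC differences matter, and the ordering is invariant to
  the convention. The winner is the lowest-AIC model among the top ten by
  adjusted R². Per-predictor variance explained is the adjusted-R² drop on
  single-predictor removal — a declared, reproducible substitute for the
  ambiguous ways such per-variable fractions are sometimes tabulated.
* **RDA** (`rda_fit()`): responses and predictors standardized (so colony
  numbers and log-distances are unit-comparable; stated in the output),
  fitted values by multivariate least squares, canonical eigenvalues from
  the fitted covariance, Ezekiel-adjusted R², and a seeded permutation
  test on the pseudo-F with 999 permutations by default,
  $p = (1 + \#\{F^* \ge F\})/(n_{perm}+1)$. Cross-checked against
  `vegan::rda` to machine precision in the tests; the one-response limit
  equals OLS R² to 1e-10.
* **Variation partitioning** (`varpart3()`): RDAs on the seven unions of
  three predictor sets, fractions by inclusion–exclusion on the adjusted
  scale. Negative fractions are reported as computed — truncating them
  would break the exact identity (fractions + residual = 1) that the
  tests assert at 1e-9. Note that unique fractions of orthogonal designs
  match each set's own adjusted R² only up to parameter-count differences
  in the adjustment (a few hundredths at n ≈ 50).
* **Normality** (`normality_check()`): Shapiro–Wilk, used to justify the
  `ln` transform of `aveMeanFD` before linear modelling.

Correlations of `colNe` with foraging distance are computed against both
the raw and ln-transformed `aveMeanFD` (the pipeline's Spearman matrix
includes `ln_aveMeanFD`; the raw column is one `cor.test` away), since
published headline correlations do not always say which scale they used.

# What the generator emulates — and what it does not

`simulate_landscape()` produces the 28 standard survey covariates as
transforms of latent Gaussian fields: a shared smooth spatial gradient
(weight 0.4 by default) plus cell-level noise correlated across variables
through a one-factor "urbanization" structure (built surfaces and
population load positively, green space negatively — PSD by
construction; a custom correlation matrix is validated for PSD and
rejected otherwise). Percent covariates go through a logistic link (hence
always in [0, 100]), counts through an exponential link, demographic
averages are affine with typical levels plausible for a large North
American city. `latent_scale = 0` collapses everything to constants, the
degenerate case the tests use.

`simulate_colonies()` draws per-cell colony counts from a Poisson whose
mean is a linear link on covariates. Links operate by default on the
covariate's rank percentile mapped to (−1, 1), so the expectation stays
within `intercept ± Σ|coefs|` by construction (a model that still goes
negative is rejected, per the contract). The defaults — density 3 ∓ 1 on
paved-surface cover, foraging-kernel scale 600 ± 250 m on road cover, a
mean of 5 netted workers per colony, 60-capture cell cap — are the
package's standing study conditions: colony densities and worker yields
of the same order as an intensive single-city survey, and kernel scales
bracketing typical *Bombus* worker foraging. The parameter-recovery tests
widen the kernel link to 850 ± 650 m, i.e. scales spanning 200–1500 m.

`simulate_sampling()` displaces each worker isotropically from its colony
by a half-normal distance (mean $\sigma\sqrt{2/\pi}$) — chosen as the
simplest one-parameter kernel with a closed-form mean, since field data
rarely constrain the kernel's shape. Captures are i.i.d. kernel draws
regardless of cell of origin, so sisters can be netted in different
cells; per-cell captures are truncated uniformly at random at the cap.
How far a worker drifts within a netting session is not modelled.

Not emulated: weather and phenology, queen dispersal, multi-year colony
dynamics, foraging barriers (roads are a covariate, not an obstacle),
spatial autocorrelation beyond the shared gradient, and the geometry of
real GIS layers (covariate extraction consumes overlap-fraction tables;
`rect_overlap_fractions()` covers synthetic rectangles). Passing recovery
tests therefore certify the *inference machinery*, not the realism of any
particular ecological effect size.

# Test problem sizes

The suite validates at desk scale, sized so the whole battery stays quick:
sibship recovery uses 20 families × 5 workers × 12 loci at the published
panel diversities over 10 seeds (adjusted Rand ≥ 0.95 required);
kernel-scale recovery runs the full pipeline (including reconstruction of
~1,100 workers) on a 36-cell landscape; the RDA sign-recovery check uses
50 replicate landscapes with colony metrics computed from the generator's
truth mapping, isolating the metric and ordination stages from sibship
noise, which the dedicated recovery test already covers. Null-uniformity
checks use 200 replicates each. A paper-scale run (270-cell grid, ~760
workers) completes in a few minutes on one CPU.

# Known limitations

* Support probabilities are restart-consensus frequencies, not posteriors;
  with 3 restarts they take values in {1/3, 2/3, 1}. More restarts refine
  them at linear cost.
* Allele frequencies are estimated once from all workers, including
  sisters; for strongly family-structured samples an iterative reweighting
  would be less biased.
* The half-sib case is out of model (deliberately, matching the biology of
  rare multiple mating); datasets from highly polyandrous taxa need a
  different likelihood.
* `colNe` inherits the detection model of its formula: it corrects the
  sampled count by the mating system only, not for spatially varying
  capture effort.
* The RDA permutes response rows freely; spatially autocorrelated
  residuals would need restricted permutations, which are not
  implemented.
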