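---
title: "Methods: phenotypic divergence in replicated genotype trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotypic divergence in replicated genotype trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenodiv)
```

## The experimental model

`phenodiv` targets one experimental layout, ubiquitous in the phenotypic
characterization of genetic resources: a balanced completely randomized
design in which `G` genotypes (mother plants, accessions) are measured for
`T` traits with `k` replicates each. The working model per trait is

$$y_{ij} = \mu + g_i + e_{ij}, \qquad g_i \sim (0, \sigma_g^2),\quad
e_{ij} \sim (0, \sigma_e^2),$$

so the one-way ANOVA mean squares have expectations
$E[\mathrm{QMg}] = \sigma_e^2 + k\,\sigma_g^2$ and
$E[\mathrm{QMr}] = \sigma_e^2$. Every estimator in the package is a
method-of-moments inversion of these two identities; everything therefore
assumes **balance** (equal `k` in every cell), and `trait_table()`
enforces it by rejecting — not imputing — missing cells. The F-test
additionally assumes normal, homoscedastic errors; the package leaves
pre-checks (Shapiro–Wilk, Bartlett) to the analyst and applies no
variance-stabilizing transformation to percentage traits, since the
estimators themselves only use second moments.

## Genetic parameters and one deliberate convention

From `QMg`, `QMr`, `k` and the grand mean `m`, `genetic_parameters()`
returns $\hat\sigma_f^2 = \mathrm{QMg}/k$,
$\hat\sigma_e^2 = \mathrm{QMr}/k$,
$\hat\sigma_g^2 = (\mathrm{QMg}-\mathrm{QMr})/k$,
$h^2 = \hat\sigma_g^2/\hat\sigma_f^2$, and the coefficients of variation.
One convention deserves emphasis: **CVe is computed from the residual
standard deviation on the observation scale**,
$\mathrm{CVe} = 100\sqrt{\mathrm{QMr}}/m$ — the familiar experimental
CV% — *not* from $\hat\sigma_e = \sqrt{\mathrm{QMr}/k}$. The two readings
differ by $\sqrt k$; the observation-scale one is what published
germplasm ANOVA tables print as CV(%), and it makes
$\mathrm{CVg}/\mathrm{CVe} = \sqrt{(\mathrm{QMg}-\mathrm{QMr})/(k\,\mathrm{QMr})}$
reproduce the CVg/CVe ratios those tables print alongside. The replay
test against a published 160-genotype summary (see `inst/extdata/`)
confirms this numerically to the printed precision.

Degenerate inputs are reported, never repaired: `QMr > QMg` yields a
negative $\hat\sigma_g^2$ with a `negative_sigma_g2` flag (truncation at
zero would bias simulation studies of the estimator), `QMr = 0` flags an
infinite ratio, and a zero mean flags undefined CVs.

## Scott–Knott grouping

`scott_knott()` implements the 1974 likelihood-ratio clustering of
ordered means. At a node holding `k` ordered means, the contiguous split
maximizing the between-group sum of squares $B_0$ is tested with
$\lambda = \frac{\pi}{2(\pi-2)}\, B_0/\hat\sigma_0^2$, where
$\hat\sigma_0^2 = \big(\sum_i(\bar y_i - \bar y)^2 + \nu s_{\bar y}^2\big)/(k+\nu)$,
$s^2_{\bar y} = \mathrm{QMr}/r$ and $\nu$ the residual degrees of
freedom; the split is accepted when $\lambda$ exceeds the $\chi^2$
quantile with the (non-integer) $k/(\pi-2)$ degrees of freedom, evaluated
with the continuous quantile function, as is standard in Scott–Knott
implementations. $\nu$ and $s^2_{\bar y}$ come from the trait's own
ANOVA and are reused unchanged at every recursion depth (the classical
procedure). Ties between splits with equal $B_0$ go to the leftmost
split, for determinism. Two consequences worth knowing:

* classes are always contiguous runs of the mean-ordered genotypes and
  can never interleave (tested as an invariant);
* as $\mathrm{QMr}\to 0$, $\hat\sigma_0^2$ is dominated by the scatter of
  the means themselves, and *every* distinct mean eventually becomes its
  own group — a property of the rule, not a bug; the suite pins this
  behavior against an exhaustive contiguous-partition oracle.

`alpha` defaults to 0.05, the conventional screening level; raising it
can only refine the partition (monotonicity is tested).

## Mahalanobis divergence and Singh contributions

The metric of `mahalanobis_matrix()` is the pooled within-genotype
residual covariance $\Psi$ of the **raw observations**
($\mathrm{E}/\mathrm{df}$ with $\mathrm{df} = G(k-1)$; its diagonal is
each trait's QMr), and distances are computed between genotype **mean
vectors**. A `scale = "means"` switch divides $\Psi$ by `k` for users who
prefer the covariance of means; this multiplies every D² by the constant
`k` and cannot change any grouping, which is why the package treats the
choice as cosmetic and defaults to the observation scale. Distances are
computed by Cholesky whitening (`backsolve`), never by explicitly
inverting $\Psi$ per pair; a reciprocal condition number below 1e−12
triggers a warning and exact singularity (e.g. a duplicated trait) an
error naming a candidate trait to drop. D² is invariant under affine
rescaling of any trait — the suite checks this at 1e−6 relative — so no
standardization is applied to the input.

`singh_contributions()` uses the additive decomposition
$c_j = d_j (\Psi^{-1} d)_j$, whose per-pair sum equals D² by construction
(asserted at 1e−9 relative). With correlated traits individual $c_j$ can
be negative; the **signed** values are aggregated, because any
sign-flipping or truncation would break the decomposition identity. The
summed contribution is computed in closed form,
$S_j = [G\,C\,\Psi^{-1}]_{jj}$ with $C$ the centred cross-product of
genotype means, and verified against a brute-force pair loop in the
tests.

## UPGMA, cophenetic correlation, Mojena cut

`upgma()` delegates to `stats::hclust(method = "average")`, whose merge
heights are exactly the average cross-pair dissimilarity (fusion level
**not halved**); the test suite proves equality with an independently
coded naive $O(G^3)$ agglomerator that recomputes every inter-cluster
average from the original matrix. Newick export rescales `ape`'s
half-height convention back to fusion-level units, so root depth reads
directly in D². The Mojena cutoff is $\bar\alpha + k\,s_\alpha$ over the
`G − 1` fusion levels (sample SD), with `k = 1.25` as the widely
recommended default; published studies usually report the resulting
cutoff rather than `k`, so `k` is exposed as a parameter. `cut_tree()`
severs merges at fusion level **≥** cutoff (strict `<` keeps a subtree
together); `stats::cutree` uses `≤`, and the boundary case is pinned in a
test, which is why the cut is implemented directly from the merge matrix.
Group ids are numbered by first appearance in leaf order.

## The synthetic cohort generator

`simulate_cohort()` draws genotypic effect vectors $g_i$ multivariate
normal with per-trait variances $\sigma_{g,t}^2$ and an optional
positive-semidefinite cross-trait correlation (applied through an
eigendecomposition square root, so exactly singular correlations — e.g.
duplicated traits — are allowed), plus independent normal residuals. This
is the simplest generator whose second moments match the ANOVA
expectations the estimators invert, which is precisely what makes it a
valid truth source for parameter-recovery tests. The seed is a mandatory
field of `cohort_spec` and the generator runs on a private RNG stream,
restoring the caller's `.Random.seed`.

What it deliberately does **not** emulate: spatial field trends,
genotype × environment interaction, non-normal or heteroscedastic errors,
unbalanced loss of replicates, measurement truncation (percent traits can
stray outside [0, 100]). Green recovery tests therefore certify the
estimators and the pipeline plumbing under the stated model — they do not
certify robustness to those real-data features.

## Validation scale and numerical choices

The suite validates at sizes chosen to keep the full run in tens of
seconds while leaving the Monte-Carlo checks well powered: oracle
equivalence uses G ≤ 8 (Scott–Knott, exhaustive enumeration) and G ≤ 10
(UPGMA); type-I error uses 1000 null traits at G = 30, r = 4 (binomial SE
≈ 0.007 around 0.05); h² recovery uses 100 cohorts of G = 160, r = 4 at
true h² ∈ {0.3, 0.7, 0.95} (SE of the mean ≤ 0.01, against a ±0.02
band); σ̂g² recovery uses 200 cohorts at σg² = 15, σe² = 2, where the 5%
acceptance band is about six Monte-Carlo standard errors — at low
heritability the same relative band would be only ~1 SE per 100 seeds,
which is why the σ̂g² check is anchored at this well-conditioned
reference point rather than at h² = 0.3. Comparisons against hand-derived
fixtures are exact to 1e−9 relative or better; the sum-of-squares
partition, the per-pair Singh identity and the percent total are asserted
at 1e−9.

## Known limitations

* Only balanced one-way (CRD) designs; no blocks, sites or years. The
  160-plant screening this workflow typically serves treats the whole
  collection as one experiment.
* Broad-sense heritability only, on a genotype-mean basis; no standard
  errors on h² and no narrow-sense decomposition.
* No multiple-testing correction across traits (none is customary in
  this literature); the per-trait α is the user's to interpret.
* Scott–Knott letters beyond 26 groups switch to two-letter labels.
* The Mojena rule with a fixed `k` can merge genuinely distinct clusters
  when between-cluster distances are very unequal (the cutoff is pulled
  up by the largest fusion level); inspecting the dendrogram with
  `plot(fit)` remains good practice.
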