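---
title: "Weighted single-step genomic BLUP and window-based GWAS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted single-step genomic BLUP and window-based GWAS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery it
implements: the single-step genomic evaluation of a low-heritability
fertility trait (the running example is calving interval in dairy cows),
the iterative SNP-reweighting scheme on top of it, the sliding-window
variance scan used for association mapping, and the synthetic-data
generator the test suite validates everything against.

## The evaluation models

Two single-trait linear animal models are supported.  For first-lactation
(primiparous) records,

$$y_{ijk} = \mu + \mathrm{HYS}_i + \mathrm{con}_j + b_1\,\mathrm{age}_k +
  b_2\,\mathrm{age}_k^2 + a_k + e_{ijk},$$

with herd-year-season of calving and country as fixed cross-classified
effects, linear and quadratic regressions on age at first calving, an
additive genetic effect $a$ and a residual $e$.  For later lactations the
repeatability form adds a parity fixed effect and a permanent-environment
random effect $pe$ that is uncorrelated with $a$, splitting the
non-genetic variance into permanent and temporary parts.  The variance
structure is $\mathrm{var}(a) = K\sigma_a^2$,
$\mathrm{var}(pe) = I\sigma_{pe}^2$, $\mathrm{var}(e) = I\sigma_e^2$,
where $K$ is either the pedigree numerator relationship matrix
$\mathbf{A}$ (pedigree BLUP) or the single-step matrix $\mathbf{H}$.

Identifiability of the fixed part uses reference-level (drop-first)
constraints on each factor, and the age covariate is centered before
squaring; both choices reparameterize the intercept and linear term
without changing the fit.  A design that is still rank deficient after
the constraints (e.g. a factor fully nested in another) raises an
estimability error naming the confounded columns rather than silently
dropping them — the solver works with ordinary inverses, not generalized
ones.

## Relationship matrices

`build_A_tabular()` is the quadratic-time tabular recursion and doubles
as the oracle for everything else.  `compute_inbreeding()` obtains
$F_i = 0.5\,a_{s(i)d(i)}$ by expanding the parents' rows of the
$\mathbf{T}$ factor of $\mathbf{A} = \mathbf{T}\mathbf{D}\mathbf{T}'$
over their ancestors, with per-animal working storage instead of a full
matrix.  `build_A_inverse()` assembles the sparse inverse from
Henderson's rules with Mendelian-sampling variances
$d_i = 0.5 - 0.25(F_s + F_d)$ (three-quarter / unit variants for missing
parents), so it equals the inverse of the tabular matrix to numerical
precision; a flag disables the inbreeding correction for sensitivity
checks.  Unknown parents are treated as unrelated founders; unknown-parent
groups and metafounders are out of scope.

The genomic matrix is VanRaden's
$\mathbf{G} = \mathbf{Z}\mathbf{D}\mathbf{Z}'\big/\sum_i 2p_i(1-p_i)$,
with gene content centered by twice the observed allele frequency and
$\mathbf{D}$ a diagonal matrix of per-SNP variance weights (identity in
the unweighted case).  Frequencies are observed in the genotyped sample,
which makes the columns of $\mathbf{Z}$ sum to zero and hence
$\mathbf{Z}\mathbf{D}\mathbf{Z}'$ singular by construction; invertibility
is restored by blending, $\mathbf{G}_b = \alpha\mathbf{G} +
(1-\alpha)\mathbf{A}_{22}$ with $\alpha = 0.95$ by default.  No further
tuning of $\mathbf{G}$ to $\mathbf{A}_{22}$ means/variances is applied,
and the single-step inverse uses the plain form

$$\mathbf{H}^{-1} = \mathbf{A}^{-1} +
  \begin{bmatrix} 0 & 0 \\ 0 & \mathbf{G}_b^{-1} - \mathbf{A}_{22}^{-1}
  \end{bmatrix},$$

without $\tau/\omega$ scaling.  Both degenerate cases — no genotyped
animals, or $\mathbf{G}_b = \mathbf{A}_{22}$ — collapse $\mathbf{H}^{-1}$
to $\mathbf{A}^{-1}$ exactly, and the tests assert this.  SNPs with minor
allele frequency strictly below the threshold (default 5%) are removed;
a SNP sitting exactly on the threshold is kept.

## Solving and variance components

`solve_mme()` builds Henderson's mixed-model equations with the ratio
$\sigma_e^2/\sigma_a^2$ on the genetic block (plus
$\sigma_e^2/\sigma_{pe}^2$ on the permanent-environment diagonal) and
solves them densely — the package targets desk-scale problems (a few
thousand animals), and the scaling boundary is the dense factorization,
documented rather than engineered around.  Prediction error variances are
exact, $\mathrm{PEV}_i = C^{aa}_{ii}\sigma_e^2$ from the inverse of the
coefficient matrix; reliability is $r^2 = 1 - \mathrm{PEV}/\sigma_a^2$
and the default accuracy is $\sqrt{r^2}$.  Because published accuracy
formulas of the form $1 - \mathrm{PEV}/\sigma_g^2$ are ambiguous between
reliability and squared accuracy, a literal mode returning $r^2$ itself
is provided; neither is asserted to be the only correct reading.  The
per-animal denominator uses $\sigma_a^2$, not $\sigma_a^2(1+F_i)$, so
genotyped animals whose genomic diagonal falls below 1 can show negative
reliabilities, which are clipped to zero with a warning.

`estimate_reml()` maximizes the restricted likelihood in the variance
components by average-information steps with step halving, falling back
to an EM step whenever an AI proposal leaves the parameter space or
decreases the objective; since EM is monotone, the reported likelihood
trajectory never decreases.  Convergence is declared when the largest
relative parameter change drops below 1e-8 (cap 500 iterations;
non-convergence is flagged on the result, not thrown).  Components are
pinned at a small positive bound (1e-8 times the phenotypic variance)
instead of being allowed to go negative.  Standard errors come from the
inverse AI matrix.  For single-record models the record-level covariance
is eigendecomposed once, making each subsequent iteration linear in the
number of records; the repeatability model uses the dense-V path.

## The weighted single-step iteration

`run_wssgblup()` starts from unit SNP weights (iteration 1 is plain
ssGBLUP) and repeats: build the weighted $\mathbf{G}^*$, blend, form
$\mathbf{H}^{-1}$, solve the MME, back-solve SNP effects from the
genotyped animals' GEBVs as

$$\hat{\mathbf{u}} = \lambda\mathbf{D}\mathbf{Z}'\mathbf{G}^{*-1}
  \hat{\mathbf{a}}_g, \qquad \lambda = 1\Big/\sum_i 2p_i(1-p_i),$$

then set each SNP's weight to $\hat u_i^2\,2p_i(1-p_i)$, normalized so
the weights sum to the SNP count (keeping the scale of $\mathbf{G}^*$
stable across rounds); zero-effect SNPs are floored at 1e-8 so
$\mathbf{D}$ stays invertible.  Five iterations are the default and the
window scan reads iteration 2, where this family of schemes typically
peaks in accuracy before the progressive over-weighting of large SNPs
erodes it.  The back-solve goes through the blended $\mathbf{G}^*$
because the unblended $\mathbf{Z}\mathbf{D}\mathbf{Z}'$ is singular with
observed frequencies (see above); for full-rank instances a direct solve
with iterative refinement and a declared ridge fallback (relative 1e-8)
is available and satisfies the reconstruction identity
$\mathbf{Z}\hat{\mathbf{u}} = \hat{\mathbf{a}}_g$ to 1e-8.

## Window scan, selection, gene overlap

For every window of $n$ consecutive SNPs on one chromosome (sizes 1, 5,
10, 20, 50 by default), the window's genetic value per genotyped animal
is $\sum_{j \in w} Z_{j}\hat u_j$ and its score is the empirical variance
of those values across animals — population denominator $n$, a choice the
source methods leave open — as a percentage of $\sigma_a^2$ from REML.
Windows slide one SNP at a time by default ("sliding" as opposed to
"distinct"; a flag gives non-overlapping windows), windows that would
cross a chromosome end are dropped, and chromosomes shorter than the
window produce none (logged).  Windows at or above the threshold (default
0.20% of additive variance) are kept and overlapping survivors on a
chromosome are merged into regions reporting the merged bp span and the
maximum window percentage, mirroring how such scans report disjoint
regions.  Gene overlap is a 1-based inclusive interval intersection
against a user-supplied annotation (4-column TSV, or BED converted from
0-based half-open by adding one to starts); a gene abutting the region
boundary counts as overlapping.  Enrichment analysis is out of scope.

Two properties of the scan are worth stating because they drive the
tests.  First, a window's variance is not the sum of its single-SNP
members when SNPs covary (linkage disequilibrium); it is exactly the sum
when the genotype columns are orthogonal.  Second, "smaller windows are
noisier" is formalized on the per-SNP-normalized window share (window
percentage divided by window size): for non-negative per-SNP
contributions the raw window percentage has mean and variance growing
with window size, so the raw variance cannot decrease — it is the
normalized share whose dispersion shrinks as windows widen, which is the
sense in which wide windows smooth single-SNP noise.

## The synthetic-data generator

`simulate_dataset()` produces a pedigree, genotypes, phenotypes and a
truth record.  Its defaults are the study conditions the package is
validated under, chosen once:

* **Population.** Founders (half each sex) followed by discrete
  generations; every dam of the previous generation leaves about
  `litter_rate` offspring (default 2), each sired by one of at most
  `n_sires` males (default 30).  The limited sire pool reproduces the
  large paternal half-sib families of artificial-insemination dairy
  breeding; those families carry most of the information about additive
  variance, and without them a heritability of 0.05 is not estimable at
  desk-scale sample sizes.
* **Genome.** Default 2000 SNPs on 5 chromosomes of 100 Mb; founder
  allele frequencies Uniform(0.05, 0.95); gene dropping with Haldane
  recombination at 1 cM/Mb and independent chromosomes; no mutation,
  genotyping error or missingness.
* **Trait.** Generating variances default to the primiparous calving
  interval scale, $\sigma_a^2 = 201.3$, $\sigma_{pe}^2 = 71.4$ (used by
  the repeatability model only), $\sigma_e^2 = 3728.7$, i.e. $h^2
  \approx 0.05$; overall mean 400 d; records restricted to the closed
  interval 270-700 d by re-drawing the residual (default, keeps the
  linear model exact) or truncation.  True breeding values are the sum of
  `qtl_count` explicit QTL (default 5) rescaled to explain
  `qtl_variance_fraction` (default 0.4) of $\sigma_a^2$, and a polygenic
  remainder dropped down the pedigree with inbreeding-corrected
  Mendelian-sampling variances.
* **Fixed effects.** Herds (default 8), years (3), seasons (4 calendar
  quarters, a code the generator defines since "season" has no universal
  definition), countries (4).  Herd-year-season cells are merged until
  every cell holds at least 3 records so the fixed effects stay
  estimable.  Country is assigned per cow and crossed with herd: fully
  nesting herds in countries would alias country with herd-year-season
  under reference-level constraints and the model would be rejected as
  inestimable by design.  Age at first calving is Uniform(22, 36) months
  with regressions $b_1 = 1.2$, $b_2 = 0.08$ on the centered scale;
  herd-year-season, country and parity effects are drawn with standard
  deviations 15, 10 and 8 d.
* **Genotyping.** A fraction (default 0.6) of non-founder animals is
  genotyped, phenotyped cows first — the animals a breeding program
  would genotype — topped up with other non-founders, so part of the
  pedigree remains ungenotyped as in real single-step applications.

What the generator deliberately does not emulate: selection and
assortative mating, genotype imputation and its errors, population-scale
linkage disequilibrium beyond what family structure and finite founder
numbers induce, genetic trend, heterogeneous residual variance, and
calendar confounding between year and generation.  Passing tests on this
generator therefore demonstrate the estimation machinery, not robustness
to those real-data complications.

## Validation design and problem sizes

Every operation with a closed-form or brute-force counterpart is tested
against it: the tabular A against textbook values, Henderson's inverse
against the tabular inverse (max-norm 1e-8 over random pedigrees), the
MME against a dense GLS oracle built from the record-level covariance,
REML against the balanced one-way ANOVA closed form, the window scan
against an explicit loop over animals, and interval overlap against an
all-pairs check.  Simulation-based checks run at sizes chosen so the
whole suite completes on one CPU in well under half an hour:
heritability recovery uses ~2800 records per seed over 10 seeds (the
mean of $\hat h^2$ is compared with the generating 0.05), and the QTL
detection and iteration-profile checks use about 2400 genotyped animals
and 4000 SNPs per seed, with the QTL fraction at the upper end of the
generator's declared 0.3-0.5 band — a pre-run power calculation
(non-centrality about $n R^2 \approx 8$ per QTL at smaller sizes) showed
weaker settings cannot separate QTL windows from family-structure noise
peaks at desk scale.  The iteration profile is scored with validation
accuracy — the correlation between GEBV and true breeding value, which
the simulation makes available — rather than PEV-based accuracy, whose
exact computation at every iteration would dominate the runtime without
changing the qualitative comparison.  The null calibration of the window
scan (no QTL) checks that no chromosome's maximum window share is
systematically elevated, and the noise property checks that the
dispersion of the normalized window share falls monotonically across
window sizes 1, 5, 10, 20, 50 on data simulated without linkage (one
huge chromosome length so adjacent SNPs are effectively unlinked).

## Known limitations

Dense factorizations bound the practical problem size at roughly ten
thousand mixed-model equations; A22-inverse is direct rather than
Colleau-style indirect; APY-type approximations for large genotyped sets
are not implemented.  Multi-trait models, Bayesian alternatives,
unknown-parent groups and genotype imputation are out of scope.  The
accuracy formula ambiguity (reliability vs squared accuracy) is exposed
as a mode rather than resolved.
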