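---
title: "Methods: pedigree- and marker-based evaluation of clonal trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree- and marker-based evaluation of clonal trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(clonalGS)
```

# The model

`clonalGS` evaluates clonally replicated trials — typically forest-tree
populations in which each genotype (clone) is vegetatively propagated into
several ramets — with the individual-tree mixed model

$$ y = X\beta + Z a + Z\,pe + Z_b b + e, \qquad e = \xi + \eta, $$

where $y$ holds one observation per plant, $\beta$ is the overall mean
(optionally plus covariates), $a \sim N(0, K\sigma^2_a)$ are additive genetic
effects of the genotypes, $pe \sim N(0, I\sigma^2_{pe})$ are clone-level
non-additive effects, $b \sim N(0, I\sigma^2_b)$ are incomplete-block
effects, and the residual splits into a spatially structured part
$\xi \sim N(0, \sigma^2_\xi\, \mathrm{AR1}(\rho_{col}) \otimes
\mathrm{AR1}(\rho_{row}))$ over the trial grid and an independent part
$\eta \sim N(0, I\sigma^2)$.

The relationship matrix $K$ is either the pedigree numerator relationship
matrix $A$ (ABLUP) or the marker-based VanRaden matrix $G$ (GBLUP). The two
analyses share one code path: only the injected matrix differs, which is the
point of the comparison — identical model, different source of relationship
information.

Key quantities derived from a fit:

* narrow-sense heritability
  $h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_{pe} + \sigma^2)$. The
  denominator deliberately excludes the block and spatial variances — they
  describe the trial environment, not the organism; a full-phenotypic
  denominator is available via `heritability(fit, full_denominator = TRUE)`
  for sensitivity analysis.
* genetic correlation between traits,
  $r_a = \sigma_{a_1 a_2} / \sqrt{\sigma^2_{a_1}\sigma^2_{a_2}}$, from a
  bivariate fit in which additive effects are correlated across traits while
  pe and block effects are trait-specific and independent, and residuals are
  correlated only through plants measured for both traits.
* breeding-value accuracy by 10-fold cross-validation (10 random replicates):
  the Pearson correlation between EBVs of masked genotypes predicted from the
  training records and their full-data EBVs.
* relative selection efficiency of GBLUP over ABLUP,
  $\mathrm{RE} = 100\, r_{GBLUP} / r_{ABLUP}$, and per year
  $\mathrm{RE}\,\mathrm{yr}^{-1} = \mathrm{RE} \cdot L_{TS}/L_{GS}$ with
  default cycle lengths of 17 years (progeny testing) and 9 years (genomic
  selection).
* status effective population size $N_s = 0.5/\bar f$, with $\bar f$ the mean
  pairwise coancestry including self-coancestries ($f_{ij} = a_{ij}/2$, so a
  non-inbred individual has self-coancestry 0.5). This convention makes
  $N_s = n$ exact for $n$ unrelated, non-inbred individuals, which is the
  property that gives the status number its meaning.

## Assumptions

Clone-level pe effects are separable from the residual only because each
genotype has replicated ramets; with a single ramet per genotype the model is
not identified and `include_pe = FALSE` should be used. The pe term is
modelled at genotype level (one effect per clone). A reading in which pe is a
ramet-level effect would be completely confounded with the independent
residual, so the genotype-level interpretation is the only estimable one in a
clonal trial.

The fixed part defaults to an intercept only; `build_design()` accepts
additional numeric covariates when the trial demands them.

# Marker handling

Genotypes are coded 0/1/2 with 2 the reference-allele homozygote; VCF input
is translated accordingly from the GT field (multi-allelic records are
skipped and counted). Markers with minor allele frequency below 0.01 or more
than 40% missing calls are discarded; remaining missing calls are replaced by
the marker's mean genotype. The genomic relationship matrix is

$$ G = \frac{ZZ'}{\mathrm{trace}(ZZ')/n}, \qquad Z = M - P, $$

with $P$ twice the reference-allele frequency per marker, computed from the
current (post-filter) sample. For $n$ the package defaults to the number of
individuals, which makes $\mathrm{mean}(\mathrm{diag}(G)) = 1$ so that $G$
can replace $A$ without rescaling the genetic variance; with the
number-of-markers divisor (`divisor = "markers"`) the trace equals the marker
count, which is not on the scale of a relationship matrix unless the two
dimensions coincide. Both are exposed; the mean-diagonal-1 convention is the
default because GBLUP substitutes $G$ for $A$ at unchanged variance scale.
$G$ built from finitely many markers can be singular (e.g. clone duplicates);
`stabilize()` adds a 1e-6 ridge to the diagonal only when the smallest
eigenvalue falls below it, and records that it did.

# REML estimation

Variance parameters are estimated by average-information (AI) REML on the
phenotypic covariance matrix directly:
$V(\theta) = \sum_k \theta_k C_k + \sigma^2_\xi S(\rho_{row}, \rho_{col})$,
where the $C_k$ are constant structure matrices and $S$ is the separable AR1
correlation at the observed grid positions. Newton steps use the AI matrix
under Levenberg–Marquardt damping with a step cap of 3 internal units, a
step-halving retry near the optimum (full Newton steps can oscillate across a
curved optimum), and a multiplicative EM-type fallback for variances that
keeps covariance correlations fixed (so their blocks remain positive
semi-definite). Accepted steps never decrease the restricted log-likelihood.

Internal parameter scales: variances on the log scale, spatial
autocorrelations on the atanh scale, and covariance components as
atanh-transformed correlations relative to $\sqrt{\sigma^2_1\sigma^2_2}$.
These choices keep every iterate feasible without hard projections — a
correlation approaching $\pm 1$ (for instance when two traits are nearly
duplicates) approaches the boundary smoothly instead of being clamped against
it, which is what makes degenerate inputs converge.

Numerical choices, all defaults of `clonal_blup()` / `fit_bivariate()`:

* starting values: genetic and residual variances at $\mathrm{var}(y)/3$,
  block and spatial variances at $\mathrm{var}(y)/10$, autocorrelations at
  0.1, covariances at 0 — scale-free and interior;
* variance floor at $10^{-8}\,\mathrm{var}(y)$; estimates pinned there are
  flagged `boundary` and reported without a standard error (published
  component tables contain exact zeros, so boundary estimates must be
  representable);
* convergence when the relative log-likelihood change is below 1e-8 **and**
  the maximum relative parameter change (internal scale) is below 1e-6, or
  when the Newton decrement — the improvement the quadratic model still
  predicts — is negligible; at most 200 iterations, after which the fit
  errors out carrying its iteration trace;
* approximate standard errors from the inverse AI matrix, transformed to the
  natural scale with the full Jacobian (the delta method); heritability and
  genetic-correlation SEs are delta-method functionals of that matrix.

`AIC = -2\log L + 2k` with $k$ the number of covariance parameters; the
spatial and non-spatial models are nested (at $\rho = 0$ the spatial variance
merges into the residual), and the pipeline reports both AICs. Following the
auditable-default principle, `run_evaluation()` applies the user's `spatial`
switch and only *reports* the AIC comparison unless `auto_spatial = TRUE`.

Breeding values for any individual in $K$ — phenotyped or not — are
$\hat a_t = \sigma^2_a K_{t,\cdot} Z' P y$ with prediction-error variances
from the same projection; this one identity serves fitting, prediction of
unphenotyped ancestors and cross-validation masking alike.

# Bivariate fits

The stacked two-trait covariance follows the block structure described above.
The spatial term is omitted from bivariate fits by default: the bivariate
variance structure treats residuals as independent within trait, and
estimating per-trait spatial fields plus shared autocorrelations adds four
parameters that the genetic-correlation target rarely supports; `spatial =
TRUE` enables per-trait spatial variances with shared $\rho$ when wanted.
Trait pairs with no shared plants have the residual covariance fixed at 0
with a warning. For nesting checks both covariances can be constrained to
zero, which recovers the sum of the two single-trait log-likelihoods.

# Cross-validation

Folds partition the *genotype* set, never the plant set: all ramets of a
clone enter the same fold, otherwise the clonal replicates of a validation
genotype would leak into training and the accuracy would be meaningless.
Variance components stay fixed at the full-data estimates inside the fold
loop by default (`refit = TRUE` re-estimates them per fold); masking then
reduces each fold to one GLS solve on the training submatrix of the full-data
covariance. A fold in which the training records carry no kinship information
about a validation genotype yields constant-zero predictions; its correlation
is undefined and the fold is scored 0 (no signal) and counted, which is also
what makes the identity-kinship control come out at zero accuracy. Accuracy
is the mean of the per-fold correlations over all folds and replicates, with
fold assignment driven by a single user seed.

# The synthetic-data generator

Because the study's raw data live in an external repository, the package
ships a generator that emulates the trial so that every stage is testable
offline and with known truth:

* a crossing pedigree: unrelated parents, families as distinct parent pairs
  (a parent may appear in several), a fixed number of clone genotypes per
  family;
* biallelic SNPs gene-dropped through the pedigree (founder minor-allele
  frequency uniform, Mendelian transmission per marker), so the realized $G$
  is consistent with $A$ by construction — their off-diagonal regression
  slope sits in [0.8, 1.2] at 1,000+ markers;
* phenotypes generated exactly from the model above: breeding values via a
  Cholesky root of $A$ (so parents get true values too), iid pe and block
  effects, a spatial field drawn on the full grid from the separable AR1
  root and read at plant positions, iid residual noise; a second trait can
  share additive structure with a prescribed correlation through a 2x2
  Cholesky mix of the standardized additive draws.

The bundled default (`radiata_scenario()`) mirrors the study conditions: 55
parents, 63 full-sib families of 10 genotypes, 3 ramets each (1,890 plants)
on a 45 x 42 grid in contiguous column-major blocks of 30 cells, 2,000
markers with founder MAF uniform on (0.05, 0.5), and the initial-height
variance components (additive 15.41, non-additive 11.50, independent residual
14.04, implying $h^2 = 0.38$). The block variance (2), spatial variance (3)
and autocorrelations (0.5) are not published quantities; they are package
defaults chosen as a moderate spatial signal typical of nursery trials, and
the serialized scenario flags them as such. The published source reports both
"10 genotypes per family" and "an average of 30 clones per family"; the
generator parameterizes genotypes-per-family (default 10, giving 630
genotypes against the study's 622) and leaves the discrepancy to the user.
Trait generation goes through pedigree breeding values rather than marker
effects, so ABLUP is the correctly specified model and the GBLUP comparison
reflects what markers capture of the pedigree signal; gene-dropped markers
remain available for marker-effect scenarios.

What the generator does **not** emulate: genotyping error and allele-calling
artefacts, selection and non-random mating in the pedigree, linkage
(markers segregate independently), non-normal trait distributions,
missing-data patterns correlated with the field layout, and
genotype-by-environment interaction. Passing recovery tests on this
generator therefore demonstrates the estimation machinery, not robustness to
those real-data complications.

# Problem sizes used by the test suite

The recovery suites run at the study scale where that is what is being
claimed — 20 replicates of the 630-genotype, 1,890-plant spatial scenario for
component recovery, and 20 replicates of a 600-genotype two-trait scenario
for the genetic-correlation recovery — and at reduced scale (150–375
genotypes) for controls whose conclusions do not depend on size, such as the
identity-kinship zero-accuracy check, the heritability-monotonicity trend and
the spatial-versus-non-spatial AIC comparison. The Monte-Carlo gene-dropping
oracle for the A matrix uses 100,000 replicates on pedigrees of up to 20
individuals, giving agreement within three Monte-Carlo standard errors.

# Known limitations

* **Nugget/spatial confounding.** In the AR1 ⊗ AR1-plus-nugget residual
  model, a short-range spatial process ($\rho \to 0$) is statistically close
  to white noise, and for some data realizations the REML optimum places the
  entire independent residual into the spatial component with a small
  autocorrelation (residual at the boundary floor). This is a property of
  the likelihood surface, not of the optimizer — multi-start fits reach the
  same optimum, and its likelihood genuinely exceeds interior solutions. In
  recovery simulations at the bundled study scale this occurs in roughly 10%
  of replicates and inflates the spatial variance (and hence the
  genetic-plus-independent-residual heritability) on average. A fit whose
  independent residual sits at the floor is flagged `boundary` and deserves
  scrutiny — a zero measurement-error variance is rarely credible; comparing
  against the non-spatial fit's components is the practical diagnostic.
* Dense-matrix algebra throughout: fits are comfortable to a few thousand
  plants per trait, which covers the clonal-trial setting it targets, but
  this is not a sparse animal-model solver for 10^5-plus pedigrees.
* Single- and two-trait models only; no factor-analytic or >2-trait
  structures.
* The spatial residual assumes one plant per grid cell and a separable AR1
  correlation; irregular layouts are handled only through grid holes.
* Heterogeneous residual variances (e.g. by treatment group) are not
  modelled.
* The bivariate residual covariance is estimable only from plants observed
  for both traits; traits measured on disjoint plant sets get a zero
  covariance by construction.
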