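# clonalGS

Genetic evaluation of clonally replicated tree trials with pedigree-based
(ABLUP) and marker-based (GBLUP) mixed models.

Tree breeding programs increasingly screen traits such as early growth,
foliar carbon isotope composition (δ13C, a surrogate for intrinsic water-use
efficiency) and chlorophyll fluorescence on clonally propagated seedlings,
and need to know (i) how heritable those traits are, (ii) how they correlate
genetically, and (iii) whether marker-based selection can replace slow
progeny testing. `clonalGS` implements that evaluation chain for the
quantitative geneticist working in R: trials with genotypes (clones)
replicated as ramets on a spatially structured grid, analysed with the
individual-tree mixed model

    y = Xβ + Z a + Z pe + Z_b b + ξ + η

with additive effects `a ~ N(0, K σ²_a)` (K the pedigree numerator matrix A
or the VanRaden genomic matrix G), clone-level non-additive effects `pe`,
incomplete-block effects `b`, a separable AR1(col) ⊗ AR1(row) spatial
residual ξ and independent noise η, fitted by average-information REML.
From the fits it computes narrow-sense heritability
`h² = σ²_a / (σ²_a + σ²_pe + σ²)`, bivariate genetic correlations
`r_a = σ_a1a2 / √(σ²_a1 σ²_a2)`, 10×10-fold cross-validated breeding-value
accuracies, the relative selection efficiency of genomic over pedigree
selection `RE = 100 · r_GBLUP / r_ABLUP` (and per year, scaling by the 17- vs
9-year breeding cycles), and the status effective population size
`Ns = 0.5 / f̄`.

A synthetic-data generator (crossing pedigrees, gene-dropped SNPs,
spatially structured clonal phenotypes with known true components) makes the
whole pipeline testable end to end without any external data.

## Worked example

Simulate a trial at the bundled default scale — 55 parents, 63 full-sib
families × 10 clones × 3 ramets (1,890 plants) on a 45 × 42 grid, initial
height with true components (additive 15.41, non-additive 11.50, residual
14.04 ⇒ h² = 0.38) — then run the pedigree and marker evaluations
(a few minutes on one core):

```r
library(clonalGS)

scenario <- radiata_scenario()
ped    <- simulate_pedigree(scenario, seed = 42)
trial  <- simulate_trial(ped, scenario, seed = 43)

A      <- numerator_relationship(ped)
design <- build_design(trial$pheno, "H_I", A)
fit    <- clonal_blup(design, spatial = TRUE)    # ABLUP, AR1xAR1 residual
summary(fit)
#> Trait 'H_I': REML logLik -5899.3029, AIC 11812.6057
#>   component   estimate        se boundary
#> 1  additive 19.7033648 5.3181455    FALSE
#> 2        pe  8.7167014 3.1087994    FALSE
#> 3     block  1.9888676 0.4998516    FALSE
#> 4  residual 15.9410796 0.9167275    FALSE
#> 5   spatial  1.3317716 0.6991506    FALSE
#> 6   rho_row  0.3639873 0.2609919    FALSE
#> 7   rho_col  0.8034873 0.1393875    FALSE
#> Narrow-sense heritability: 0.4442 (SE 0.0956)
```

The estimated components sit near the generating values for one replicate
(additive 19.7 vs 15.41 true, non-additive 8.7 vs 11.50, residual 15.9 vs
14.04), and ĥ² = 0.44 (SE 0.10) against a true 0.38 — single-replicate
sampling noise; the averaged recovery checks live in the test suite. The same
model with the genomic matrix, then cross-validated accuracy:

```r
markers <- gene_drop(ped, n_markers = 2000, seed = 44)
clones  <- unique(trial$pheno$genotype_id)
G <- stabilize(genomic_relationship(impute_mean(
  marker_matrix(unclass(markers)[clones, ]))))
fitG <- clonal_blup(build_design(trial$pheno, "H_I", G), spatial = TRUE)

plan <- make_folds(clones, k = 10, reps = 10, seed = 7)
accA <- cv_accuracy(fit,  plan)
accG <- cv_accuracy(fitG, plan)
re   <- relative_efficiency(accG$mean, accA$mean)
#> ABLUP accuracy 0.78, GBLUP accuracy 0.87
#> RE 112%, RE per year 211%

f <- average_coancestry(A)
status_number(f)
#> mean coancestry 0.0119, status number Ns = 42.2
```

On gene-dropped synthetic markers G measures *realized* relatedness, so GBLUP
can out-predict the pedigree expectation (RE > 100%); on real exome-capture
data the ranking typically reverses while the per-year efficiency still
favours genomic selection because its breeding cycle is roughly half as long.

The whole chain — descriptive statistics, spatial vs non-spatial AIC
comparison, ABLUP + GBLUP components and h², cross-validation, RE — runs in
one call from files on disk:

```r
cfg <- run_config(pheno = "phenotypes.csv", pedigree = "pedigree.csv",
                  markers = "genotypes.vcf", marker_format = "vcf",
                  traits = c("H_I"), spatial = TRUE,
                  cv_k = 10, cv_reps = 10, seed = 1, out_dir = "out/")
bundle <- run_evaluation(cfg)   # writes out/report.json and CSV tables
```

Trait utilities are included: `delta13c()` (isotope-ratio arithmetic, ‰ vs
the VPDB standard), `fvfm()` (dark-adapted PSII quantum yield),
`summarize_trait()` (N, mean, SD, range, signed CV%), `growth_increase()`,
`oneway_anova()` and group-mean `trait_correlation()`.

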