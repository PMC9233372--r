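# pdvnet

Rare-variant pathway burden analysis for cross-trait genetics: from
per-variant damage scores to per-individual biological-process dysfunction
scores and their association with a quantitative phenotype.

## The problem

Children with autism spectrum disorder (ASD) frequently have co-occurring
sleep disturbances. One mechanistic hypothesis is pleiotropy: damaging
rare variants accumulating in genes whose proteins connect ASD biology
with sleep-duration biology. `pdvnet` implements an end-to-end pipeline
for that style of analysis, usable with any two candidate gene sets:

1. **PDV scoring.** Each high-consequence variant gets a
   predicted-damaging score `PDV = FD × Z`, where
   `FD = ((D − B) + 1)/(N + 1)` aggregates the calls of nine in-silico
   predictors (`D` damaging, `B` benign, `N = D + B`; range −0.8 to 1.0,
   negatives truncated to 0) and `Z` is a zygosity weight (het = 1,
   hom = 2) with pseudoautosomal-aware handling of male X variants and
   CNVs scored at full weight against coding/5′-UTR gene intervals.
2. **Pleiotropy network.** Candidate sets are restricted to PDV-bearing
   genes and joined by protein–protein interaction edges (combined score
   ≥ 400) that cross the two sets.
3. **GO overrepresentation.** Network genes are tested per biological
   process with one-sided hypergeometric tests under a topology-aware
   elimination procedure (elim), with Benjamini–Hochberg FDR control and
   Anno/Sig/Exp/FE reporting.
4. **DBP scores.** Per individual and significant process,
   `DBP = Σ(PDV_gene × EBP_gene) / nGenes`, where the EBP weight combines
   GO evidence-code frequencies with a child-term fraction of the
   process's sub-hierarchy.
5. **Association.** The process with the most evidence of dysfunction is
   regressed against sleep duration (OLS with age/sex/race/IQ
   adjustment), extreme-duration categories (≤ 420 min, ≥ 660 min),
   interaction terms and age-stratified models. Feature-matched random
   gene sets (GC content, transcript size, spliceoform count) provide a
   negative control.

Real cohorts of this kind are access-restricted, so the package includes a
synthetic-cohort generator (`simulate_cohort()`) that emulates all seven
input formats with planted ground truth, making every stage testable.

## Worked example

```r
library(pdvnet)
sim <- simulate_cohort(sim_scenario(), seed = 42)  # 500 individuals
run <- run_pipeline(sim)
print(run)
```

```
pdvnet pipeline run
  QC-passing variant rows: 15738 
  scored variants: 14146 ; gene burdens: 13920 
  PDV-bearing candidates: A = 120 , B = 100 ; overlap = 29 
  network: 132 genes, 150 cross-set edges
  significant processes: 1 
  top process: GO:9000013 
```

The cohort has 29 genes planted in both candidate sets (all recovered),
and the 150 planted cross-set interaction edges are recovered exactly.
One GO process is FDR-significant — the planted target term:

```r
head(as.data.frame(run$enrichment), 3)
```

```
     term_id                  name anno sig  exp   fe        p      fdr
1 GO:9000013 simulated process 013   30  30 3.27 9.16 2.08e-33 7.28e-32
2 GO:9000027 simulated process 027   20   5 2.18 2.29 5.57e-02 9.74e-01
3 GO:9000022 simulated process 022   20   4 2.18 1.83 1.64e-01 1.00e+00
```

`anno` is the number of annotated universe genes, `sig` the network genes
among them, `exp` the chance expectation and `fe = sig/exp` the fold
enrichment. DBP scores over the significant process then feed the
association models:

```r
print(run$association$linear)
```

```
regression of sleep_minutes on 6 terms, n = 483 
           term       beta       se        t          p
1   (Intercept)  672.74609  22.3973  30.0370 4.767e-112
2           dbp 1578.10397 395.7740   3.9874  7.728e-05
3     age_years   -9.24525   0.7684 -12.0322  2.638e-29
4       sexmale  -18.24664   9.2340  -1.9760  4.873e-02
5 racenon_white  -12.49625   8.0886  -1.5449  1.230e-01
6            iq   -0.09535   0.1957  -0.4873  6.262e-01
```

The DBP coefficient (1578 ± 396 minutes per DBP unit) recovers the
planted effect of 1200 within one standard error; age and sex effects
match their planted values. `run$diagnostics` reports per-process
dysfunction proportions, Shapiro–Wilk normality tests and Spearman
correlations, and `run$association$stratified` the age-stratified fits.

A thin command-line wrapper is provided for file-based runs:

```sh
Rscript inst/scripts/run_pipeline.R simulate --out cohort_dir --seed 5
Rscript inst/scripts/run_pipeline.R run-all --in cohort_dir --out results_dir
```

See `vignettes/pdvnet-methods.Rmd` for the full model description,
parameter defaults and design decisions.

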