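---
title: "Methods: variant damage scores, pleiotropy networks and process dysfunction"
author: "pdvnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant damage scores, pleiotropy networks and process dysfunction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`pdvnet` implements a systems-level rare-variant analysis that connects two
traits — in the motivating application, autism spectrum disorder (ASD) and
childhood sleep duration (SD) — through shared protein biology. The pipeline
has five stages:

1. **PDV scoring.** Each high-consequence variant receives a predicted-damaging
   score from the consensus of nine in-silico predictors, weighted by zygosity.
2. **Pleiotropy network.** The two candidate gene sets are restricted to
   PDV-bearing genes and joined by protein–protein interaction edges that
   cross the two sets.
3. **GO overrepresentation.** Network genes are tested for enrichment of
   Gene Ontology biological processes with a topology-aware elimination
   procedure and FDR control.
4. **DBP scores.** Each individual receives, per significant process, an
   evidence-weighted dysfunction score aggregating their gene-level PDV
   burdens.
5. **Phenotype association.** The process with the most evidence of
   dysfunction is tested against sleep duration with covariate adjustment,
   extreme-duration category models, interaction terms and age-stratified
   models. Feature-matched random gene sets provide a negative control.

Because the motivating cohort is access-restricted, the package ships a
synthetic-cohort generator with planted ground truth; every stage is tested
against that ground truth or against independent analytic oracles.

# Variant-level model

## The FD consensus score

For a variant with `D` predictors calling it damaging, `B` calling it benign
and `N = D + B` providing a categorical prediction,

$$FD = \frac{(D - B) + 1}{N + 1}.$$

The `+1` constant encodes the prior that variants enter the pipeline only
after pre-selection for high-consequence annotations (splice-site
alterations, stop gains/losses, start losses, frameshifts), so a variant
with no categorical predictions scores 1. With nine predictors the score
ranges from −0.8 (all benign) to 1.0 (all damaging); negative scores are
truncated to zero before weighting, since only damage evidence is
aggregated.

Two readings of `N` are possible; `pdvnet` enforces `D + B = N`, i.e.
"providing a prediction" means a categorical damaging/benign call and
abstentions are excluded. This reading is the one consistent with the
attainable score range (−0.8 requires `D = 0, B = N = 9`). The
token-to-call mapping for predictor columns is configurable
(`default_token_map()`) because annotation-tool output dialects differ.

## Zygosity and the pseudoautosomal regions

The damage weight is `PDV = FD × Z` with `Z = 1` for heterozygous and
`Z = 2` for homozygous genotypes. On the X chromosome, male heterozygous
calls inside PAR1/PAR2 behave autosomally (`Z = 1`), while male X variants
outside the PARs are hemizygous and receive `Z = 2` regardless of the
called genotype — a heterozygous call there is a genotyping artifact. Male
Y-chromosome variants are treated as hemizygous (`Z = 2`) by the same
logic; the protocol we follow is silent on Y, so this default is explicit
and documented here.

## CNVs

A copy-number variant overlapping (≥ 1 bp) the coding, splice-site or
proximal-promoter (5′-UTR) intervals of a gene is scored at the maximal
damage weight (`FD = 1`) and assumed heterozygous, so `PDV = 1`, with at
most one record per CNV per gene. Intronic-only overlap does not score:
gene models supplied to `cnv_pdv()` must contain only scoreable intervals.

## QC

SNV/indel rows require read depth ≥ 8 and genotype quality ≥ 20
(inclusive); CNV interval calls carry no read-level QC and bypass the
filter. An optional `gt_pass` column accommodates upstream genotype-filter
flags whose criteria are tool-specific.

# The pleiotropy network

Gene sets are first restricted to genes with a positive PDV burden in at
least one individual. An interaction edge (combined score ≥ 400, the
STRING "medium confidence" convention; the source protocol says "medium
confidence or better" without a number, and 400 is STRING's documented
value for it) is retained when it connects the A side to the B side; genes
implicated in both sets satisfy either side. Within-set edges are excluded
from the pleiotropy definition by default because the scientific object is
*cross-trait* interaction evidence, but `cross_only = FALSE` provides the
full candidate subgraph for visualization. Raising the score threshold can
only shrink the network (tested as an invariant).

# GO overrepresentation

Annotations are propagated by the true-path rule (a gene annotated to a
term is annotated to all ancestors; `is_a` and `part_of` are treated
identically). Each term with at least `min_node_size = 3` annotated
universe genes (a conventional node-size pruning, configurable) is tested
with the one-sided upper-tail hypergeometric probability; `Exp` and fold
enrichment `FE = Sig/Exp` are reported alongside.

The reference protocol uses topGO's *weight01* algorithm. weight01's exact
down-weighting is defined only by that package's internals, so `pdvnet`
implements the published *elim* member of the same family: terms are
visited deepest-first, and when a term is significant at
`alpha_elim = 0.01` its (currently annotated) genes are removed from all
ancestors before those are tested. With `alpha_elim = 0` the procedure
reduces exactly to the classic Fisher test — a property used as a test
oracle. Reported `Anno/Sig/Exp/FE` are always unpruned counts; only the
p-value reflects elimination, mirroring topGO's reporting. FDR control is
Benjamini–Hochberg at α = 0.05; result rows are ordered by p-value with
ties broken by term id for determinism.

# DBP scores

For each significant process X and individual,

$$DBP_X = \frac{\sum_{\text{genes } A}\; PDV^{A} \times EBP_X^{A}}{nGenes_{BP_x}},$$

where `PDV^A` is the sum of PDV scores over the individual's distinct
variants in gene A (distinctness keyed on individual/chrom/pos/ref/alt),
`nGenes` counts all genes assigned to the process in the analysis universe
after true-path propagation, and the evidence weight is

$$EBP_X^{A} = \sum_{\text{codes } c\; \text{supporting } A}
 f_X(c) \;+\; \frac{|\text{descendant terms of } X \text{ hit by } A|}
 {|\text{descendant terms of } X|},$$

with `f_X(c)` the frequency of evidence code `c` among all annotation
records of the process. Two deliberate readings are documented here
because the defining sentence is grammatically ambiguous:

* The division by the descendant-term count applies to the **child count
  only** (default). This keeps the evidence component on the frequency
  scale and the child component in [0, 1]. The alternative, dividing the
  whole sum, is available as `ebp_parse = "whole-sum"`.
* "Child terms in the same branch" is operationalized as the descendant
  terms of the process to which the gene is annotated. When the process
  has no descendants the child component is zero.
* Distinct evidence codes per gene–term pair count once each; "codes
  supporting assignment" is read as a set.
* `nGenes` counts all annotated universe genes, not only PDV-bearing study
  genes; this is configurable via the `universe` argument.

DBP is linear in the burdens, additive over genes, non-negative, zero
exactly when the individual has no PDV in an assigned gene, and monotone
under added burden — all verified as property tests.

Score diagnostics follow the protocol: per-process Shapiro–Wilk tests
(skipped for constant columns; subsampled to 5000 with the run seed above
that size, the test's validity range), pairwise Spearman correlations, the
per-process proportion of individuals with any dysfunction (DBP > 0), and
selection of the process with the highest such proportion as the
association phenotype.

# Matched-random validation

Random sets of the same size as each candidate set are drawn (seeded
rejection sampling with a retry cap) from the feature universe excluding
both candidate sets, accepting a draw when set-level means match the
candidate set within tolerance. The matching tolerances are not stated in
the reference protocol; defaults are |Δ mean GC| ≤ 0.01, |Δ mean
transcript size| ≤ 5% relative, and |Δ mean spliceoforms| ≤ 0.5 — tight
enough to be meaningful, loose enough for rejection sampling to terminate
on realistic universes — and all configurable. Matching is on set-level
means, as described, not per-gene nearest neighbors. Welch t-tests compare
the realized features. The negative control re-runs restriction → network
→ enrichment on the random sets; under the null the expected count of
FDR-significant processes is ≈ 0, which the acceptance suite verifies over
seeded replicates.

# Phenotype association

Sleep duration (minutes/night) is regressed on the selected DBP score with
ordinary least squares, adjusting for age at ascertainment, genetically
determined sex, reported race and full-scale IQ; optional
symptom-severity covariates can be appended. Race is coded
majority-group-reference (two-level by default, matching the cohort
description); complete-case analysis throughout, no multiplicity
correction across phenotype models, significance at p < 0.05 — all
mirroring the protocol.

Extreme-duration categories use inclusive cutoffs: ≤ 420 min (extremely
short), ≥ 660 min (extremely long), otherwise non-extreme; a percentile
mode recomputes the 5th/95th percentiles from the supplied distribution.
The category models default to a linear probability model (least squares
on the 0/1 indicator) because the reported effect magnitudes in the
reference analysis are on the probability scale; a logistic link is
available behind a flag. Interaction models add a DBP × age or DBP × sex
product term with main effects. Age-stratified models use the bins 4–5,
6–12 and 13–18 years, refit the covariate-adjusted model within each
stratum, skip strata with insufficient complete cases, and drop covariates
that are constant within a stratum.

Rank-deficient designs are rejected with the offending columns listed
rather than silently dropped. OLS estimates are validated against a
normal-equations oracle to 10⁻¹⁰ relative tolerance.

# The synthetic cohort

The generator (`simulate_cohort()`) emulates every pipeline input with
controlled ground truth:

* **Cohort shape.** Default 500 individuals, 86% male, 79% majority race
  group — the composition of the reference cohort at desk scale; a
  `paper_scale` switch gives 2380 individuals. 500/2000 genes keeps
  generation around a few seconds while leaving every stage non-trivial.
* **Genotypes.** Variant counts are Poisson per gene (higher rate in
  candidate genes); each variant carries a latent damaging state reported
  by each of nine predictors with probability κ = 0.9, flipped or missing
  otherwise; depth/GQ place ~5% of rows below the QC thresholds; ~4% of
  universe genes are X-linked, with PAR1 covering part of the X block so
  both PAR and non-PAR male X variants occur.
* **Candidate sets.** Sizes 120/100 with a planted 29-gene overlap (the
  overlap count of the reference analysis). Because a small cohort can by
  chance leave a candidate gene without any PDV, the generator records the
  *realized* PDV-bearing sets in its ledger — the scorer itself is run
  during generation — and plants interaction edges among realized PDV
  genes, so recovery checks are exact rather than probabilistic.
* **Interactome.** Cross-set edges planted at score 700, noise edges at
  200 (below the 400 threshold), and optionally high-confidence background
  edges among non-candidate genes for negative-control studies.
* **Ontology.** A DAG of depth 3, fan-out 3 with one target leaf term
  annotated to network genes and the remaining terms annotated at random;
  evidence codes drawn from a configurable mixture over
  {EXP, IDA, IMP, ISS, IEA}.
* **Phenotypes.** `sleep = 640 − 8·age − 5·male + β·DBP + ε`,
  ε ~ N(0, 70²) minutes, with the true DBP computed by the real scoring
  path so phenotype generation cannot drift from the scorer; ~4% of
  individuals lack sleep data, mirroring the reduced association sample.
  The planted effect defaults to β = 1200 minutes per DBP unit: DBP units
  are small (typical scores ~0.01 because of the per-process gene-count
  normalization), so this corresponds to roughly 0.15 standard deviations
  of sleep per standard deviation of DBP — a modest, cohort-detectable
  effect. The independent check on this construction is parameter
  recovery (confidence-interval coverage), not score re-derivation.

What the generator does **not** emulate: realistic allele-frequency
spectra, linkage disequilibrium, family/trio structure, correlated
predictor errors, or biologically structured interactomes and ontologies.
Passing tests therefore demonstrate that the pipeline recovers what was
planted under clean conditions; they do not certify performance on real
cohort data.

# Numerical choices and degenerate inputs

* Fisher tails via the hypergeometric distribution function; verified
  against exhaustive binomial-coefficient sums on every table with
  universe ≤ 30.
* BH adjustment delegates to the standard step-up implementation; output
  order ties broken by term id.
* `exp`/`fe` identities hold to 10⁻¹² and are asserted in tests.
* Terms with no annotated study gene are reported as non-tested rather
  than p = 1, so they do not dilute FDR.
* Constant DBP columns skip the normality test with a note; constant
  covariates within an age stratum are dropped from that stratum's model.
* Duplicate variant rows are deduplicated with a warning; duplicate
  annotation triples collapse silently.
* Empty restricted gene sets, terms without annotations, zero-gene
  processes, constant category indicators and constant interaction
  modifiers are all fatal with specific messages.

# Problem sizes used by the test and acceptance suites

Chosen as the package's own balance between statistical resolution and a
comfortable desk-scale run: unit tests use a 120-individual/600-gene
cohort; ledger-recovery tests use the 500-individual default scenario;
coverage and stratified-localization checks use one 2000-individual cohort
with 500 and 200 phenotype replicates respectively; the negative control
uses 100 replicates of a 100-individual/500-gene scenario. The full suite
runs in a few minutes on one CPU.

# Known limitations

* elim is a documented stand-in for weight01; exact topGO p-values are not
  reproduced, and the reported Sig/Exp/FE columns are unpruned counts.
* The gene-level identifier space is assumed decomposed and stable;
  multi-allelic decomposition is upstream of this package.
* Inheritance state is consumed for reporting only.
* The association models treat individuals as independent; family
  structure is out of scope.
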