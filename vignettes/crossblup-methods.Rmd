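---
title: "Simulating and evaluating crossbred genomic prediction with crossBLUP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and evaluating crossbred genomic prediction with crossBLUP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Many livestock systems select purebred parents to improve crossbred (F1)
commercial performance. crossBLUP provides both halves of the computational
experiment needed to study this: a forward-in-time simulator of a
two-purebred-line + F1 beef-cattle system, and the single-step genomic
evaluation machinery (ssGBLUP and its SNP-weighted variant) used to predict
crossbred breeding values from alternative training-population designs.

# The simulated system

`simulatePopulation()` builds, under one seed:

1. **A deep random-mating history** (1,000 generations of 2,000 animals,
   then 20 generations of 1,500) that accumulates linkage disequilibrium
   (LD) by drift. All loci start at allele frequency exactly 0.50. At a
   marker spacing of 0.05 cM the equilibrium adjacent-pair r2 under drift
   and recombination is roughly 1/(1 + 4 Ne c), which for Ne = 2,000 and
   c = 0.0005 is 0.2 — the historical design *is* the LD target.
2. **A founder bottleneck**: 100 males + 100 females sampled from the last
   historical generation. QTL effects are drawn here — gamma(shape 0.40)
   with random sign — and rescaled so the founder-cohort QTL variance equals
   the architecture's QTL heritability times the phenotypic variance.
3. **An expansion population** grown with five offspring per female for
   eight generations (litter sexes alternate, so the sex ratio is 1:1 and
   replacement never starves).
4. **Two selected lines** (Line1: 10 generations; Line2: 30), each bred
   with one offspring per dam, sires drawn with replacement, and truncation
   selection on pedigree-BLUP EBVs computed each generation with the true
   additive variance: the *lowest*-EBV candidates are selected and the
   *highest*-EBV parents culled (sire/dam replacement 0.60/0.20).
5. **Four F1 cohorts** from Line1 dams x Line2 sires taken at parental
   generations (7, 27), (8, 28), (9, 29) and (10, 30).

Phenotypes are `mu + sex effect + TBV(QTL) + TBV(polygenic) + e`, with
residual variance (1 − h2) Vp, h2 = 0.33 and Vp = 0.13. The polygenic part
is transmitted as parent average plus a Mendelian-sampling deviation with
variance 0.5 sigma2_poly (1 − mean parental F); inbreeding F is tracked
exactly from Henderson's decomposition of the pedigree.

## Trait architectures

Five stock architectures (`simArchitecture()`): 0, 198 or 4,500 QTLs
explaining 0, 1/3 or all of the heritability, the remainder being
infinitesimal polygenic. The QTL count is deliberately **not** scaled with
genome length on reduced maps: with few loci carrying a fixed variance
budget, per-locus effects become large and 30 generations of truncation
selection fix them, collapsing the line's genetic variance — the trait would
leave the polygenic class the design simulates. Keeping the stated count
preserves per-locus effect sizes and the selection response. (A
`qtlDensityScaling` switch exists for tiny structural-test genomes.)

## Scaling the design to a desk

The full design (64,000-animal expansion; 52,886 SNPs) is a cluster-scale
object. The desk profile used throughout the tests runs one 25 cM
chromosome with 500 evenly spaced SNPs (the panel's 0.05 cM spacing) and
`simParams(scaleFactor = 0.05)`. Scaling is deliberately asymmetric:

* **Dam counts, cohort sizes and the expansion target scale
  proportionally** — they set data volume, not population genetics.
* **Historical sizes never scale.** Ancestral LD at a given spacing is set
  by historical Ne; at Ne = 100 the equilibrium r2 would be ~0.83 and no
  line could ever show 0.2.
* **Sire counts are floored (default 25).** A line's effective size is
  approximately 4 Nm Nf / (Nm + Nf), dominated by the sire pool; dividing
  sires by 20 would multiply per-generation drift twenty-fold over the same
  generation counts. With the floor, the scaled lines reproduce the
  full-scale design's realized behaviour: adjacent-SNP r2 ~ 0.17/0.29
  (Line1/Line2), mean inbreeding ~ 0.02/0.12, and a clear Line1-Line2-F1
  structure.

Line founders are drafted from the final expansion generation with sexes
assigned at drafting time; the expansion-final animals never breed within
the expansion, and the full-scale design requires more line dams than a
binomial sex split would provide.

# Genotype quality control

`qcPipeline()` keeps a SNP when, in every population, its minor allele
frequency is strictly above 0.05 and the absolute difference between its
observed and expected (2p(1−p)) heterozygote frequency is strictly below
0.15; only SNPs passing everywhere are kept. Both thresholds are strict
inequalities; the filters are per-SNP predicates, so filter order cannot
change the result and the pipeline is idempotent.

# Relationship matrices and the single-step H-inverse

* `buildA()` — Henderson's tabular recursion (dense; for toys and oracles).
* `buildAinv()` — Henderson's sparse rules with inbreeding-adjusted
  Mendelian-sampling variances.
* `relSubset()` — A among an arbitrary subset via sparse triangular solves
  on A = T D T', avoiding the full dense matrix; `inbreeding()` uses the
  same decomposition level by level, which stays fast on deep, completely
  recorded pedigrees where ancestor-list recursions degrade.
* `buildG()` — VanRaden's G = Z D Z'/k, Z = M − P, k = 2 Σ p(1−p), with
  optional per-SNP weights D. The allele-frequency source is an explicit
  argument (training purebreds, crossbreds, or pooled) because one of the
  evaluated designs exists precisely to put crossbred frequencies into G;
  the default is the pooled genotyped training set.
* `blendHinv()` — H⁻¹ = A⁻¹ + [0, 0; 0, tau (0.95 G + 0.05 A22)⁻¹ − omega
  A22⁻¹]. Blending precedes inversion; with G = A22 and tau = omega the
  correction cancels exactly (a test pins this). tau and omega are accepted
  within the tested grid (0.9–2.5 and 0.5–1.2) by default.

# Mixed models, REML, and SNP weighting

`solveSingleTrait()`/`solveMultiTrait()` assemble the usual mixed-model
equations (treatment-contrast fixed effects: mean, sex and, for pooled
single-trait training sets, population; the F1 cohorts share one
population level) and solve them with Jacobi-preconditioned conjugate
gradients — the standard iterative solver for animal-model MMEs, and robust
to the dense genotyped block of H⁻¹ — with a supernodal Cholesky fallback.
Solutions are accepted at a relative residual below 1e−8. Animals without
records obtain breeding values through the relationships; in the
three-trait model (Line1, Line2, F1 records as traits; u ~ N(0, G0 ⊗ H);
diagonal residual covariance because the traits are measured on different
animals) every animal receives all three trait GEBVs and crossbred
validation uses the F1 column.

`remlEstimate()` is AI-REML on the marginal covariance of the recorded
animals (V = G0[t(i),t(j)] A[i,j] + diag(R0)), with step halving, a
positive-definiteness guard on G0, a variance floor of 1e−6 Vp (boundary
estimates are flagged), and convergence at a relative parameter change
below 1e−8 (cap 200 iterations). Variance components are estimated with
the pedigree matrix, never H. At desk scale REML runs on a record subset
(default cap 900) chosen to keep every crossbred trainer together with its
recorded purebred parents — those parent-offspring links across the line
boundary are the only information identifying the purebred-F1 genetic
covariances, so random subsampling would discard exactly the informative
pairs.

`wssgblupRun()` implements the two-iteration weighting schedule: iteration
1 is plain ssGBLUP (identity D); SNP effects are then back-solved as
u = (1/k) D Z' G⁻¹ GEBV from the designated weight-source animals (their G
is blended 0.95/0.05 with the pedigree block for invertibility; with these
conventions Z u reproduces the genomic GEBVs exactly), converted to weights
d_j = u_j² 2p_j(1−p_j), normalized to mean one (keeping the genetic
variance scale stable and making the weights invariant to any constant
rescaling of the effects), and used to rebuild G and re-solve. No weight
ceiling is applied. In the purebred-training designs the crossbred weight
animals are not part of the genomic matrix; their iteration-1 GEBVs arrive
through the pedigree, which is the point of those designs.

# Scenarios, the scaling-factor grid, and validation

`scenarioSpec()` encodes the five designs (training sets, model, method and
weight source); `assembleScenario()` materializes them, always keeping the
two validation F1 cohorts genotyped and never letting their phenotypes into
training (a no-leakage test mutates them and asserts bitwise-identical
results). `validateGebv()` returns the Pearson accuracy and the dispersion
slope of true breeding values on GEBVs. `tauOmegaGrid()` evaluates the full
17 x 8 grid on the pooled single-trait design, re-using one inversion of
the blended G and of A22 across all 136 combinations, and selects the pair
minimizing |1 − slope| (slope averaged over both validation cohorts), with
ties broken by higher accuracy and then lower tau — the selection rule had
to be fixed here because only the winning pair is reported at full scale.
`pairedComparison()` runs paired t-tests across replicates, reporting
zero-variance difference vectors as degenerate. `runExperiment()` drives
replicates x architectures x scenarios with one simulation per replicate
shared by all scenarios, so comparisons are paired by replicate seed.

# Measurement conventions for connectedness

The diagnostics mirror the standard genotype-tooling conventions the
published workflow relies on:

* **Phase consistency** (`phaseConsistency()`): signed r per population
  for SNP pairs binned by physical distance (1 cM = 1 Mb; 60-kb bins up to
  ~1 Mb, so the first bin is the 0–60 kb headline bin). By default each
  population orients every locus to its *own minor allele* before signing r
  — the convention of per-population runs of the standard tooling. This
  matters: both lines inherit the same ancestral LD, so under a shared,
  pedigree-consistent allele labeling their signed-r correlation at 60 kb
  is ~0.7 at any scale; the per-population minor-allele convention, which
  randomizes label agreement wherever minor alleles differ, is the only
  reading consistent with the low published correlations (and with mean
  allele-A frequencies of ~0.3, which are mean minor-allele frequencies).
  `orient = "asIs"` is available for pedigree-consistent analyses.
* **Allele-frequency correlations** (`alleleFreqCorrelation()`): same
  orientation convention, same reasoning.
* **PCA** (`pcaOfG()`): eigendecomposition of G with scores scaled by the
  root eigenvalues; `deskDiagnostics()` reports the first component's share
  of the *leading 20* eigenvalues, the set the standard tooling outputs.
  Even under that convention the desk-scale share is ~10–18%: after pooled
  centering the leading eigenvalue is roughly n times the mean within-line
  relatedness contrast, while the within-line drift spectrum — produced by
  the same drift that correctly reproduces the LD and inbreeding targets —
  contributes eigenvalues of the same order. We verified the share does not
  rise between scale 0.05 and 0.15. The qualitative structure (PC1
  separates the lines with F1 intermediate) does hold and is asserted
  separately; the published ~80% share is not recoverable from the stated
  design under any eigen-share convention we could construct, which we
  report rather than emulate.

# Problem sizes and numerical choices

The package's own test and validation sweep uses two desk replications at
scale 0.05, each preserving the feature its quantities measure. Marker-level
quantities (adjacent r2, phase consistency, PCA, single-trait REML) run on
the 1 x 25 cM x 500 SNP genome, which keeps the design's 0.05 cM marker
spacing. Variance-component quantities run the 4,500-QTL trait on the
full-length 29-chromosome, 2,696.54 cM map with a token marker panel:
compressing thousands of QTLs onto one short chromosome makes truncation
selection act on whole-chromosome haplotypes, and the resulting hitchhiking
erodes the long-selected line's genetic variance about nine-fold — a
different trait class from the polygenic design — while REML never reads
markers, so the sparse panel changes nothing downstream. The sweep runs
five replicates for the marker-level criteria and three to five for the
three-trait REML, with REML record caps of 900 (bivariate pre-fits 600) and
a 200-animal-per-population PCA subsample — sizes chosen so a full
validation sweep is a coffee-break computation on one core while keeping
every per-replicate estimate comfortably inside its Monte-Carlo band.

The three-trait REML fit is two-stage, the standard multi-trait practice:
bivariate purebred-F1 analyses (which are well identified through recorded
parent-offspring pairs across the line boundary) supply starting values,
and the purebred-purebred covariance starts at the product of the two
purebred-F1 correlations. Without this, the Line1-Line2 covariance — almost
unidentified because the lines share no close pedigree ties — can wander to
a large negative value, where the positive-definiteness constraint on the
additive covariance matrix caps both identifiable correlations at
sqrt((1 + r12)/2) and the fit stalls far from its optimum. Degenerate
inputs are handled explicitly: monomorphic loci are rejected by `buildG()`
(QC must remove them) but zero-weighted with a warning in the weighting
path; zero additive variance short-circuits BLUP to all-equal (zero)
breeding values; zero-variance GEBVs make the dispersion slope an error
rather than an Inf.

# Known limitations

* Additive gene action only — no dominance or heterosis, so crossbred
  superiority arises only from line means and frequency differences.
* No genotyping error, missing data, or pedigree errors; QC therefore has
  no call-rate filter.
* The desk-scale replication preserves LD, inbreeding and variance targets
  but not sampling-noise magnitudes of the full design; accuracies at desk
  scale are lower and noisier than the full-scale figures, and the PCA
  variance share is scale-bound as described above.
* True simulated phase is used for LD; statistical phasing of real data is
  out of scope, as are APY-style approximations of H⁻¹ and unknown-parent
  groups.
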