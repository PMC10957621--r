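---
title: "Genomic prediction and GWAS from tetraploid allele-frequency genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction and GWAS from tetraploid allele-frequency genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model overview

`tetragp` implements a complete genomic-selection and association-mapping
workflow for autotetraploid crops genotyped by low-depth sequencing, of the
kind used in tetraploid potato breeding panels. The pipeline runs from read
counts to predictions:

1. **Allele-frequency genotypes.** Elite potato is autotetraploid but not
   uniformly so (gene copy number varies along the genome), so called
   discrete dosages can be misleading. Instead, the genotype of sample *i*
   at SNP *k* is taken directly as the alternative-allele read fraction
   `X_ik = alt / (ref + alt)`, a continuous value on [0, 1] whose expectation
   is dosage/4. Cells with zero depth are missing.
2. **Relationship matrix.** The genotype matrix is centered by marker means
   `p_k` and scaled per sample by the missing-data weight
   `w_i = sum_k p_k(1-p_k) / sum_{k observed in i} p_k(1-p_k)`, giving
   `Z_ik = (X_ik - p_k) w_i` with missing entries set to 0 (mean imputation
   on the centered scale). The genomic relationship matrix is
   `G = ZZ' / c` with the global tetraploid scaling
   `c = 0.25 sum_k p_k(1-p_k)`, the expected sum of genotypic variances of
   allele-frequency genotypes and, under Hardy-Weinberg-like data, the
   expected average diagonal of `ZZ'`.
3. **GBLUP.** `y = 1 mu + g + e`, `g ~ N(0, G sigma_g^2)`,
   `e ~ N(0, I sigma_e^2)`. Variance components are estimated by REML with
   the ratio `delta = sigma_e^2 / sigma_g^2` profiled on the
   eigendecomposition of `G`; GEBVs are the BLUP solutions. Genomic
   heritability is `h_g^2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)`.
4. **Cross-validation.** Clones are split into 8 random folds; each fold is
   masked in turn and predicted through the relationship matrix; the scheme
   is repeated 10 times and the headline GEBV is the across-repeat average.
   Accuracy is the Pearson correlation `r(GEBV : y)`; calibration is the
   slope of observed on predicted (1 = unbiased). Accuracies of competing
   marker sets are compared by Welch t-tests at a Bonferroni-corrected
   level.
5. **GWAS.** Each marker is tested in
   `y = 1 mu + x_i b_i + g + e` where the polygenic covariance uses a
   leave-one-chromosome-out (LOCO) `G`, so a tested marker never also feeds
   the correction term. Genomic control divides the chi-squared quantiles by
   the inflation factor `lambda_gc = median(chi^2) / 0.45494` whenever
   `lambda_gc > 1`; significance uses the Bonferroni threshold `0.05/N` and
   per-marker variance explained is reported in percent.
6. **Heritability from pedigree.** Narrow-sense heritability is also
   estimated as the OLS slope of offspring phenotype on mid-parent
   phenotype, the classical quantitative-genetics estimator for a diallel
   panel with phenotyped parents.

# Estimation choices

**REML instead of sampling.** The flat-prior additive GBLUP has a
deterministic REML solution once `G` is eigendecomposed: for a candidate
ratio `delta` the rotated model is diagonal, `sigma_g^2` profiles out
analytically and a one-dimensional maximization over `log delta`
(`stats::optimize` on [-12, 12]) finds the REML estimate in milliseconds.
A Monte-Carlo sampler would estimate the same posterior mean for this model
at far higher cost and with seed-dependent jitter, so the package uses the
REML route throughout; its equivalence to ridge-regression SNP-BLUP at
shrinkage `lambda = c sigma_e^2 / sigma_g^2` is verified to 1e-8 in the
test suite (the classical GBLUP/RR-BLUP duality).

**Held-out predictions.** Masked clones are predicted by relationship
propagation, `g_test = sigma_g^2 G[test,train] V_train^{-1} (y_train - mu)`,
which is algebraically identical to fitting ridge SNP effects on the
training clones and applying them to the test genotypes — also covered by
the duality test.

**EMMAX-style scans.** Variance components are estimated once per LOCO
matrix on the null model and held fixed across that chromosome's markers;
each marker then needs only a 2x2 generalized-least-squares solve in the
rotated basis. Per-marker REML would cost thousands of eigendecompositions
for no material change in the Wald statistics. The Wald test uses the
large-sample normal reference by default (`df_correction = TRUE` switches
to a t with n-2 df). P-values are floored at 1e-300 so the chi-squared
back-conversion used by genomic control stays finite on extreme scans.

**Unplaced markers.** Markers on chromosome "0" (pseudomolecule bin) are
tested against the genome-minus-chromosome-0 matrix and are never excluded
when a real chromosome is tested: an unplaced marker cannot double-count a
placed chromosome.

**Numerical safeguards.** `G` is used as-is (no eigenvalue clipping); a
1e-6 diagonal ridge is added only if the spectrum is materially indefinite.
Monomorphic markers are skipped (and flagged) in scans; markers with zero
variance contribute nothing to `c`; an all-monomorphic panel is an error.

# Filters, subsets and marker reduction

Marker filters follow the two-pass convention for GBS panels: first a minor
allele frequency bound of 1% (mean per-sample allele frequency strictly
inside (0.01, 0.99)), mean depth > 5 and marker missingness <= 50%; then a
depth band of 5-60 and removal of individuals missing > 70% of markers. The
MAF can alternatively be computed from pooled read counts
(`maf_method = "pooled"`); the mean-frequency reading is the default because
the filters are defined on average variant frequencies.

Annotation subsets split markers into non-synonymous, synonymous and
non-coding classes; the non-coding class is thinned to every third variant
(by position) to keep class sizes comparable, the combination set is the
union of the three, and a further 1-in-3 thinning of the combination set
serves as a reduced scan panel.

The density-reduction series repeatedly halves the position-sorted marker
set into interleaved bins (preserving whole-genome dispersion), keeping
four replicate bins per level once eight or more would arise — one child
per parent bin with alternating parity, a deterministic, seedless rule.
Halving continues while bins still hold at least `min_markers` (default
~150) markers, so the last halved level sits just below the target; a final
level takes every 10th marker of the first smallest bin. A 1,000-marker set
therefore yields levels of 500, 250 and 125 markers plus a 13-marker tail.

# The simulator

The synthetic-data generator exists so that every stage can be validated
against known truth without external downloads. It emulates the design of a
tetraploid potato breeding panel:

* **Founders and crosses.** 18 tetraploid founders by default, crossed in a
  full diallel (all ordered pairs, reciprocals distinct, no selfing);
  partial cross lists emulate male-sterile parents. Founder homolog alleles
  are i.i.d. Bernoulli(p_k), so founder dosages are Binomial(4, p_k).
* **Meiosis.** Bivalent pairing only: the four homologs pair at random into
  two bivalents and each contributes one recombinant product, so every
  gamete carries two homologs. Crossovers are Poisson with mean equal to
  the chromosome length in Morgans (Haldane map, no interference; 1 Morgan
  per chromosome by default). Double reduction is deliberately excluded —
  the downstream methods only need dosage-structured data, and bivalent
  pairing is the simplest defensible tetrasomic model. Gamete dosage
  distributions are tested against exact enumeration of the C(4,2) homolog
  pairs.
* **Sequencing.** Read depth per cell is negative binomial (mean 8,
  dispersion 2 by default, Poisson when dispersion is infinite), emulating
  overdispersed low-depth GBS; alt reads are Binomial(depth,
  d/4(1-e) + (1-d/4)e) with per-read error e = 0.005; zero depth is
  recorded as missing.
* **Annotation.** Chromosomes are tiled into segments; segments are genic
  with probability matching the non-synonymous + synonymous fractions
  (default 0.18/0.19/0.63 for ns/s/noncoding, the approximate class ratios
  of an annotated potato GBS panel before non-coding thinning); markers in
  genic segments split ns:s, markers outside are non-coding.
* **Phenotypes.** `y = mu + TBV + year_j + e` with additive QTL effects,
  fixed year effects (defaults: two years, offset 1.5, replicate counts 1
  and 2) and residual variance solved from the target heritability:
  `sigma_e^2 = Var(TBV)(1 - h^2)/h^2`. Founders receive phenotypes too, so
  mid-parent regression is estimable.

What the simulator does **not** emulate: linkage-disequilibrium block
structure calibrated to any real panel (map length is a free parameter),
sequence-level reads, selfing, aneuploidy, double reduction, dominance or
epistasis, and genotype-by-environment interaction. Passing tests therefore
demonstrate correctness of the algorithms under tetrasomic additive
inheritance with family structure — not that any particular real panel will
reach a given accuracy.

# Validation experiments and problem sizes

The automated checks (test suite and `scripts/acceptance.R`) recompute the
following, with sizes chosen to finish in minutes on one core while leaving
Monte-Carlo noise well inside the asserted bands:

* exact agreement of the vectorized `G` with a brute-force double-loop
  evaluation of the printed formulas (10 samples x 20 markers, 1e-12);
* mean diagonal of `G` within 1 +/- 0.05 on an i.i.d. HWE tetraploid panel
  (200 x 5,000);
* GBLUP/RR-BLUP duality to 1e-8 (50 x 200), including held-out clones;
* heritability recovery: median absolute error < 0.1 over 10 seeds for
  true h-squared in {0.2, 0.5, 0.8} (800 x 3,000), with cross-validated
  accuracy never exceeding sqrt(h^2) + 0.05;
* scan calibration: a trait polygenic in all panel markers — the covariance
  the relationship matrix is built for, as in LD-rich real data — at 200
  samples x 8,000 markers, so each marker's own polygenic share (n/m) is
  individually negligible; raw type-I error 0.05 +/- 0.01 and lambda_gc in
  [0.9, 1.1]. The simulator has no linkage disequilibrium between panel
  markers, so at large n/m every tested marker would carry a visible share
  of its own signal (E[chi-squared] grows by roughly n h^2 / m) — the small
  n/m regime isolates the calibration property itself. An uncorrected scan
  of a two-family population inflates lambda_gc far above 1.2;
* power: a QTL explaining 15% of phenotypic variance reaches the Bonferroni
  threshold in at least 18 of 20 replicates (700 x 5,000);
* density response on a 6-parent diallel (420 clones x 2,000 markers):
  per-bin mean bias within 1 +/- 0.15 at all densities above 100 markers,
  with the accuracy collapse confined to the final ~13-marker level. A
  family-structured panel is used here because subsets of a few hundred
  markers can only keep predicting while they still capture the realized
  relationships — the regime the method is designed for; on an unrelated
  panel of this size the baseline accuracy itself is too low for bias to be
  meaningful.

The phenotype utilities are checked against hand-evaluated values: the
under-water-weighing dry-matter equation, the length/width ratio with
re-orientation, Dixon's two-tailed Q test against the tabulated critical
values (r10 table for n <= 30; for 30 < n <= 200 a log-log regression fit
to the table tail, since published tables stop at 30), and the year-effect
mixed model (lme4) against a balanced closed-form design.

# Known limitations

* The year-correction model carries forward `mu + BLUP(genotype)`; a
  no-shrinkage alternative (`method = "means"`) is provided because the
  carried-forward quantity is a modeling choice, not a derived fact.
* PVE uses the effect/standard-error form
  `2 b^2 f(1-f) / (2 b^2 f(1-f) + se^2 2 n f(1-f))`; other PVE conventions
  exist and give different magnitudes at the same scan.
* The mid-parent regression slope is reported as the heritability estimate
  without standard-error-in-variables correction; with noisy parental
  phenotypes it is attenuated.
* Genomic-control correction is global per scan (one lambda per trait and
  marker set), not per chromosome.
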