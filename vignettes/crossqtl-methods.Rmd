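---
title: "Methods: integrative QTL, hotspot, causality and network analysis in F2 crosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative QTL, hotspot, causality and network analysis in F2 crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossqtl)
```

crossqtl implements the statistical backbone of an integrative-genetics
study in an F2 intercross: genome scans for clinical-trait QTL (cQTL) and
expression QTL (eQTL), permutation-based FDR calibration, detection and
replication of trans-eQTL hotspots, likelihood-based causality calls for
locus–transcript–trait triplets, weighted co-expression network modules,
and a matched-resampling test for eSNP enrichment in GWAS results. This
vignette describes the models, the tunable parameters, the numerical
choices, and what the synthetic-data generator does and does not emulate.

## The F2 cross and genotype probabilities

An F2 intercross of two inbred strains segregates each locus 1:2:1
(AA:AB:BB). Genotypes are observed at markers only; scans run on a cM grid
that includes pseudomarkers. `genotype_probabilities()` computes
$P(g_{i\ell} \mid \text{markers})$ by a three-state forward–backward
algorithm with

* prior $(\tfrac14, \tfrac12, \tfrac14)$,
* transitions from two independent meioses under the Haldane map
  $r = \tfrac12(1 - e^{-2d/100})$ (no crossover interference), e.g.
  $P(AA \to AB) = 2r(1-r)$ and $P(AB \to AB) = (1-r)^2 + r^2$,
* emissions $1-\varepsilon$ for the observed class and $\varepsilon/2$ for
  each other class.

Defaults: grid step 2 cM; genotyping-error rate $\varepsilon = 0.001$, a
small buffer against miscalls (the error model of the original genotyping
is not recoverable, so this is a package choice). The forward–backward
recursion is checked in the test suite against exhaustive path enumeration
on chains of up to four markers at $10^{-10}$.

`estimate_map()` re-estimates adjacent-marker recombination fractions by EM
on the F2 two-meiosis transition model. Every cell of the 3×3 joint
genotype table has a known recombinant-meiosis count except the double
heterozygote, which mixes zero and two recombinations with posterior weight
$2r^2/((1-r)^2 + r^2)$; the E-step fills that in, the M-step divides by
twice the sample size. Physical marker order is trusted (no reordering),
and monomorphic markers are dropped with a warning.

## Haley–Knott scans and LOD scores

Each trait is regressed at each grid locus on the expected genotype
components $L_A = P(AA) - P(BB)$ and $L_D = P(AB)$:

$$y_i = \mu + a\,L_{A i} + d\,L_{D i} + e_i, \qquad
\mathrm{LOD} = \frac{n}{2}\log_{10}\frac{RSS_0}{RSS_1}.$$

Expression traits are first pre-adjusted for gender by taking residuals of
a linear model on a gender indicator (`adjust_for_gender()`); on balanced
data this agrees with fitting gender as an additive covariate to within
about 0.2 LOD, which the suite checks. A perfect fit is capped at LOD 300
and flagged so results stay finite and serialisable; a rank-deficient
design drops the dominance column with a flag; a constant trait scores 0
everywhere. `hk_scan_matrix()` vectorises the solve across thousands of
transcripts with one QR per locus.

Permutations shuffle individual labels of the trait against whole genotype
rows, preserving genome-wide LD — the standard QTL permutation. The
package permutes gender-adjusted residuals (whether the original analysis
permuted raw or adjusted values is not recoverable; adjusted residuals keep
the null model aligned with the scan model).

## Permutation FDR

Trait-wise (cQTL-style) FDR: each observed genome-wide peak is converted to
an empirical p-value $p = (1 + \#\{\text{null} \ge \text{obs}\})/(P+1)$
against its own trait's $P$ permutation maxima; permuted maxima are
converted with the same formula (the count then includes the value itself —
the "self-counting" convention). The FDR at threshold $t$ is the mean
permuted discovery count over the observed discovery count, monotonised
q-value-style and capped at 1. Defaults: 1,000 permutations for clinical
traits, 5 for expression (pooled across probes in `eqtl_fdr()`, where
$\mathrm{FDR}(\lambda)$ is the average permuted exceedance count over the
observed count at LOD $\lambda$).

A limitation worth stating plainly: with $P$ permutations the smallest
attainable p-value is $1/(P+1)$. Under a complete null, some trait will
beat all of its permutations with appreciable probability once the number
of traits approaches $P$, and the estimated FDR at that threshold is then
0 — indistinguishable, by construction, from a true signal. This is a
resolution limit of permutation FDR at small $P$, not an implementation
artifact; with the production default of 1,000 permutations it is ten times
rarer than at the 200 used in the calibration tests.

## eQTL catalogs and hotspot detection

A reporter is counted once per (reporter, chromosome, tissue) at its
maximum LOD (`collapse_catalog()`), thresholded at LOD 5 by default. Peak
cM positions are converted to Mb by linear interpolation between flanking
markers' physical positions, and an eQTL is *cis* when it lies on the
gene's own chromosome within ±20 Mb of the gene (boundary inclusive),
otherwise *trans*. Catalog counts are binned into half-open 10 cM (or
10 Mb) bins anchored at 0 per chromosome. For each bin, `hotspot_test()`
reports

* a Poisson upper-tail p-value against the uniform expectation
  (catalog size divided by the number of genome bins — all mapped
  chromosomes at full length), computed in log space and floored at the
  smallest positive double so astronomically small values stay
  representable, and
* an empirical p against the genome-wide maximum bin count of each
  permuted catalog.

Cross-tissue sharing uses (reporter, chromosome) keys with a union
denominator by default; a conditional-on-A denominator is available via
`denominator = "a"` since the printed percentages do not pin the convention
down. Replication of a signature in a second cohort supports two rules: a
lenient one (LOD ≥ 2 anywhere on the stated chromosome) and a strict one
(LOD ≥ 3 with the chromosome-wide peak inside a stated cM interval);
reporters absent from the replication cohort are tallied separately rather
than counted as failures.

The hotspot signature is summarised by `signature_pc1()` — the first
principal component of the standardised signature submatrix, sign-oriented
so the sum of gene loadings is positive — and correlated with clinical
traits by Pearson correlation with the usual two-sided t-approximation p.

## Likelihood-based causality model selection (LCMS)

For a transcript R and clinical trait C sharing a locus L, three joint
models are compared:

* **M1 (causal)**: $P(L)\,P(R\mid L)\,P(C\mid R)$ — the locus acts on the
  trait through the transcript;
* **M2 (reactive)**: $P(L)\,P(C\mid L)\,P(R\mid C)$;
* **M3 (independent)**: $P(L)\,P(R\mid L)\,P(C\mid L)$ with independent
  residuals.

$R$ and $C$ are normal about per-genotype means at L. Genotype uncertainty
enters as a mixture likelihood over the three-class posterior at L (hard
0/1 rows give hard-call mode); means and the common variance are fitted by
EM (tolerance $10^{-8}$, at most 500 iterations, deterministic). $P(L)$ is
common to all three models and cancels in AIC differences. Parameter
counts are $k = 7, 7, 8$; `AIC = 2k - 2\log L`; the verdict is the unique
argmin, with `no_call` on ties (difference below $10^{-9}$), constant
inputs, or degenerate fits (zero residual variance). M3 is implemented
without a residual-correlation parameter by default, matching the
verbal model definitions; `m3_correlation = TRUE` adds a bivariate-normal
correlation ($k = 9$) for sensitivity analysis, since the original
parameterisation of the independent model is not recoverable from the text.

Overlap pairs are collected when a trait peak and an expression peak
(both LOD ≥ 2) have intersecting LOD > 1 support regions on one
chromosome; the test marker L is the genotyped marker nearest the midpoint
of the two peaks, ties to the lower cM. The built-in calibration harness
(`lcms_calibration()`) simulates triplets under each generative model
(1:2:1 locus, additive effect 1 residual SD, linking coefficient 1, noise
SD 1, n = 300) and tabulates verdict rates; at these defaults the correct
call dominates in essentially all replicates, comfortably above the 80%
(causal, reactive) and 70% (independent) floors asserted in the tests.

Causal-gene enrichment of a signature uses the fold ratio
(signature causal fraction over array causal fraction) with a one-sided
Fisher exact p, cross-checked in the tests against a direct hypergeometric
summation oracle.

## Co-expression network modules

The network pipeline follows the weighted (soft-threshold) construction:
select the top 25% most variable genes (variance ranking; "most
differentially expressed" has no formal definition here, and MAD ranking is
available via a flag), form absolute Pearson correlations, and raise them
to a power β: $a_{ij} = |r_{ij}|^\beta$. β is the smallest integer whose
network is approximately scale-free, judged by the $R^2$ of regressing
$\log p(k)$ on $\log k$ over equal-width log-scale connectivity bins
(threshold 0.8, 10 bins). The unsigned network is the default because a
plain power of negative correlations is not well defined; a signed variant
(negative correlations truncated to zero) is available. The plain log–log
fit is implemented; a truncated-power-law variant of the fitting index is a
possible alternative reading and is not implemented.

The topological overlap matrix is
$\omega_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) / (\min(k_i,k_j) + 1 - a_{ij})$
with unit diagonal, and modules come from average-linkage clustering on
$1-\omega$ with a fixed-height branch cut. The cut is an **absolute**
dissimilarity height (default 0.99): joins involving background genes
saturate at exactly $1-\omega = 1$, so any high quantile of the join
heights equals the maximum and would merge the whole tree — an absolute
height just below 1 separates coherent branches from background reliably.
Branches of at least 20 genes become modules, coloured in descending size
order from a fixed palette (turquoise, blue, brown, yellow, green, red, …)
so colour labels are reproducible; everything else is grey. When all
pairwise dissimilarities are equal the result is a single module or all
grey depending on the minimum size — a documented boundary. Module
eigengenes are standardised within-module first principal components,
sign-oriented to positive mean gene correlation. Gene-set/module
enrichment is a hypergeometric upper tail with the fold defined relative to
a stated universe. Knockout signatures come from a per-gene two-group
one-way ANOVA (F test) at a configurable α (default 0.05; the threshold the
original analysis used is unstated).

## eSNP enrichment by matched resampling

The eligible universe keeps SNPs within 1 Mb of a gene with MAF strictly
above 4%. The observed statistic is the fraction of the eSNP set with GWAS
p below 0.05. The null is built from random SNP sets matched to the eSNP
set's MAF-decile × distance-quartile profile, drawn without replacement
within a resample and independently across resamples (default 100,000
resamples in production; tests use 2,000). Because the per-stratum hit
count of a without-replacement draw is exactly hypergeometric, the
implementation draws stratum counts from `rhyper` directly — identical in
distribution to materialising every index draw, and fast enough to repeat
the whole experiment hundreds of times in calibration tests. Strata too
small for their quota borrow from the nearest stratum with a warning. The
test reports $Z = (\text{obs} - \bar{f}_{null})/s_{null}$, the one-sided
upper normal-tail p, and a 95% percentile interval of the null. Matching
on linkage-disequilibrium structure is not implemented: the procedure's
own description specifies location and MAF matching only, and no LD
reference is available to a self-contained pipeline. The normal-tail p is
anti-conservative when the expected hit count is small (hypergeometric
skewness); calibration is checked at set sizes of a few thousand, where the
approximation is sound.

## The synthetic cross generator

`sim_config()` + `simulate_f2()` / `simulate_expression()` /
`simulate_traits()` / `simulate_snp_study()` generate a full study with
known truth:

* **Genotypes**: 19 autosomes (lengths declining 100→55 cM, 2 Mb/cM linear
  physical scale so the ±20 Mb cis logic is exercisable), markers every
  10 cM, two independent gametes per individual with Poisson crossover
  counts (Haldane, no interference), 2% genotypes missing completely at
  random, gender a balanced binary covariate.
* **Expression**: a trans hotspot on chromosome 8 at 35 cM drives 200
  transcripts located on other chromosomes with additive effect 1
  residual SD (half negative); 100 cis genes with effect at their own
  location; the rest pure noise; per-gene gender effects ~ N(0, 0.3).
  The effect-size distribution of the real hotspot is unknown; these
  defaults are chosen once for testability and held fixed.
* **Traits**: causal traits are linear in the hotspot signature score
  (mean of standardised hotspot-gene expression, each gene oriented by its
  true effect sign) plus noise; independent traits are driven by the locus
  with separate noise; reactive traits are driven by the locus and then
  generate a fresh block of linked genes from the trait — these genes are
  appended to the expression matrix and flagged in the truth table, since
  a reactive structure cannot be imposed on already-simulated transcripts.
* **SNP study**: association p-values uniform for background SNPs; a
  fraction π of eSNPs (default 0.10 when enrichment is planted, 0.05 for
  a null study) falls below 0.05.

What the generator does *not* emulate: crossover interference,
X-chromosome dosage, litter/cage and diet-time effects, heavy-tailed or
correlated expression noise, LD between the GWAS SNPs. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated generative assumptions, not robustness to every feature of real
data.

## Problem sizes and determinism

All generators and resampling routines are seeded; identical
(configuration, seed) pairs give byte-identical outputs, and the LCMS EM is
seed-free. The test suite and the acceptance script run the hotspot
experiment at n = 300 with 2,000 transcripts and 5 permuted catalogs, the
FDR calibration at 100 traits × 200 permutations on a 5-chromosome null
cross, LCMS calibration at 500 replicates per model, and the eSNP
calibration at 200 repeated experiments of 2,000 resamples — sizes chosen
so the whole suite completes in minutes on one core while keeping every
statistical property measurable.
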