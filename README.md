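# crossqtl

Integrative genetics for F2 intercross populations, in one tested R
package: Haley–Knott genome scans for clinical and expression traits on
hidden-Markov genotype probabilities, permutation-based FDR, trans-eQTL
hotspot detection against Poisson and permutation nulls, cross-cohort
hotspot replication, likelihood-based causality model selection (LCMS) for
locus–transcript–trait triplets, weighted gene co-expression network
modules (soft thresholding, topological overlap, fixed-height tree cut),
and a matched-resampling test for eSNP enrichment in GWAS results.

It is aimed at quantitative geneticists analysing two-strain mouse (or
similar) intercrosses who want the full chain — from genotype tables to
"this transcript tests causal for this trait" and "this eSNP set is
enriched for GWAS signal" — reproducible from code, with a seeded
synthetic-cross generator so every stage is testable without external
data.

## The statistics at the core

* **Scans.** At each grid locus, a trait is regressed on the expected
  genotype components L_A = P(AA) − P(BB) and L_D = P(AB) computed by a
  3-state forward–backward algorithm under the Haldane map;
  LOD = (n/2)·log10(RSS0/RSS1). Expression traits are pre-adjusted for
  gender.
* **FDR.** Trait-wise empirical p-values against per-trait permutation
  nulls ((1 + #{null ≥ obs})/(P+1)), with the FDR at a threshold estimated
  as mean permuted discoveries over observed discoveries; eQTL FDR pools
  permuted scans across all probes.
* **Hotspots.** eQTL counted once per (reporter, chromosome, tissue),
  cis when within ±20 Mb of the gene; per-10 cM-bin unique-reporter counts
  tested against a uniform Poisson expectation and against permuted-catalog
  maxima.
* **LCMS.** For a locus L, transcript R and trait C, AIC compares
  M1 P(L)P(R|L)P(C|R) (causal), M2 P(L)P(C|L)P(R|C) (reactive) and
  M3 P(L)P(R|L)P(C|L) (independent), with R and C normal about
  per-genotype means and genotype uncertainty handled by a mixture
  likelihood (k = 7, 7, 8).
* **Networks.** a_ij = |r_ij|^β with the smallest β whose connectivity
  distribution is approximately scale-free (log–log R² > 0.8), topological
  overlap ω, average-linkage clustering of 1−ω with a fixed-height cut;
  module eigengenes are within-module first principal components.
* **eSNP enrichment.** Z = (observed − null mean)/null SD over random SNP
  sets matched to the eSNP set's MAF × distance-to-gene profile;
  p = 1 − Φ(Z).

## Worked example

Simulate a 300-individual cross with a 100-gene trans hotspot on
chromosome 8, scan, build the eQTL catalog, and test the hotspot:

```r
library(crossqtl)

cfg <- sim_config(n_f2 = 300, n_cis_genes = 50, n_null_genes = 450,
                  hotspot = list(chr = 8, pos_cM = 35, n_genes = 100,
                                 effect = 1, sign_mix = 0.5),
                  seed = 2024)
cross <- simulate_f2(cfg)
probs <- genotype_probabilities(cross, step = 2)
sim   <- simulate_expression(cross, cfg)
Y     <- apply(sim$expr, 2, adjust_for_gender, gender = cross$gender)
scan  <- hk_scan_matrix(Y, probs)
catalog <- build_catalog(peak_table(scan, threshold = 5),
                         sim$genes, cross$map, tissue = "adipose")
dplyr::count(catalog, chr, cis, sort = TRUE)
#>     chr cis       n
#> 1     8 trans   101
#> 2     3 cis       6
#> 3     1 cis       5
#> ...
```

All 100 planted hotspot transcripts (plus one lucky null gene) map in
trans to chromosome 8 at LOD ≥ 5; the cis genes map to themselves. The
hotspot test against 5 permuted catalogs:

```r
perm <- permute_scan_matrix(Y, probs, n_perm = 5, seed = 1, peaks = TRUE)
perm_cats <- lapply(perm$peak_tables, build_catalog, genes = sim$genes,
                    map = cross$map, threshold = 5)
hs <- hotspot_test(catalog, perm_cats,
                   tibble::tibble(chr = cfg$chromosomes$chr,
                                  length = cfg$chromosomes$length_cM),
                   bin_size = 10, unit = "cM")
glance(hs)
#>   top_chr top_bin_start top_count expected p_poisson p_empirical perm_max
#> 1       8            30        76    0.981 4.52e-113       0.167        1
```

76 unique reporters land in the [30, 40) cM bin of chromosome 8 against
an expectation of ~1 (Poisson p ≈ 1e−113), and no permuted catalog ever
puts more than 1 eQTL in any bin — the planted hotspot, recovered. The
signature's first principal component correlates strongly with the
simulated adiposity-like trait:

```r
tr  <- simulate_traits(sim, cross, cfg)
pc1 <- signature_pc1(tr$expr, sim$genes$gene[sim$genes$type == "hotspot"])
correlate_pc_traits(pc1, tr$traits)
#>   trait            n     r        p
#> 1 fat_mass       300 0.720 3.97e-49
#> ...
```

and the LCMS test calls a simulated causal chain correctly:

```r
trip <- simulate_lcms_triplet("causal", n = 300)
lcms(trip$W, trip$R, trip$C)
#> LCMS call: causal (n = 300)
#>   AIC  causal 1660.85  reactive 1712.29  independent 1878.34
```

The causal model's AIC beats the reactive model by ~51 and the independent
model by ~217: the data strongly support L → R → C.

Results are tibbles throughout; `tidy()`/`glance()` methods cover scans,
FDR tables, hotspot results, LCMS calls and module partitions, and
`autoplot()` draws LOD curves, hotspot bin profiles and module sizes.

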