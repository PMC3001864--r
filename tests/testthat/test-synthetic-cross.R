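# Generator properties: segregation ratios, map-distance behaviour of
# recombination, planted expression structure, trait architectures, SNP study.

test_that("F2 genotypes segregate 1:2:1 and respect map distances", {
  cfg <- sim_config(n_f2 = 10000,
                    chromosomes = tibble::tibble(chr = 1, length_cM = 60,
                                                 mb_per_cM = 2),
                    marker_spacing = 10, missing_rate = 0, hotspot = NULL,
                    seed = 11L)
  cross <- simulate_f2(cfg)
  freq <- table(cross$geno[, 1]) / nrow(cross$geno)
  expect_lt(max(abs(freq - c(0.25, 0.5, 0.25))), 0.01)

  # chi-square goodness of fit not rejected at alpha = 0.001
  gof <- stats::chisq.test(table(cross$geno[, 3]), p = c(0.25, 0.5, 0.25))
  expect_gt(gof$p.value, 0.001)

  # markers 10 cM apart: recombination fraction ~ Haldane closed form 0.0906
  g1 <- cross$geno[, 1]; g2 <- cross$geno[, 2]
  # count recombinant meioses among unambiguous cells via EM-free proxy:
  # use the package-independent EM oracle at large n via direct counting of
  # parental transitions in homozygote pairs
  hom <- g1 %in% c(1, 3) & g2 %in% c(1, 3)
  # between homozygote pairs each meiosis is observable: r_hat from
  # P(same | hom) = ((1-r)^2 + r^2-free) -- use gamete-level identity:
  # fraction of double-recombinant transitions
  same <- mean(g1[hom] == g2[hom])
  # P(AA->AA)/(P(AA->AA)+P(AA->BB)) = (1-r)^2/((1-r)^2+r^2)
  r_grid <- seq(0.001, 0.49, by = 1e-4)
  pred <- (1 - r_grid)^2 / ((1 - r_grid)^2 + r_grid^2)
  r_hat <- r_grid[which.min(abs(pred - same))]
  expect_lt(abs(r_hat - 0.0906), 0.01)
})

test_that("zero map distance gives identical gamete columns", {
  set.seed(5)
  g <- crossqtl:::simulate_gametes(300, 50, c(20, 20, 35))
  expect_identical(g[, 1], g[, 2])
  expect_false(all(g[, 2] == g[, 3]))  # 15 cM apart: some recombinants
})

test_that("adjacent-marker recombination increases with spacing and plateaus", {
  cfg <- sim_config(n_f2 = 4000,
                    chromosomes = tibble::tibble(chr = 1, length_cM = 400,
                                                 mb_per_cM = 1),
                    marker_spacing = 100, missing_rate = 0, hotspot = NULL,
                    seed = 21L)
  cross <- simulate_f2(cfg)
  first <- cross$geno[, 1]
  rf_to_first <- vapply(2:5, function(j) {
    g <- cross$geno[, j]
    hom <- first %in% c(1, 3) & g %in% c(1, 3)
    same <- mean(first[hom] == g[hom])
    r_grid <- seq(0.001, 0.5, by = 1e-3)
    pred <- (1 - r_grid)^2 / ((1 - r_grid)^2 + r_grid^2)
    r_grid[which.min(abs(pred - same))]
  }, numeric(1))
  expect_true(all(diff(rf_to_first) > -0.03))  # monotone up to noise
  expect_lt(abs(rf_to_first[4] - 0.5), 0.05)   # 400 cM: plateau at 1/2
})

test_that("simulation is reproducible and validates its configuration", {
  cfg <- small_cross$cfg
  a <- simulate_f2(cfg); b <- simulate_f2(cfg)
  expect_identical(a$geno, b$geno)
  ea <- simulate_expression(a, cfg); eb <- simulate_expression(b, cfg)
  expect_identical(ea$expr, eb$expr)
  sa <- simulate_snp_study(cfg); sb <- simulate_snp_study(cfg)
  expect_identical(sa$snps, sb$snps)

  expect_error(sim_config(n_f2 = 0), "positive")
  expect_error(sim_config(marker_spacing = 0), "positive")
  expect_error(sim_config(chromosomes = tibble::tibble(chr = numeric(),
                                                       length_cM = numeric(),
                                                       mb_per_cM = numeric())),
               "non-empty")
})

test_that("expression carries the planted hotspot, cis and null structure", {
  cross <- small_cross$cross; cfg <- small_cross$cfg
  sim <- small_cross$sim
  hot_marker <- sim$genes$qtl_cM[1]
  mk <- cross$map$marker[cross$map$chr == 2 &
                           cross$map$pos_cM == hot_marker][1]
  x <- cross$geno_true[, mk]

  # additive effect: mean(AA) - mean(BB) = 2a up to sampling error
  g1 <- sim$expr[, 1]
  a <- sim$genes$effect[1]
  diff_obs <- mean(g1[x == 1]) - mean(g1[x == 3])
  expect_lt(abs(diff_obs - 2 * a), 0.5)  # AA carries +1, BB -1
  # null gene uncorrelated with the hotspot genotype
  null_idx <- which(sim$genes$type == "null")[1]
  expect_lt(abs(cor(sim$expr[, null_idx], x)), 0.15)
})

test_that("gender effect disappears when its SD is zero", {
  cfg <- sim_config(n_f2 = 2000,
                    chromosomes = tibble::tibble(chr = 1:2, length_cM = 60,
                                                 mb_per_cM = 2),
                    hotspot = list(chr = 1, pos_cM = 30, n_genes = 5,
                                   effect = 1, sign_mix = 0),
                    n_cis_genes = 5, n_null_genes = 10,
                    gender_effect_sd = 0, seed = 31L)
  cross <- simulate_f2(cfg)
  sim <- simulate_expression(cross, cfg)
  m <- cross$gender == "M"
  diffs <- abs(colMeans(sim$expr[m, ]) - colMeans(sim$expr[!m, ]))
  expect_lt(max(diffs), 0.2)  # pure sampling error at n = 2000
})

test_that("trait architectures have the right conditional independences", {
  cfg <- sim_config(n_f2 = 500,
                    chromosomes = tibble::tibble(chr = 1:3, length_cM = 60,
                                                 mb_per_cM = 2),
                    hotspot = list(chr = 2, pos_cM = 30, n_genes = 40,
                                   effect = 1, sign_mix = 0.5),
                    n_cis_genes = 5, n_null_genes = 10, seed = 41L)
  cross <- simulate_f2(cfg)
  sim <- simulate_expression(cross, cfg)
  tr <- simulate_traits(sim, cross, cfg)
  mk <- tr$trait_truth$locus_marker[1]
  x <- cross$geno_true[, mk] - 2
  s <- tr$score

  pcor <- function(a, b, z) {
    ra <- residuals(lm(a ~ z)); rb <- residuals(lm(b ~ z))
    cor(ra, rb)
  }
  # causal: trait independent of locus given the signature score
  expect_lt(abs(pcor(tr$traits$fat_mass, x, s)), 0.15)
  # independent: trait independent of any hotspot gene given the locus
  expect_lt(abs(pcor(tr$traits$bone_density, sim$expr[, 1], x)), 0.15)
  # reactive: linked genes correlate with the trait
  linked <- tr$trait_truth$linked_genes[[2]]
  expect_gt(abs(cor(tr$expr[, linked[1]], tr$traits$glucose)), 0.5)

  # zero linking coefficient: trait uncorrelated with the signature score
  cfg0 <- cfg
  cfg0$trait_specs <- list(list(name = "flat", architecture = "causal",
                                coef = 0, noise_sd = 1))
  tr0 <- simulate_traits(sim, cross, cfg0)
  expect_lt(abs(cor(tr0$traits$flat, tr0$score)), 0.15)

  cfg_bad <- cfg
  cfg_bad$trait_specs <- list(list(name = "x", architecture = "mystery",
                                   coef = 1, noise_sd = 1))
  expect_error(simulate_traits(sim, cross, cfg_bad), "unknown trait architecture")
})

test_that("SNP study plants the configured enrichment", {
  cfg <- sim_config(seed = 51L,
                    snp_spec = list(n_snps = 50000, esnp_fraction = 0.1,
                                    enriched_fraction = 0.10,
                                    maf_range = c(0.01, 0.5)))
  s <- simulate_snp_study(cfg)
  frac <- mean(s$snps$p[s$snps$esnp] < 0.05)
  expect_lt(abs(frac - 0.10), 0.01)
  # null SNPs near 5%
  expect_lt(abs(mean(s$snps$p[!s$snps$esnp] < 0.05) - 0.05), 0.01)

  cfg_bad <- cfg; cfg_bad$snp_spec$n_snps <- 0
  expect_error(simulate_snp_study(cfg_bad), "positive")
  cfg_warn <- cfg; cfg_warn$snp_spec$enriched_fraction <- 0.04
  expect_warning(simulate_snp_study(cfg_warn), "indistinguishable")
})
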